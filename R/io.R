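#' Read and write session trial tables
#'
#' Sessions are stored as CSV with header
#' `trial,trial_type,cluster_type,gort_ms,ssd_ms,srrt_ms,outcome` and empty
#' fields for absent values. All durations are held internally in
#' milliseconds; files recorded in centi-seconds (`time_unit = "cs"`) are
#' converted on read (x10) and on write (/10). Malformed rows are rejected
#' with their trial numbers.
#'
#' @param path File path.
#' @param time_unit Unit of the durations in the file: `"ms"` or `"cs"`.
#' @param participant_id,group_label Metadata attached to the session.
#'
#' @return `read_session()` returns an `sst_session` tibble;
#'   `write_session()` returns the path invisibly.
#' @examples
#' s <- simulate_session(sst_design(96), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_session(s, f)
#' s2 <- read_session(f)
#' @export
read_session <- function(path, time_unit = c("ms", "cs"),
                         participant_id = "unknown", group_label = "unknown") {
  time_unit <- match.arg(time_unit)
  spec <- list(
    trial = readr::col_integer(),
    trial_type = readr::col_character(),
    cluster_type = readr::col_character(),
    gort_ms = readr::col_double(),
    ssd_ms = readr::col_double(),
    srrt_ms = readr::col_double(),
    outcome = readr::col_character()
  )
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character())))
  required <- c("trial", "trial_type", "gort_ms", "ssd_ms", "srrt_ms", "outcome")
  missing_cols <- setdiff(required, hdr)
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s.", paste(missing_cols, collapse = ", ")))
  }
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = do.call(readr::cols, spec[intersect(names(spec), hdr)]))
  if (nrow(x) == 0L) abort("Session file is empty.")
  if (any(diff(x$trial) != 1L) || x$trial[1] != 1L) {
    abort("`trial` must be 1..n with no gaps.")
  }
  scale <- if (time_unit == "cs") 10 else 1
  for (col in c("gort_ms", "ssd_ms", "srrt_ms")) x[[col]] <- x[[col]] * scale
  validate_session(x)
  p_ss <- mean(x$trial_type == "stop")
  new_sst_session(ensure_clusters(x), participant_id = participant_id,
                  group_label = group_label, p_ss = p_ss)
}

#' Validate a session trial table
#'
#' Checks the structural consistency rules of a trial table: outcomes only
#' on stop trials, delays only (and always) on stop trials, signal-respond
#' RTs exactly on failed stops, go RTs exactly on go trials. Violations
#' raise one error naming every broken rule with example trial numbers.
#'
#' @param x A session trial table.
#' @return `x`, invisibly, when valid.
#' @examples
#' validate_session(fixture_session("six"))
#' @export
validate_session <- function(x) {
  bad_type <- !x$trial_type %in% c("go", "stop")
  if (any(bad_type)) {
    abort(sprintf("Unknown trial_type at trial(s) %s.",
                  paste(head(x$trial[bad_type], 5), collapse = ", ")))
  }
  go <- x$trial_type == "go"
  problems <- c(
    "outcome present on a go trial" = any(go & !is.na(x$outcome)),
    "missing outcome on a stop trial" = any(!go & (is.na(x$outcome) | !x$outcome %in% c("SI", "FI"))),
    "SSD present on a go trial" = any(go & !is.na(x$ssd_ms)),
    "SSD missing on a stop trial" = any(!go & is.na(x$ssd_ms)),
    "SRRT present off a failed stop" = any(!is.na(x$srrt_ms) &
                                             !(x$trial_type == "stop" & !is.na(x$outcome) & x$outcome == "FI")),
    "SRRT missing on a failed stop" = any(!go & !is.na(x$outcome) & x$outcome == "FI" & is.na(x$srrt_ms)),
    "GORT present on a stop trial" = any(!go & !is.na(x$gort_ms)),
    "GORT missing on a go trial" = any(go & is.na(x$gort_ms))
  )
  if (any(problems)) {
    which_bad <- function(flag) switch(flag,
      "outcome present on a go trial" = x$trial[go & !is.na(x$outcome)],
      "missing outcome on a stop trial" = x$trial[!go & (is.na(x$outcome) | !x$outcome %in% c("SI", "FI"))],
      "SSD present on a go trial" = x$trial[go & !is.na(x$ssd_ms)],
      "SSD missing on a stop trial" = x$trial[!go & is.na(x$ssd_ms)],
      "SRRT present off a failed stop" = x$trial[!is.na(x$srrt_ms) &
                                                   !(x$trial_type == "stop" & !is.na(x$outcome) & x$outcome == "FI")],
      "SRRT missing on a failed stop" = x$trial[!go & !is.na(x$outcome) & x$outcome == "FI" & is.na(x$srrt_ms)],
      "GORT present on a stop trial" = x$trial[!go & !is.na(x$gort_ms)],
      "GORT missing on a go trial" = x$trial[go & is.na(x$gort_ms)]
    )
    msgs <- vapply(names(problems)[problems], function(f) {
      sprintf("%s (trial %s)", f, paste(head(which_bad(f), 3), collapse = ", "))
    }, character(1))
    abort(paste("Invalid session:", paste(msgs, collapse = "; ")))
  }
  invisible(x)
}

#' @rdname read_session
#' @param session An `sst_session` or compatible trial table.
#' @export
write_session <- function(session, path, time_unit = c("ms", "cs")) {
  time_unit <- match.arg(time_unit)
  cols <- c("trial", "trial_type", "cluster_type", "gort_ms", "ssd_ms",
            "srrt_ms", "outcome")
  session <- ensure_clusters(session)
  x <- as_tibble(session)[cols]
  scale <- if (time_unit == "cs") 0.1 else 1
  for (col in c("gort_ms", "ssd_ms", "srrt_ms")) x[[col]] <- x[[col]] * scale
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' Write per-session SSRT estimate tables
#'
#' Writes an estimates table (e.g. rows from [estimate_all()]) as CSV with
#' a stable column order and durations rounded to 0.1 ms.
#'
#' @param rows Non-empty data frame of estimate rows.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_estimates <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) abort("No estimate rows to write.")
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(v) round(v, 1))
  readr::write_csv(as_tibble(rows), path, na = "")
  invisible(path)
}

#' Write a simulated cohort to disk with a manifest
#'
#' Saves each session as its own CSV and writes a manifest CSV listing
#' `participant_id`, `group_label`, `category`, `a`, `n_trials`, `seed`,
#' and the session file path.
#'
#' @param cohort A tibble from [build_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort$file <- file.path(dir, sprintf("%s_n%d.csv", cohort$participant_id,
                                        cohort$n_trials))
  purrr::walk2(cohort$session, cohort$file, write_session)
  manifest <- cohort |>
    select("participant_id", "group_label", "category", "a", "n_trials",
           "seed", "file")
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' @rdname write_cohort
#' @param manifest_path Path to a manifest CSV written by [write_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  manifest$session <- purrr::pmap(
    list(manifest$file, manifest$participant_id, manifest$group_label),
    function(f, pid, grp) {
      if (!file.exists(f)) f <- file.path(base, basename(f))
      read_session(f, participant_id = pid, group_label = grp)
    }
  )
  manifest
}

#' Small hand-built example sessions
#'
#' Deterministic miniature trial tables used in examples and tests: a
#' 6-trial session covering every observation pattern and a 12-trial
#' session with both clusters populated.
#'
#' @param which `"six"` or `"twelve"`.
#' @return An `sst_session` tibble.
#' @examples
#' fixture_session("six")
#' @export
fixture_session <- function(which = c("six", "twelve")) {
  which <- match.arg(which)
  if (which == "six") {
    x <- tibble(
      trial = 1:6,
      trial_type = c("go", "stop", "go", "stop", "go", "go"),
      gort_ms = c(400, NA, 520, NA, 480, 610),
      ssd_ms = c(NA, 200, NA, 150, NA, NA),
      srrt_ms = c(NA, 380, NA, NA, NA, NA),
      outcome = c(NA, "FI", NA, "SI", NA, NA)
    )
  } else {
    x <- tibble(
      trial = 1:12,
      trial_type = c("go", "go", "stop", "stop", "go", "go",
                     "stop", "go", "go", "stop", "go", "go"),
      gort_ms = c(420, 450, NA, NA, 510, 460, NA, 530, 470, NA, 495, 505),
      ssd_ms = c(NA, NA, 200, 250, NA, NA, 200, NA, NA, 250, NA, NA),
      srrt_ms = c(NA, NA, NA, 430, NA, NA, 410, NA, NA, NA, NA, NA),
      outcome = c(NA, NA, "SI", "FI", NA, NA, "FI", NA, NA, "SI", NA, NA)
    )
  }
  new_sst_session(ensure_clusters(x), participant_id = paste0("fixture_", which),
                  group_label = "fixture", p_ss = mean(x$trial_type == "stop"))
}
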