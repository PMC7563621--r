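#' Simulate one tracking stop-signal-task session
#'
#' Generates an ordered trial table under the independent horse-race model.
#' On every trial a latent go-process finish time is drawn from the
#' cluster-specific go-RT distribution; on stop trials a latent stop-process
#' finish time (SSRT) is drawn as well and the race decides the outcome:
#' the inhibition succeeds iff `gort > ssrt + ssd`. The stop-signal delay
#' follows a 1-up/1-down staircase (`+ssd_step` after a successful
#' inhibition, `-ssd_step` after a failed one, floored at 0 ms), which
#' drives the successful-inhibition rate toward 50%.
#'
#' Observability follows the task: on go trials the response time (`gort_ms`)
#' is recorded; on failed stop trials the emitted response is recorded as the
#' signal-respond RT (`srrt_ms`) together with the SSD; on successful stop
#' trials only the SSD is recorded. Latent draws are kept in
#' `latent_gort_ms` / `latent_ssrt_ms` as simulation ground truth.
#'
#' Trial 1 has no predecessor and is labelled cluster A (the go-preceded
#' convention).
#'
#' @param design An [sst_design()].
#' @param participant_id Participant identifier stored on the session.
#' @param group_label Arbitrary group label stored on the session.
#' @param seed Optional integer seed; when given the session is reproducible.
#'
#' @return A tibble of class `sst_session`, one row per trial, with columns
#'   `trial`, `trial_type` (`"go"`/`"stop"`), `cluster_type` (`"A"`/`"B"`),
#'   `gort_ms`, `ssd_ms`, `srrt_ms`, `outcome` (`"SI"`/`"FI"`/`NA`),
#'   `latent_gort_ms`, `latent_ssrt_ms`. Session metadata (`participant_id`,
#'   `group_label`, `p_ss`, `time_unit = "ms"`) is carried in attributes.
#' @examples
#' s <- simulate_session(sst_design(96), seed = 1)
#' table(s$trial_type)
#' @export
simulate_session <- function(design, participant_id = "sim", group_label = "synthetic",
                             seed = NULL) {
  if (!inherits(design, "sst_design")) abort("`design` must be an `sst_design` object.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- design$n_trials

  if (design$cluster_mode == "merge") {
    n_a <- as.integer(round(n * design$w_a))
    streams <- list()
    if (n_a > 0L) {
      streams$A <- sim_stream(n_a, design$gort_a, design$ssrt_a, design,
                              allocation = "bernoulli")
    }
    if (n - n_a > 0L) {
      streams$B <- sim_stream(n - n_a, design$gort_b, design$ssrt_b, design,
                              allocation = "bernoulli")
    }
    merged <- bind_rows(
      if (!is.null(streams$A)) mutate(streams$A, cluster_type = "A"),
      if (!is.null(streams$B)) mutate(streams$B, cluster_type = "B")
    )
    merged <- merged[sample.int(n), , drop = FALSE]
    merged$trial <- seq_len(n)
    out <- merged
  } else {
    is_stop <- allocate_stops(n, design, design$allocation)
    cluster <- c("A", ifelse(is_stop[-n], "B", "A"))
    a_idx <- cluster == "A"
    latent_gort <- numeric(n)
    latent_gort[a_idx] <- rexgauss(sum(a_idx), design$gort_a)
    latent_gort[!a_idx] <- rexgauss(sum(!a_idx), design$gort_b)
    latent_ssrt <- rep(NA_real_, n)
    stop_a <- is_stop & a_idx
    stop_b <- is_stop & !a_idx
    latent_ssrt[stop_a] <- rexgauss(sum(stop_a), design$ssrt_a)
    latent_ssrt[stop_b] <- rexgauss(sum(stop_b), design$ssrt_b)
    raced <- run_staircase(is_stop, latent_gort, latent_ssrt, design)
    out <- tibble(
      trial = seq_len(n),
      trial_type = ifelse(is_stop, "stop", "go"),
      cluster_type = cluster,
      gort_ms = ifelse(is_stop, NA_real_, latent_gort),
      ssd_ms = raced$ssd,
      srrt_ms = ifelse(!is.na(raced$outcome) & raced$outcome == "FI",
                       latent_gort, NA_real_),
      outcome = raced$outcome,
      latent_gort_ms = latent_gort,
      latent_ssrt_ms = latent_ssrt
    )
  }
  new_sst_session(out, participant_id = participant_id,
                  group_label = group_label, p_ss = design$p_ss)
}

allocate_stops <- function(n, design, allocation) {
  switch(allocation,
    bernoulli = runif(n) < design$p_ss,
    blocked = {
      bs <- design$block_size
      if (n %% bs != 0L) abort("`n_trials` must be a multiple of `block_size` in blocked mode.")
      per_block <- round(bs * design$p_ss)
      as.vector(vapply(seq_len(n %/% bs), function(b) {
        v <- logical(bs)
        v[sample.int(bs, per_block)] <- TRUE
        v
      }, logical(bs)))
    }
  )
}

run_staircase <- function(is_stop, latent_gort, latent_ssrt, design) {
  n <- length(is_stop)
  ssd <- rep(NA_real_, n)
  outcome <- rep(NA_character_, n)
  cur_ssd <- design$ssd_init
  for (t in which(is_stop)) {
    ssd[t] <- cur_ssd
    if (latent_gort[t] > latent_ssrt[t] + cur_ssd) {
      outcome[t] <- "SI"
      cur_ssd <- cur_ssd + design$ssd_step
    } else {
      outcome[t] <- "FI"
      cur_ssd <- max(0, cur_ssd - design$ssd_step)
    }
  }
  list(ssd = ssd, outcome = outcome)
}

# one homogeneous tracking stream (single cluster's distributions, own staircase)
sim_stream <- function(n, gort_par, ssrt_par, design, allocation) {
  is_stop <- allocate_stops(n, design, allocation)
  latent_gort <- rexgauss(n, gort_par)
  latent_ssrt <- rep(NA_real_, n)
  latent_ssrt[is_stop] <- rexgauss(sum(is_stop), ssrt_par)
  raced <- run_staircase(is_stop, latent_gort, latent_ssrt, design)
  tibble(
    trial = seq_len(n),
    trial_type = ifelse(is_stop, "stop", "go"),
    cluster_type = NA_character_,
    gort_ms = ifelse(is_stop, NA_real_, latent_gort),
    ssd_ms = raced$ssd,
    srrt_ms = ifelse(!is.na(raced$outcome) & raced$outcome == "FI",
                     latent_gort, NA_real_),
    outcome = raced$outcome,
    latent_gort_ms = latent_gort,
    latent_ssrt_ms = latent_ssrt
  )
}

new_sst_session <- function(x, participant_id = "unknown", group_label = "unknown",
                            p_ss = NA_real_, time_unit = "ms") {
  x <- as_tibble(x)
  attr(x, "participant_id") <- participant_id
  attr(x, "group_label") <- group_label
  attr(x, "p_ss") <- p_ss
  attr(x, "time_unit") <- time_unit
  class(x) <- unique(c("sst_session", class(x)))
  x
}

#' @export
print.sst_session <- function(x, ...) {
  cat(sprintf("<sst_session> participant %s (%s), %d trials, %d stop\n",
              attr(x, "participant_id") %||% "?",
              attr(x, "group_label") %||% "?",
              nrow(x), sum(x$trial_type == "stop")))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seed derivation: keeps every derived seed a valid
# 32-bit integer and distinct across (base, index) pairs in practice.
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 104729) %% 2147483587) + 1L
}

#' Simulate the standard 44-participant cohort
#'
#' Builds the [cohort_grid()] and simulates one tracking session per
#' participant per requested session length. Stop-trial allocation,
#' staircase, and cluster structure follow [simulate_session()] defaults
#' (25% stop trials, initial SSD 200 ms, 50 ms steps).
#'
#' @param trial_counts Session lengths to simulate for every participant;
#'   each must be one of 96, 192, 288, 384, 480, 960.
#' @param base_seed Master seed; per-session substreams are derived from it
#'   deterministically, so equal `base_seed` gives byte-identical cohorts.
#' @param grid Participant grid; defaults to [cohort_grid()]. Must carry the
#'   same columns.
#' @param ... Further arguments passed to [sst_design()] (e.g. `allocation`).
#'
#' @return A tibble with one row per (participant, session length):
#'   `participant_id`, `group_label`, `category`, `k`, `a`, `n_trials`,
#'   `seed`, and a list-column `session` of `sst_session` tibbles.
#' @examples
#' coh <- build_cohort(trial_counts = 96, base_seed = 1,
#'                     grid = cohort_grid()[1:2, ])
#' nrow(coh)
#' @export
build_cohort <- function(trial_counts = c(96L, 960L), base_seed = 1L,
                         grid = cohort_grid(), ...) {
  allowed <- c(96L, 192L, 288L, 384L, 480L, 960L)
  if (!all(trial_counts %in% allowed)) {
    abort(sprintf("`trial_counts` must be among {%s}.", paste(allowed, collapse = ", ")))
  }
  needed <- c("participant_id", "category", "k", "a",
              "gort_a", "gort_b", "ssrt_a", "ssrt_b")
  if (!all(needed %in% names(grid))) abort("`grid` is missing design columns.")

  sessions <- tidyr::expand_grid(grid, n_trials = as.integer(trial_counts))
  sessions$seed <- derive_seed(base_seed, seq_len(nrow(sessions)))
  # arbitrary synthetic 11/33 group split; carries no distributional meaning
  sessions$group_label <- ifelse(sessions$category == "inc_inc", "groupX", "groupY")
  sessions$session <- pmap(
    list(sessions$gort_a, sessions$gort_b, sessions$ssrt_a, sessions$ssrt_b,
         sessions$n_trials, sessions$participant_id, sessions$group_label,
         sessions$seed),
    function(ga, gb, sa, sb, nt, pid, grp, sd) {
      simulate_session(
        sst_design(n_trials = nt, gort_a = ga, gort_b = gb,
                   ssrt_a = sa, ssrt_b = sb, ...),
        participant_id = pid, group_label = grp, seed = sd
      )
    }
  )
  sessions |>
    select("participant_id", "group_label", "category", "k", "a",
           "n_trials", "seed", "session")
}
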