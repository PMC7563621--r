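#' Stop-signal task simulation design
#'
#' Bundles everything needed to simulate one tracking stop-signal-task (SST)
#' session under the independent horse-race model: ex-Gaussian go-RT (GORT)
#' and stop-process (SSRT) distributions for the two trial-history clusters,
#' the stop-signal probability, and the staircase that tracks the
#' stop-signal delay (SSD).
#'
#' Trials are labelled by the type of the *preceding* trial: a type-A trial
#' follows a go trial, a type-B trial follows a stop trial. Participants slow
#' down and stop better right after a stop trial, so the B-cluster
#' distributions are allowed to differ from the A-cluster ones.
#'
#' @param n_trials Total trials per session. Must be divisible by 4 so the
#'   expected stop-trial count `n_trials * p_ss` is integral at the default
#'   `p_ss = 0.25`.
#' @param gort_a,gort_b [exg_params()] for the go-RT distribution in the A
#'   and B clusters.
#' @param ssrt_a,ssrt_b [exg_params()] for the latent stop-process finish
#'   time in the A and B clusters.
#' @param p_ss Stop-signal probability, strictly between 0 and 1 (0 is
#'   allowed as a degenerate all-go design for testing).
#' @param ssd_init Initial stop-signal delay, ms.
#' @param ssd_step Staircase step, ms: SSD increases by this amount after a
#'   successful inhibition and decreases by it after a failed one
#'   (floored at 0).
#' @param allocation `"bernoulli"` places stop trials independently with
#'   probability `p_ss`; `"blocked"` places exactly `p_ss * block_size` stop
#'   trials in every block of `block_size` trials, in random order.
#' @param block_size Block length for `allocation = "blocked"`.
#' @param cluster_mode `"predecessor"` (default) labels each trial by the
#'   realized type of the previous trial, which keeps the cluster label
#'   truthful and yields a type-A stop-trial weight near `1 - p_ss`;
#'   `"merge"` instead simulates a type-A stream of `w_a * n_trials` trials
#'   and a type-B stream of `w_b * n_trials` trials separately — each with
#'   its own distributions and its own SSD staircase — and randomly
#'   interleaves them, keeping each trial's stream label. The merge mode
#'   trades label truthfulness (a merged trial's realized predecessor need
#'   not match its label) for exact control of the cluster weights and
#'   within-cluster tracking.
#' @param w_a Target type-A weight used only by `cluster_mode = "merge"`.
#'
#' @return An object of class `sst_design` (a named list).
#' @examples
#' d <- sst_design(96)
#' d$p_ss
#' @export
sst_design <- function(n_trials = 96L,
                       gort_a = exg_params(300, 35, 30),
                       gort_b = exg_params(450, 50, 30),
                       ssrt_a = exg_params(130, 70, 60),
                       ssrt_b = exg_params(150, 90, 60),
                       p_ss = 0.25,
                       ssd_init = 200,
                       ssd_step = 50,
                       allocation = c("bernoulli", "blocked"),
                       block_size = 24L,
                       cluster_mode = c("predecessor", "merge"),
                       w_a = 0.75) {
  allocation <- match.arg(allocation)
  cluster_mode <- match.arg(cluster_mode)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    abort("`n_trials` must be a positive count.")
  }
  n_trials <- as.integer(n_trials)
  if (n_trials %% 4L != 0L) abort("`n_trials` must be divisible by 4.")
  if (p_ss < 0 || p_ss >= 1) abort("`p_ss` must lie in [0, 1).")
  if (ssd_step <= 0) abort("`ssd_step` must be positive.")
  if (ssd_init < 0) abort("`ssd_init` must be non-negative.")
  if (w_a < 0 || w_a > 1) abort("`w_a` must lie in [0, 1].")
  for (nm in c("gort_a", "gort_b", "ssrt_a", "ssrt_b")) {
    p <- get(nm)
    if (!inherits(p, "exg_params")) abort(sprintf("`%s` must be an `exg_params` object.", nm))
  }
  structure(
    list(
      n_trials = n_trials, gort_a = gort_a, gort_b = gort_b,
      ssrt_a = ssrt_a, ssrt_b = ssrt_b, p_ss = p_ss,
      ssd_init = ssd_init, ssd_step = ssd_step,
      allocation = allocation, block_size = as.integer(block_size),
      cluster_mode = cluster_mode, w_a = w_a
    ),
    class = "sst_design"
  )
}

#' The 44-participant simulation grid
#'
#' Returns the standard 4-category x 11-participant design grid used for
#' cohort simulations. Go-RT distributions are ExG(300, 35, 30) in the A
#' cluster and ExG(450, 50, 30) in the B cluster for everyone. The latent
#' SSRT distributions vary by category and by a per-participant offset
#' `a = 2k`, `k = 1..11`:
#'
#' | category | A-cluster SSRT | B-cluster SSRT |
#' |---|---|---|
#' | `inc_inc` | ExG(130+a, 70+a, 60+a) | ExG(150+a, 90+a, 60+a) |
#' | `inc_dec` | ExG(130+a, 70-a, 60)   | ExG(150+a, 90-a, 60)   |
#' | `dec_inc` | ExG(130-a, 70+a, 60)   | ExG(150-a, 90+a, 60)   |
#' | `dec_dec` | ExG(130-a, 70-a, 60-a) | ExG(150-a, 90-a, 60-a) |
#'
#' The category names encode the direction of change of the SSRT mean and
#' standard deviation with `a`. In every cell the B-cluster SSRT mean
#' exceeds the A-cluster mean by exactly 20 ms.
#'
#' @return A 44-row tibble with columns `participant_id`, `category`, `k`,
#'   `a`, and list-columns `gort_a`, `gort_b`, `ssrt_a`, `ssrt_b` of
#'   [exg_params()].
#' @examples
#' g <- cohort_grid()
#' nrow(g) # 44
#' @export
cohort_grid <- function() {
  cats <- c("inc_inc", "inc_dec", "dec_inc", "dec_dec")
  grid <- tidyr::expand_grid(category = cats, k = 1:11)
  grid$a <- 2L * grid$k
  ssrt_pars <- function(category, a, base_mu, base_sigma) {
    switch(category,
      inc_inc = exg_params(base_mu + a, base_sigma + a, 60 + a),
      inc_dec = exg_params(base_mu + a, base_sigma - a, 60),
      dec_inc = exg_params(base_mu - a, base_sigma + a, 60),
      dec_dec = exg_params(base_mu - a, base_sigma - a, 60 - a)
    )
  }
  grid |>
    mutate(
      participant_id = sprintf("%s_k%02d", .data$category, .data$k),
      gort_a = list(exg_params(300, 35, 30)),
      gort_b = list(exg_params(450, 50, 30)),
      ssrt_a = map2(.data$category, .data$a, ssrt_pars, base_mu = 130, base_sigma = 70),
      ssrt_b = map2(.data$category, .data$a, ssrt_pars, base_mu = 150, base_sigma = 90)
    ) |>
    select("participant_id", "category", "k", "a",
           "gort_a", "gort_b", "ssrt_a", "ssrt_b")
}
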