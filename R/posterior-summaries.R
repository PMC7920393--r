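#' Recruitment probability
#'
#' The posterior probability that a region has been recruited (has started
#' seizing) by time `t`: `r_i(t) = p(t_i <= t)`, estimated as the fraction
#' of posterior onset-time draws at or below `t`. Nondecreasing in `t`
#' with `r_i(0) = 0`.
#'
#' @param onset_draws draws x regions matrix of posterior onset times
#'   (e.g. `predict(fit, "onsets")`).
#' @param times time grid, seconds.
#' @return `length(times)` x regions matrix of probabilities.
#' @export
recruitment_probability <- function(onset_draws, times) {
  stopifnot(is.matrix(onset_draws), is.numeric(times))
  r <- vapply(times, function(tt) colMeans(onset_draws <= tt),
              numeric(ncol(onset_draws)))
  r <- t(matrix(r, ncol(onset_draws), length(times)))
  colnames(r) <- colnames(onset_draws)
  rownames(r) <- times
  r
}

#' High-excitability probability
#'
#' The posterior probability that a region's excitability exceeds the
#' high-excitability threshold, `p_i = p(c_i > c_h)`, the Monte-Carlo
#' fraction of draws above `c_h`. Regions with `c >= 2` can switch to the
#' seizure state autonomously, without input from recruited neighbours;
#' under the standard-normal prior the threshold `c_h = 2` corresponds to
#' an expected `n * (1 - pnorm(2))` highly excitable regions.
#'
#' @param c_draws draws x regions matrix of excitability draws, or a
#'   `"seizure_fit"`.
#' @param c_h high-excitability threshold.
#' @return Named vector of probabilities in `[0, 1]`.
#' @export
high_excitability_probability <- function(c_draws, c_h = 2) {
  if (inherits(c_draws, "seizure_fit"))
    c_draws <- draw_matrix(c_draws$draws, good_chains(c_draws))
  stopifnot(is.matrix(c_draws))
  colMeans(c_draws > c_h)
}

#' Posterior predictive seizure ensembles
#'
#' Generates `n_reps` ensembles of `n_seizures` simulated seizures under
#' fixed excitation parameters `q`, drawing excitabilities from the
#' standard-normal prior, and summarizes each ensemble by the statistics
#' used in posterior predictive checking: the per-seizure fraction of
#' seizing regions, the SD of the seizing onset times, and their
#' 10th/50th/90th percentiles.
#'
#' @param q an [excitation_params()] object.
#' @param connectomes list of [connectome()]s, recycled across seizures.
#' @param n_seizures seizures per ensemble.
#' @param n_reps number of ensembles.
#' @param seed integer seed.
#' @param constants [model_constants()].
#' @return List with `stats` (a data frame of per-seizure, per-rep
#'   statistics) and `envelope` (5-95 percentile range of each ensemble-
#'   mean statistic across reps).
#' @export
posterior_predictive_ensemble <- function(q, connectomes, n_seizures,
                                          n_reps = 100, seed = 1,
                                          constants = model_constants()) {
  stopifnot(length(connectomes) >= 1)
  set.seed(seed)
  tl <- constants$t_lim
  rows <- vector("list", n_reps * n_seizures)
  idx <- 1L
  for (rep in seq_len(n_reps)) {
    for (s in seq_len(n_seizures)) {
      W <- connectomes[[(s - 1L) %% length(connectomes) + 1L]]
      n <- nrow(W)
      c <- stats::rnorm(n)
      t <- simulate_onsets(W, q, c, t_max = tl)
      sz <- t < tl
      tsz <- t[sz]
      rows[[idx]] <- data.frame(
        rep = rep, seizure = s,
        frac_seizing = mean(sz),
        onset_sd = if (sum(sz) > 1) stats::sd(tsz) else NA_real_,
        onset_p10 = if (any(sz)) unname(stats::quantile(tsz, .1)) else NA_real_,
        onset_p50 = if (any(sz)) unname(stats::quantile(tsz, .5)) else NA_real_,
        onset_p90 = if (any(sz)) unname(stats::quantile(tsz, .9)) else NA_real_)
      idx <- idx + 1L
    }
  }
  st <- do.call(rbind, rows)
  per_rep <- stats::aggregate(
    st[, c("frac_seizing", "onset_sd", "onset_p10", "onset_p50",
           "onset_p90")],
    by = list(rep = st$rep), FUN = mean, na.rm = TRUE)
  env <- apply(per_rep[, -1, drop = FALSE], 2, stats::quantile,
               probs = c(0.05, 0.95), na.rm = TRUE)
  list(stats = st, per_rep = per_rep, envelope = env)
}
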