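#' Generate a random normalized connectome
#'
#' Directed random network with Bernoulli(`density`) edges, heavy-tailed
#' log-normal weight magnitudes (like tractography streamline counts),
#' zero diagonal, passed through the max-ingoing-sum normalization so it
#' satisfies the connectome invariants.
#'
#' @param n number of regions (at least 2).
#' @param density edge probability in `(0, 1]`.
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal weight parameters before
#'   normalization.
#' @return A [connectome()] with max ingoing weight sum exactly 1.
#' @export
generate_network <- function(n, density = 0.3, seed = 1,
                             meanlog = 0, sdlog = 1) {
  stopifnot(n >= 2, density > 0, density <= 1)
  set.seed(seed)
  A <- matrix(stats::rbinom(n * n, 1, density) *
                stats::rlnorm(n * n, meanlog, sdlog), n, n)
  diag(A) <- 0
  if (max(rowSums(A)) == 0) A[1, 2] <- 1  # degenerate draw: keep connected
  A <- A / max(rowSums(A))
  connectome(A, paste0("R", seq_len(n)))
}

#' Generate a synthetic seizure with partial observation
#'
#' The generative direction of the statistical model: excitabilities are
#' drawn from the standard-normal prior, onsets simulated by the
#' propagation model, a hidden set chosen uniformly at random, and the
#' observed seizing onsets corrupted with Gaussian observation noise
#' (clipped to `(0, t_lim)`). Simulated onsets at or beyond `t_lim` are
#' observed as non-seizing. The full ground truth is returned alongside
#' so every downstream scorer is testable.
#'
#' @param W a [connectome()].
#' @param q an [excitation_params()] object.
#' @param hidden_fraction fraction of regions hidden, in `[0, 1)`.
#' @param noise_sd onset observation noise SD (s); default `sigma_t`.
#' @param seed integer seed.
#' @param constants [model_constants()].
#' @return List with `obs` (a [seizure_observation()]), `c_true`,
#'   `t_true`.
#' @export
generate_seizure <- function(W, q, hidden_fraction = 0.3, noise_sd = 5,
                             seed = 1, constants = model_constants()) {
  stopifnot(is_connectome(W), hidden_fraction >= 0, hidden_fraction < 1)
  set.seed(seed)
  n <- nrow(W)
  tl <- constants$t_lim
  c_true <- stats::rnorm(n)
  t_true <- simulate_onsets(W, q, c_true, t_max = 4 * tl)
  n_hidden <- round(hidden_fraction * n)
  hidden <- sample.int(n, n_hidden)
  status <- rep("hidden", n)
  onset <- rep(NA_real_, n)
  for (i in setdiff(seq_len(n), hidden)) {
    if (t_true[i] < tl) {
      tt <- t_true[i] + stats::rnorm(1, 0, noise_sd)
      tt <- min(max(tt, 1e-6), tl - 1e-6)  # clip into (0, t_lim)
      status[i] <- "seizing"; onset[i] <- tt
    } else {
      status[i] <- "non-seizing"; onset[i] <- Inf
    }
  }
  list(obs = seizure_observation(region_ids(W), status, onset),
       c_true = c_true, t_true = t_true)
}

#' Generate a synthetic cohort
#'
#' A cohort of patients with patient-specific random connectomes and a
#' fixed number of seizures per patient, all generated from one shared
#' excitation parameterization — the setting the hierarchical
#' multi-seizure fit is meant to invert. Defaults mirror the scale used
#' throughout the test suite: 20 regions, 15 patients x 2 seizures,
#' hidden fraction 0.3, observation noise 5 s.
#'
#' @param q an [excitation_params()] object (the shared truth).
#' @param n_regions,n_patients,seizures_per_patient cohort dimensions.
#' @param density connectome edge density.
#' @param hidden_fraction,noise_sd observation model.
#' @param seed integer seed.
#' @param constants [model_constants()].
#' @return List with `data` (list of `list(obs, W)` ready for
#'   [fit_cohort()]), `truth` (per-seizure `c_true`, `t_true`), and the
#'   generating `q`.
#' @export
generate_cohort <- function(q, n_regions = 20, n_patients = 15,
                            seizures_per_patient = 2, density = 0.3,
                            hidden_fraction = 0.3, noise_sd = 5, seed = 1,
                            constants = model_constants()) {
  data <- list(); truth <- list()
  k <- 0L
  for (p in seq_len(n_patients)) {
    W <- generate_network(n_regions, density, seed = seed * 10000L + p)
    for (s in seq_len(seizures_per_patient)) {
      k <- k + 1L
      gs <- generate_seizure(W, q, hidden_fraction, noise_sd,
                             seed = seed * 10000L + 100L * p + s,
                             constants = constants)
      data[[k]] <- list(obs = gs$obs, W = W, patient = p)
      truth[[k]] <- list(c_true = gs$c_true, t_true = gs$t_true,
                         patient = p)
    }
  }
  list(data = data, truth = truth, q = q)
}

#' Generate SEEG-like channel signals from region onset times
#'
#' Band-limited Gaussian noise whose variance is multiplied by `gain`
#' from the channel's region onset until the end of the seizure — the
#' band-power structure the onset detector responds to (a `gain`-fold
#' power step; amplitude scales by `sqrt(gain)`). No attempt is made to
#' mimic real SEEG morphology (spikes, DC shifts, artifacts).
#'
#' @param onsets named vector of region onset times, seconds into the
#'   recording (`Inf` for non-seizing); must leave at least 60 s of
#'   baseline before the earliest onset.
#' @param fs sampling rate (Hz).
#' @param duration recording length (s).
#' @param seizure_end end of seizure activity (s); defaults to
#'   `duration`.
#' @param band passband (Hz) of the noise.
#' @param gain power gain during the seizure.
#' @param clinical_onset clinician mark (s); defaults to the earliest
#'   finite onset.
#' @param seed integer seed.
#' @return List of [channel_record()]s, one per region.
#' @export
generate_seeg_signal <- function(onsets, fs = 256, duration = 400,
                                 seizure_end = duration, band = c(2, 40),
                                 gain = 10, clinical_onset = NULL,
                                 seed = 1) {
  stopifnot(fs > 2 * max(band))
  first <- suppressWarnings(min(onsets[is.finite(onsets)]))
  if (is.finite(first) && first < 60)
    stop("need at least 60 s of baseline before the earliest onset")
  if (is.null(clinical_onset))
    clinical_onset <- if (is.finite(first)) first else duration / 2
  set.seed(seed)
  ns <- round(duration * fs)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  tt <- seq_len(ns) / fs
  lapply(seq_along(onsets), function(i) {
    x <- as.numeric(signal::filtfilt(bf, stats::rnorm(ns)))
    if (is.finite(onsets[i])) {
      during <- tt >= onsets[i] & tt < seizure_end
      x[during] <- x[during] * sqrt(gain)
    }
    channel_record(names(onsets)[i], x, fs, clinical_onset)
  })
}

#' Generate a resection scenario
#'
#' Builds a resection set for a simulated seizure: either the true
#' epileptogenic zone (all regions with `c_true > c_h`, strategy
#' `"true_ez"`) or `k` regions chosen uniformly at random
#' (`"random_k"`).
#'
#' @param W a [connectome()].
#' @param c_true ground-truth excitabilities.
#' @param strategy `"true_ez"` or `"random_k"`.
#' @param k number of regions for `"random_k"`.
#' @param c_h high-excitability threshold.
#' @param seed integer seed.
#' @return List with `resected` (region ids; possibly empty) and the
#'   `strategy`.
#' @export
generate_resection_scenario <- function(W, c_true,
                                        strategy = c("true_ez", "random_k"),
                                        k = 0, c_h = 2, seed = 1) {
  strategy <- match.arg(strategy)
  set.seed(seed)
  ids <- region_ids(W)
  resected <- if (strategy == "true_ez") ids[c_true > c_h]
              else if (k > 0) sample(ids, k) else character(0)
  list(resected = resected, strategy = strategy)
}
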