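#' State prediction accuracy
#'
#' The predictive probability that a region's seizing/non-seizing state
#' matches the ground truth: the fraction of posterior onset draws below
#' `t_lim` if the truth is seizing, and at or above `t_lim` otherwise.
#' The two cases partition the draws, so the accuracies for the two
#' possible truths sum to one.
#'
#' @param t_draws numeric vector of posterior onset-time draws for the
#'   region (`Inf` allowed).
#' @param truth_seizing logical ground-truth state.
#' @param t_lim seizure time limit (s).
#' @return Accuracy in `[0, 1]`.
#' @export
state_prediction_accuracy <- function(t_draws, truth_seizing, t_lim = 90) {
  stopifnot(length(t_draws) >= 1)
  if (truth_seizing) mean(t_draws < t_lim) else mean(t_draws >= t_lim)
}

#' Onset prediction accuracy
#'
#' The predictive probability that the onset time is within `T` seconds
#' of the ground truth: the fraction of draws with `|t^s - t_true| < T`.
#' Only defined for seizing regions with `t_true < t_lim - T` (regions
#' closer to the limit suffer a border effect and are skipped).
#'
#' @param t_draws posterior onset-time draws.
#' @param t_true ground-truth onset (s).
#' @param T temporal resolution (s).
#' @param t_lim seizure time limit (s).
#' @return Accuracy in `[0, 1]`, or `NA` if the region is ineligible.
#' @export
onset_prediction_accuracy <- function(t_draws, t_true, T = 5, t_lim = 90) {
  if (!is.finite(t_true) || t_true >= t_lim - T) return(NA_real_)
  mean(abs(t_draws - t_true) < T)
}

#' Unweighted empirical estimate
#'
#' A baseline that replaces the posterior onset draws of region `i` by the
#' observed onset times of all other observed regions in the same seizure
#' (non-seizing regions entering as `Inf`), then applies the same accuracy
#' definitions.
#'
#' @param t_others observed onsets of the other observed regions (`Inf`
#'   for non-seizing); at least one.
#' @param truth_seizing logical ground-truth state of region `i`.
#' @param t_true ground-truth onset of region `i` (only used for the
#'   onset accuracy).
#' @param T,t_lim constants as in the accuracy measures.
#' @return List with `state_pa` and `onset_pa` (`NA` when ineligible).
#' @export
unweighted_estimate <- function(t_others, truth_seizing, t_true = NA,
                                T = 5, t_lim = 90) {
  stopifnot(length(t_others) >= 1)
  list(
    state_pa = state_prediction_accuracy(t_others, truth_seizing, t_lim),
    onset_pa = if (is.finite(t_true))
      onset_prediction_accuracy(t_others, t_true, T, t_lim) else NA_real_)
}

#' Weighted empirical estimate
#'
#' As [unweighted_estimate()], but each other region's observation is
#' weighted by its symmetrized connection strength to region `i`,
#' `w_ij + w_ji`, normalized once — equivalent to repeating each
#' observation proportionally to the weight. Scale-invariant in the
#' weights; reduces to the unweighted estimate when all weights are
#' equal. Undefined (reported `NA`) when the total weight is zero.
#'
#' @param t_others observed onsets of the other observed regions.
#' @param weights `w_ij + w_ji` for each of them.
#' @inheritParams unweighted_estimate
#' @return List with `state_pa` and `onset_pa`.
#' @export
weighted_estimate <- function(t_others, weights, truth_seizing,
                              t_true = NA, T = 5, t_lim = 90) {
  stopifnot(length(t_others) == length(weights), all(weights >= 0))
  tw <- sum(weights)
  if (tw == 0)
    return(list(state_pa = NA_real_, onset_pa = NA_real_))
  w <- weights / tw
  state <- if (truth_seizing) sum(w * (t_others < t_lim))
           else sum(w * (t_others >= t_lim))
  onset <- if (is.finite(t_true) && t_true < t_lim - T)
    sum(w * (abs(t_others - t_true) < T)) else NA_real_
  list(state_pa = state, onset_pa = onset)
}

#' Leave-one-out cross-validation of one seizure
#'
#' For every observed region of the seizure: hide its observation, refit
#' the single-seizure model, and score the posterior prediction for the
#' left-out region against the withheld truth with the state and onset
#' prediction accuracies. The same truths are also scored with the
#' unweighted and weighted empirical estimates built from the remaining
#' observations. Fits in which all chains are stuck are dropped (and
#' listed in the `excluded` attribute).
#'
#' @param obs a [seizure_observation()].
#' @param W a [connectome()].
#' @param q excitation parameters — the point estimate from a cohort fit
#'   on data *not* containing this seizure.
#' @param chains,warmup,draws,seed,method passed to [fit_seizure()].
#' @param constants [model_constants()].
#' @return Data frame with one row per observed region: truth, and
#'   `state_pa` / `onset_pa` for methods `inference`, `unweighted`,
#'   `weighted`.
#' @export
run_loo <- function(obs, W, q, chains = 2, warmup = 500, draws = 500,
                    seed = 1, method = "nuts",
                    constants = model_constants()) {
  stopifnot(inherits(obs, "seizure_observation"), is_connectome(W))
  tl <- constants$t_lim; TT <- constants$T
  observed <- which(obs$status != "hidden")
  rows <- list(); excluded <- character(0)
  for (i in observed) {
    truth_seizing <- obs$status[i] == "seizing"
    t_true <- if (truth_seizing) obs$onset_s[i] else NA_real_
    # hide region i; others untouched
    obs_i <- obs
    obs_i$status[i] <- "hidden"
    obs_i$onset_s[i] <- NA_real_
    fit <- fit_seizure(obs_i, W, q, chains = chains, warmup = warmup,
                       draws = draws, seed = seed + i, method = method,
                       constants = constants)
    if (isTRUE(fit$diagnostics$all_stuck)) {
      excluded <- c(excluded, obs$region_ids[i])
      next
    }
    t_draws <- predict(fit, "onsets")[, i]
    others <- setdiff(observed, i)
    t_others <- ifelse(obs$status[others] == "seizing",
                       obs$onset_s[others], Inf)
    wsym <- unclass(W)[i, others] + unclass(W)[others, i]
    est <- unweighted_estimate(t_others, truth_seizing, t_true, TT, tl)
    west <- weighted_estimate(t_others, wsym, truth_seizing, t_true, TT, tl)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = obs$region_ids[i],
      truth_state = if (truth_seizing) "seizing" else "non-seizing",
      truth_onset = t_true,
      state_pa_inference =
        state_prediction_accuracy(t_draws, truth_seizing, tl),
      onset_pa_inference = if (truth_seizing)
        onset_prediction_accuracy(t_draws, t_true, TT, tl) else NA_real_,
      state_pa_unweighted = est$state_pa,
      onset_pa_unweighted = est$onset_pa,
      state_pa_weighted = west$state_pa,
      onset_pa_weighted = west$onset_pa)
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Precision-recall curve against a relevant region set
#'
#' Sweeps a threshold `p_t` over the per-region high-excitability
#' probabilities: regions with `p_i > p_t` are predicted epileptogenic
#' and compared with the relevant set (e.g. the resected regions with
#' resection extent above 50%). Precision is `TP / (TP + FP)`, recall is
#' `TP / (TP + FN)`; with no predictions, precision is reported as 1 and
#' flagged (`no_predictions`), and such points are dropped from curves by
#' default.
#'
#' @param p named vector of `p(c_i > c_h)` per region.
#' @param relevant character vector of relevant region ids (nonempty).
#' @param thresholds threshold grid for `p_t`.
#' @param drop_empty drop thresholds with no predictions.
#' @return Data frame with `threshold`, `precision`, `recall`,
#'   `no_predictions`.
#' @export
precision_recall_curve <- function(p, relevant,
                                   thresholds = seq(0, 1, by = 0.02),
                                   drop_empty = TRUE) {
  stopifnot(!is.null(names(p)), length(relevant) >= 1)
  rel <- names(p) %in% relevant
  rows <- lapply(thresholds, function(pt) {
    pred <- p > pt
    tp <- sum(pred & rel); fp <- sum(pred & !rel); fn <- sum(!pred & rel)
    empty <- (tp + fp) == 0
    data.frame(threshold = pt,
               precision = if (empty) 1 else tp / (tp + fp),
               recall = tp / (tp + fn),
               no_predictions = empty)
  })
  out <- do.call(rbind, rows)
  if (drop_empty) out <- out[!out$no_predictions, , drop = FALSE]
  out
}

#' Virtual resection
#'
#' Removes the resected regions from the network and re-simulates the
#' seizure for every posterior excitability draw (each draw restricted to
#' the surviving regions), then counts the regions whose recruitment
#' probability at `t_lim` exceeds 50%: pre-operatively over the intact
#' network (all regions), post-operatively over the surviving regions
#' only — resected regions are never counted post-operatively. The
#' relative reduction `(n_preop - n_postop) / n_preop` summarizes the
#' predicted surgical effect. A thresholding-free variant — the decrease
#' of the mean seizure probability, with resected regions entering the
#' post-operative mean as zero so the denominators match — is reported
#' alongside.
#'
#' @param W a [connectome()] (pre-operative).
#' @param resected region ids to remove.
#' @param c_draws draws x regions matrix of posterior excitability draws
#'   from the pre-operative fit (columns named by region), or the
#'   pre-operative `"seizure_fit"` itself.
#' @param q excitation parameters.
#' @param constants [model_constants()].
#' @return List with `n_preop`, `n_postop`, `relative_reduction`,
#'   `prob_preop`, `prob_postop`, `prob_decrease`.
#' @export
virtual_resection <- function(W, resected, c_draws, q,
                              constants = model_constants()) {
  stopifnot(is_connectome(W))
  if (inherits(c_draws, "seizure_fit")) {
    c_draws <- draw_matrix(c_draws$draws, good_chains(c_draws))
    colnames(c_draws) <- region_ids(W)
  }
  stopifnot(is.matrix(c_draws))
  if (is.null(colnames(c_draws))) colnames(c_draws) <- region_ids(W)
  tl <- constants$t_lim
  q4 <- q_anchors(q)
  ids <- region_ids(W)
  surviving <- setdiff(ids, resected)

  t_pre <- sim_onsets_many_cpp(unclass(W), q4, c_draws[, ids, drop = FALSE],
                               tl)
  r_pre <- colMeans(t_pre < tl)
  names(r_pre) <- ids

  W_post <- apply_resection(W, resected)
  t_post <- sim_onsets_many_cpp(unclass(W_post), q4,
                                c_draws[, surviving, drop = FALSE], tl)
  r_post <- colMeans(t_post < tl)
  names(r_post) <- surviving

  n_preop <- sum(r_pre > 0.5)
  n_postop <- sum(r_post > 0.5)
  prob_preop <- mean(r_pre)
  prob_postop <- sum(r_post) / length(ids)
  list(n_preop = n_preop, n_postop = n_postop,
       relative_reduction = if (n_preop > 0)
         (n_preop - n_postop) / n_preop else 0,
       prob_preop = prob_preop,
       prob_postop = prob_postop,
       prob_decrease = prob_preop - prob_postop)
}

#' Aggregate virtual-resection results per patient
#'
#' @param results list of [virtual_resection()] results (one per seizure).
#' @param fun `"mean"` (default) or `"min"` across seizures.
#' @return Named list of aggregated `n_postop` and `relative_reduction`.
#' @export
aggregate_virtual_resection <- function(results, fun = c("mean", "min")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") mean else min
  list(n_postop = f(vapply(results, `[[`, numeric(1), "n_postop")),
       relative_reduction =
         f(vapply(results, `[[`, numeric(1), "relative_reduction")))
}

#' Load a resection scenario
#'
#' Reads a CSV `(region_id, resected_fraction)` and applies the
#' above-50% (strict) extent cut to define the resected set.
#'
#' @param path CSV path.
#' @param engel optional Engel class (`"I"`..`"IV"`).
#' @return List with `resected` (region ids) and `engel`.
#' @export
read_resection <- function(path, engel = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region_id", "resected_fraction") %in% names(df)))
  list(resected = df$region_id[df$resected_fraction > 0.5], engel = engel)
}

#' Permutation feature importance
#'
#' Model-agnostic importance behind a fit/predict/score contract: for each
#' feature, its column is permuted `K` times, the model is re-scored on
#' the corrupted data, and the importance is the drop of the average
#' permuted score below the intact score, `i_j = s - mean_k s_kj`. The
#' regressor is a pluggable black box: any fitted object with a `predict`
#' method (or an explicit `predict_fun`) works.
#'
#' @param model fitted regressor.
#' @param X data frame of features.
#' @param y numeric target.
#' @param K number of permutations per feature.
#' @param seed integer seed.
#' @param score_fun `function(y, yhat)`; default R^2.
#' @param predict_fun `function(model, newdata)`; default calls
#'   `predict()` (with `ranger`-style `$predictions` unwrapping).
#' @return Named vector of importances, one per feature.
#' @export
permutation_feature_importance <- function(model, X, y, K = 30, seed = 1,
                                           score_fun = NULL,
                                           predict_fun = NULL) {
  stopifnot(is.data.frame(X), nrow(X) == length(y), K >= 1)
  if (is.null(score_fun))
    score_fun <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  if (is.null(predict_fun))
    predict_fun <- function(m, nd) {
      p <- stats::predict(m, nd)
      if (is.list(p) && !is.null(p$predictions)) p$predictions else
        as.numeric(p)
    }
  set.seed(seed)
  s0 <- score_fun(y, predict_fun(model, X))
  imp <- vapply(names(X), function(j) {
    sk <- vapply(seq_len(K), function(k) {
      Xp <- X
      Xp[[j]] <- Xp[[j]][sample.int(nrow(X))]
      score_fun(y, predict_fun(model, Xp))
    }, numeric(1))
    s0 - mean(sk)
  }, numeric(1))
  imp
}
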