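# internal: integer status coding shared with the C++ side
status_code <- function(obs) {
  unname(c(hidden = 0L, seizing = 1L, `non-seizing` = 2L)[obs$status])
}

tobs_vector <- function(obs) {
  t <- obs$onset_s
  t[!is.finite(t) | is.na(t)] <- 0  # unused entries
  t[obs$status == "seizing"] <- obs$onset_s[obs$status == "seizing"]
  as.double(t)
}

#' Single-seizure log posterior
#'
#' The unnormalized log posterior density of the excitabilities `c` given
#' one partially observed seizure and fixed excitation parameters `q`:
#' a standard-normal prior on every `c_i`, plus, with simulated onsets
#' `t = P_{W,q}(c)` capped at `t_lim`, a Gaussian observation term
#' `N(t_obs_i | min(t_i, t_lim), sigma_t)` for every observed seizing
#' region and `N(t_lim | min(t_i, t_lim), sigma_t)` for every observed
#' non-seizing region (a one-sided soft penalty pushing the simulated
#' onset past the limit). Hidden regions contribute no likelihood term.
#'
#' @param c numeric vector of excitabilities.
#' @param obs a [seizure_observation()].
#' @param W a [connectome()].
#' @param q an [excitation_params()] object.
#' @param constants [model_constants()] (uses `sigma_t`, `t_lim`).
#' @param gradient if `TRUE`, return `list(lp, grad_c, grad_q)` with the
#'   analytic gradient (the `min(t, t_lim)` kink uses the flat, capped
#'   subgradient).
#' @return The log posterior value, or a list when `gradient = TRUE`.
#'   Non-finite `c` gives `-Inf`.
#' @export
log_posterior_single <- function(c, obs, W, q, constants = model_constants(),
                                 gradient = FALSE) {
  stopifnot(inherits(obs, "seizure_observation"), is_connectome(W))
  if (any(!is.finite(c))) return(if (gradient) list(lp = -Inf) else -Inf)
  r <- lp_single_cpp(unclass(W), q_anchors(q), as.double(c),
                     status_code(obs), tobs_vector(obs),
                     constants$sigma_t, constants$t_lim, gradient)
  if (!gradient) return(r$lp)
  r
}

#' Hierarchical multi-seizure log posterior
#'
#' The joint unnormalized log posterior of the excitation hyperparameters
#' `q` and the per-seizure excitability vectors `c_k`. Hyperpriors:
#' `q_aa, q_ab ~ Normal(0, sigma_q)` and the monotonicity increments
#' `q_ba*, q_bb* ~ HalfNormal(sigma_q)`. Each seizure contributes its own
#' standard-normal prior on `c_k` (counted once) and its observation
#' terms as in [log_posterior_single()].
#'
#' @param q an [excitation_params()] object (`q_ba_star < 0` or
#'   `q_bb_star < 0` gives `-Inf`).
#' @param c_list list of excitability vectors, one per seizure.
#' @param data list of seizures, each a list with elements `obs`
#'   (a [seizure_observation()]) and `W` (a [connectome()]).
#' @param constants [model_constants()] (uses `sigma_t`, `sigma_q`,
#'   `t_lim`).
#' @return The log posterior value.
#' @export
log_posterior_multi <- function(q, c_list, data,
                                constants = model_constants()) {
  stopifnot(length(c_list) == length(data))
  qv <- if (inherits(q, "excitation_params"))
    c(q$q_aa, q$q_ab, q$q_ba_star, q$q_bb_star) else q
  if (qv[3] < 0 || qv[4] < 0) return(-Inf)
  sq <- constants$sigma_q
  lp <- sum(stats::dnorm(qv[1:2], 0, sq, log = TRUE)) +
    sum(stats::dnorm(qv[3:4], 0, sq, log = TRUE) + log(2))
  for (k in seq_along(data)) {
    lp <- lp + log_posterior_single(c_list[[k]], data[[k]]$obs,
                                    data[[k]]$W, qv, constants)
  }
  lp
}
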