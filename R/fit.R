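#' Fit the single-seizure model
#'
#' Samples the posterior of the region excitabilities `c` for one
#' partially observed seizure with the excitation parameters `q` held
#' fixed, targeting [log_posterior_single()]. The default sampler is the
#' built-in No-U-Turn sampler over the analytic gradient supplied by the
#' forward sensitivities of the event-driven solver; `method = "rwm"`
#' switches to an adaptive gradient-free random-walk Metropolis fallback
#' suitable for tiny networks. Chains are initialized with independent
#' draws from the standard-normal prior.
#'
#' @param obs a [seizure_observation()].
#' @param W a [connectome()].
#' @param q an [excitation_params()] object (typically the posterior-mean
#'   point estimate from a [fit_cohort()] on other patients' data).
#' @param chains,warmup,draws MCMC layout (defaults 2 chains, 500 warmup,
#'   500 kept draws).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param method `"nuts"` (default) or `"rwm"`.
#' @param adapt_delta target acceptance statistic of the step-size
#'   adaptation.
#' @param max_treedepth maximum doublings of one NUTS trajectory.
#' @param constants [model_constants()].
#' @return Object of class `"seizure_fit"` with components `draws`
#'   (iterations x chains x regions array of `c` draws), `lp`, the inputs,
#'   and `diagnostics` (split R-hat, ESS, stuck-chain flags).
#' @seealso [fit_cohort()], [recruitment_probability()],
#'   [high_excitability_probability()]
#' @export
fit_seizure <- function(obs, W, q, chains = 2, warmup = 500, draws = 500,
                        seed = 1, method = c("nuts", "rwm"),
                        adapt_delta = 0.8, max_treedepth = 10,
                        constants = model_constants()) {
  stopifnot(inherits(obs, "seizure_observation"), is_connectome(W),
            chains >= 1)
  method <- match.arg(method)
  n <- nrow(W)
  q4 <- q_anchors(q)
  status <- status_code(obs)
  tobs <- tobs_vector(obs)
  lg <- function(theta) {
    r <- lp_single_cpp(unclass(W), q4, theta, status, tobs,
                       constants$sigma_t, constants$t_lim, TRUE)
    list(lp = r$lp, grad = r$grad_c)
  }
  arr <- array(NA_real_, c(draws, chains, n),
               dimnames = list(NULL, NULL, paste0("c_", region_ids(W))))
  lpm <- matrix(NA_real_, draws, chains)
  divergences <- integer(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed * 1000L + ch)
    init <- stats::rnorm(n)
    res <- if (method == "nuts") {
      nuts_sample(lg, init, warmup = warmup, draws = draws,
                  adapt_delta = adapt_delta, max_treedepth = max_treedepth)
    } else {
      rwm_sample(lg, init, warmup = warmup, draws = draws)
    }
    arr[, ch, ] <- res$draws
    lpm[, ch] <- res$lp
    divergences[ch] <- res$divergences
  }
  diag <- if (chains >= 2) mcmc_diagnostics(arr, lpm) else
    list(rhat = rep(NA_real_, n), n_eff = rep(NA_real_, n),
         stuck = apply(lpm, 2, stats::var) < 1e-8, all_stuck = FALSE)
  structure(list(draws = arr, lp = lpm, obs = obs, W = W, q = q,
                 constants = constants, method = method, seed = seed,
                 divergences = divergences, diagnostics = diag),
            class = "seizure_fit")
}

# adaptive random-walk Metropolis (gradient-free fallback): Gaussian
# proposals with Robbins-Monro scale adaptation toward 23% acceptance
rwm_sample <- function(lp_grad, init, warmup = 500, draws = 500,
                       target_accept = 0.23) {
  d <- length(init)
  theta <- init
  lp <- lp_grad(theta)$lp
  scale <- 0.3 / sqrt(d)
  out <- matrix(NA_real_, draws, d)
  lp_out <- numeric(draws)
  n_acc <- 0L
  for (it in seq_len(warmup + draws)) {
    prop <- theta + stats::rnorm(d, 0, scale)
    lp_p <- lp_grad(prop)$lp
    if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
      theta <- prop; lp <- lp_p; n_acc <- n_acc + 1L
      acc <- 1
    } else acc <- 0
    if (it <= warmup) scale <- scale * exp((acc - target_accept) / sqrt(it))
    else {
      out[it - warmup, ] <- theta
      lp_out[it - warmup] <- lp
    }
  }
  list(draws = out, lp = lp_out, divergences = 0L,
       accept_rate = n_acc / (warmup + draws))
}

#' Fit the hierarchical multi-seizure model
#'
#' Samples the joint posterior of the excitation hyperparameters `q` and
#' the per-seizure excitabilities `c_k` over a cohort of seizures,
#' targeting [log_posterior_multi()]. Sampling runs on the unconstrained
#' scale (`log` transform of the nonnegative increments `q_ba*`, `q_bb*`,
#' with the Jacobian included). The point estimate of `q` is the
#' componentwise posterior mean, available via `coef()`.
#'
#' @param data list of seizures, each a list with elements `obs`
#'   (a [seizure_observation()]) and `W` (a [connectome()]); at most two
#'   seizures per patient should enter a training cohort.
#' @param chains,warmup,draws MCMC layout (defaults 4 chains, 500 + 500).
#' @param seed integer seed.
#' @param adapt_delta target acceptance statistic of the step-size
#'   adaptation.
#' @param max_treedepth maximum doublings of one NUTS trajectory
#'   (default 8 for the joint fit, bounding the cost of one iteration).
#' @param constants [model_constants()].
#' @return Object of class `"cohort_fit"` with `q_draws` (iterations x
#'   chains x 4, free parameterization `q_aa, q_ab, q_ba_star, q_bb_star`),
#'   `c_draws` (per-seizure list of arrays), `lp`, and `diagnostics`.
#' @export
fit_cohort <- function(data, chains = 4, warmup = 500, draws = 500,
                       seed = 1, adapt_delta = 0.8, max_treedepth = 8,
                       constants = model_constants()) {
  stopifnot(length(data) >= 1)
  packed <- lapply(data, function(d) {
    stopifnot(inherits(d$obs, "seizure_observation"), is_connectome(d$W))
    list(W = unclass(d$W), status = status_code(d$obs),
         tobs = tobs_vector(d$obs))
  })
  sizes <- vapply(packed, function(p) nrow(p$W), integer(1))
  dtot <- 4L + sum(sizes)
  lg <- function(theta) {
    r <- lp_multi_cpp(theta, packed, constants$sigma_t, constants$t_lim,
                      constants$sigma_q, TRUE)
    list(lp = r$lp, grad = r$grad)
  }
  qarr <- array(NA_real_, c(draws, chains, 4),
                dimnames = list(NULL, NULL,
                                c("q_aa", "q_ab", "q_ba_star", "q_bb_star")))
  carr <- lapply(sizes, function(n) array(NA_real_, c(draws, chains, n)))
  lpm <- matrix(NA_real_, draws, chains)
  divergences <- integer(chains)
  for (ch in seq_len(chains)) {
    set.seed(seed * 1000L + ch)
    # random initialization with anchor log-rates near 1/t_lim, so the
    # initial simulated onsets fall on the observation time scale rather
    # than in the zero-gradient plateau beyond t_lim
    init <- c(stats::rnorm(1, log(2 / constants$t_lim), 0.5),
              stats::rnorm(1, log(20 / constants$t_lim), 0.5),
              stats::rnorm(2, 0, 0.5),
              stats::rnorm(sum(sizes)))
    res <- nuts_sample(lg, init, warmup = warmup, draws = draws,
                       adapt_delta = adapt_delta,
                       max_treedepth = max_treedepth, dense_block = 4L)
    th <- res$draws
    qarr[, ch, 1] <- th[, 1]
    qarr[, ch, 2] <- th[, 2]
    qarr[, ch, 3] <- exp(th[, 3])
    qarr[, ch, 4] <- exp(th[, 4])
    off <- 4L
    for (k in seq_along(sizes)) {
      carr[[k]][, ch, ] <- th[, off + seq_len(sizes[k]), drop = FALSE]
      off <- off + sizes[k]
    }
    lpm[, ch] <- res$lp
    divergences[ch] <- res$divergences
  }
  full <- array(NA_real_, c(draws, chains, dtot))
  full[, , 1:4] <- qarr
  off <- 4L
  for (k in seq_along(sizes)) {
    full[, , off + seq_len(sizes[k])] <- carr[[k]]
    off <- off + sizes[k]
  }
  dimnames(full) <- list(NULL, NULL, c(
    dimnames(qarr)[[3]],
    unlist(lapply(seq_along(data), function(k)
      paste0("c", k, "_", data[[k]]$obs$region_ids)))))
  diag <- if (chains >= 2) mcmc_diagnostics(full, lpm) else
    list(rhat = NULL, n_eff = NULL,
         stuck = apply(lpm, 2, stats::var) < 1e-8, all_stuck = FALSE)
  structure(list(q_draws = qarr, c_draws = carr, draws = full, lp = lpm,
                 data = data, constants = constants, seed = seed,
                 divergences = divergences, diagnostics = diag),
            class = "cohort_fit")
}

# ---- methods: seizure_fit ----

# draws as a flat matrix, S x n, restricted to the given chains
draw_matrix <- function(arr, chains = NULL) {
  d <- dim(arr)
  if (is.null(chains)) chains <- seq_len(d[2])
  arr <- arr[, chains, , drop = FALSE]
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  colnames(m) <- dimnames(arr)[[3]]
  m
}

# chains retained for posterior summaries: the non-stuck ones (all
# chains if every chain is flagged — such fits are excluded downstream)
good_chains <- function(fit) {
  stuck <- fit$diagnostics$stuck
  if (is.null(stuck) || all(stuck)) seq_len(dim(fit$lp)[2]) else
    which(!stuck)
}

#' @export
print.seizure_fit <- function(x, ...) {
  cat(sprintf("Single-seizure fit (%s): %d regions, %d chains x %d draws\n",
              x$method, dim(x$draws)[3], dim(x$draws)[2], dim(x$draws)[1]))
  if (!is.null(x$diagnostics$rhat) && !all(is.na(x$diagnostics$rhat)))
    cat(sprintf("  max R-hat %.3f, min N_eff %.0f, stuck chains %d/%d\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$n_eff, na.rm = TRUE),
                sum(x$diagnostics$stuck), length(x$diagnostics$stuck)))
  invisible(x)
}

#' @export
coef.seizure_fit <- function(object, ...) {
  m <- draw_matrix(object$draws, good_chains(object))
  stats::setNames(colMeans(m), region_ids(object$W))
}

#' @export
summary.seizure_fit <- function(object, ...) {
  m <- draw_matrix(object$draws, good_chains(object))
  data.frame(
    region_id = region_ids(object$W),
    status = object$obs$status,
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    rhat = object$diagnostics$rhat,
    n_eff = object$diagnostics$n_eff,
    p_high = colMeans(m > object$constants$c_h),
    row.names = NULL)
}

#' Posterior predictions from a fitted seizure model
#'
#' `type = "onsets"` simulates the onset times for every posterior draw
#' (a draws x regions matrix); `type = "recruitment"` turns them into
#' recruitment probabilities `r_i(t) = p(t_i <= t)` on a time grid.
#'
#' @param object a `"seizure_fit"`.
#' @param type what to predict.
#' @param times time grid (s) for `type = "recruitment"`.
#' @param t_max simulation horizon for the per-draw simulations; onsets
#'   beyond it are `Inf`.
#' @param ... unused.
#' @export
predict.seizure_fit <- function(object, type = c("onsets", "recruitment"),
                                times = seq(0, object$constants$t_lim,
                                            by = 1),
                                t_max = 4 * object$constants$t_lim, ...) {
  type <- match.arg(type)
  tmat <- sim_onsets_many_cpp(unclass(object$W), q_anchors(object$q),
                              draw_matrix(object$draws, good_chains(object)), t_max)
  colnames(tmat) <- region_ids(object$W)
  if (type == "onsets") return(tmat)
  recruitment_probability(tmat, times)
}

#' @export
residuals.seizure_fit <- function(object, ...) {
  tmat <- predict(object, "onsets")
  tl <- object$constants$t_lim
  m <- colMeans(pmin(tmat, tl))
  sz <- object$obs$status == "seizing"
  stats::setNames(object$obs$onset_s[sz] - m[sz],
                  object$obs$region_ids[sz])
}

#' Posterior predictive observations
#'
#' Draws replicated noisy observations: for `nsim` posterior draws of `c`
#' the onsets are re-simulated and Gaussian observation noise `sigma_t` is
#' added to the capped onset times.
#'
#' @param object a `"seizure_fit"`.
#' @param nsim number of replicated observation vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return `nsim` x regions matrix of replicated observed onset times.
#' @export
simulate.seizure_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tmat <- predict(object, "onsets")
  idx <- sample.int(nrow(tmat), nsim, replace = nsim > nrow(tmat))
  tl <- object$constants$t_lim
  capped <- pmin(tmat[idx, , drop = FALSE], tl)
  capped + matrix(stats::rnorm(length(capped), 0, object$constants$sigma_t),
                  nrow(capped))
}

#' @export
plot.seizure_fit <- function(x, times = seq(0, x$constants$t_lim, by = 1),
                             ...) {
  r <- predict(x, "recruitment", times = times)
  graphics::image(times, seq_len(ncol(r)), r,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (s)", ylab = "region",
                  main = "posterior recruitment probability", ...)
  invisible(r)
}

# ---- methods: cohort_fit ----

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf(
    "Multi-seizure fit: %d seizures, %d chains x %d draws\n",
    length(x$data), dim(x$q_draws)[2], dim(x$q_draws)[1]))
  qm <- coef(x)
  cat(sprintf(
    "  q point estimate: q_aa=%.3f q_ab=%.3f q_ba*=%.3f q_bb*=%.3f\n",
    qm[1], qm[2], qm[3], qm[4]))
  invisible(x)
}

#' @export
coef.cohort_fit <- function(object, ...) {
  m <- draw_matrix(object$q_draws, good_chains(object))
  colMeans(m)
}

#' Point estimate of the excitation parameters
#'
#' The componentwise posterior mean of `q`, as an [excitation_params()]
#' object ready for single-seizure fitting.
#'
#' @param fit a `"cohort_fit"`.
#' @export
point_estimate_q <- function(fit) {
  qm <- coef(fit)
  excitation_params(qm[["q_aa"]], qm[["q_ab"]],
                    qm[["q_ba_star"]], qm[["q_bb_star"]])
}

#' @export
summary.cohort_fit <- function(object, probs = c(0.05, 0.5, 0.95), ...) {
  m <- draw_matrix(object$q_draws, good_chains(object))
  qs <- t(apply(m, 2, stats::quantile, probs = probs))
  data.frame(parameter = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd), qs,
             rhat = object$diagnostics$rhat[1:4],
             n_eff = object$diagnostics$n_eff[1:4],
             row.names = NULL, check.names = FALSE)
}

#' @export
plot.cohort_fit <- function(x, ...) {
  m <- draw_matrix(x$q_draws, good_chains(x))
  graphics::par(mfrow = c(2, 2))
  for (j in 1:4) {
    d <- stats::density(m[, j])
    graphics::plot(d, main = colnames(m)[j], xlab = "", ...)
  }
  invisible(x)
}
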