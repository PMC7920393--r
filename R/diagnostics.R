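# MCMC convergence diagnostics: split-chain potential scale reduction
# factor and effective sample size, per Gelman et al. (BDA3, ch. 11).

split_chain_matrix <- function(m) {
  # m: iterations x chains -> iterations/2 x (2*chains)
  n <- nrow(m) %/% 2L
  do.call(cbind, lapply(seq_len(ncol(m)), function(j)
    cbind(m[seq_len(n), j], m[n + seq_len(n), j])))
}

#' Split-chain R-hat
#'
#' @param m matrix of draws, iterations x chains (at least 2 chains).
#' @return The split-chain potential scale reduction factor (NaN when the
#'   chains have zero variance).
#' @export
split_rhat <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("R-hat requires at least 2 chains")
  s <- split_chain_matrix(m)
  n <- nrow(s)
  W <- mean(apply(s, 2, stats::var))
  B <- n * stats::var(colMeans(s))
  var_hat <- (n - 1) / n * W + B / n
  sqrt(var_hat / W)
}

#' Effective sample size (split chains, Geyer initial positive sequence)
#'
#' @inheritParams split_rhat
#' @return Estimated number of effectively independent draws, capped at
#'   the total draw count.
#' @export
ess <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("ESS requires at least 2 chains")
  s <- split_chain_matrix(m)
  n <- nrow(s); nc <- ncol(s)
  W <- mean(apply(s, 2, stats::var))
  B <- n * stats::var(colMeans(s))
  var_hat <- (n - 1) / n * W + B / n
  if (!is.finite(var_hat) || var_hat <= 0) return(NaN)
  # per-chain autocovariances (biased, via acf)
  acov <- sapply(seq_len(nc), function(j)
    stats::acf(s[, j], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)) / var_hat
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive
  tau <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + pair
    t <- t + 2
  }
  tau <- max(tau, rho[1])
  min(nc * n, nc * n / (2 * tau - 1))
}

#' Convergence diagnostics for a set of chains
#'
#' Computes split-chain R-hat and effective sample size per parameter and
#' flags stuck chains: a chain whose within-chain variance of the log
#' posterior falls below `stuck_tol` has effectively stopped moving.
#' Fits in which *all* chains are stuck are unusable and should be
#' excluded downstream.
#'
#' @param draws array of draws, iterations x chains x parameters.
#' @param lp matrix of log-posterior values, iterations x chains.
#' @param stuck_tol variance threshold below which a chain counts as
#'   stuck.
#' @param lp_gap a chain whose mean log posterior lies more than this
#'   far below the best chain's is also flagged (trapped in a
#'   low-probability region, e.g. the flat no-seizing plateau).
#' @return List with `rhat` and `n_eff` (per parameter), `stuck`
#'   (per-chain logical), and `all_stuck`.
#' @export
mcmc_diagnostics <- function(draws, lp, stuck_tol = 1e-8, lp_gap = 50) {
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("diagnostics require at least 2 chains")
  P <- dim(draws)[3]
  rhat <- vapply(seq_len(P), function(p) split_rhat(draws[, , p]),
                 numeric(1))
  n_eff <- vapply(seq_len(P), function(p) ess(draws[, , p]), numeric(1))
  pn <- dimnames(draws)[[3]]
  if (!is.null(pn)) { names(rhat) <- pn; names(n_eff) <- pn }
  lp <- as.matrix(lp)
  stuck <- apply(lp, 2, stats::var) < stuck_tol
  mean_lp <- colMeans(lp)
  stuck <- stuck | (mean_lp < max(mean_lp) - lp_gap)
  list(rhat = rhat, n_eff = n_eff, stuck = stuck,
       all_stuck = all(stuck))
}
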