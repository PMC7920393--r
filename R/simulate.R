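#' Simulate region onset times (exact event-driven solver)
#'
#' Solves the threshold dynamics
#' `z_i' = f_q(c_i, sum_j w_ij H(z_j - 1))`, `z_i(0) = 0`, exactly: between
#' threshold crossings every slow variable grows linearly, so the next
#' onset is `min_i (1 - z_i) / slope_i` and the trajectory is advanced
#' event by event. A region's onset time is the first time its slow
#' variable reaches 1 (the region counts as seizing from that instant on).
#' Regions reaching the threshold at the same event time are switched in
#' one batch. Because `f_q > 0`, every onset is finite when `t_max = Inf`;
#' with a finite horizon, regions still below threshold at `t_max` are
#' returned as `Inf`.
#'
#' @param W a [connectome()] (normalized: max ingoing weight sum at most 1).
#' @param q an [excitation_params()] object.
#' @param c numeric vector of region excitabilities.
#' @param t_max simulation horizon in seconds (default `Inf`).
#' @param gradient if `TRUE`, also return the Jacobians of the onset times
#'   with respect to `c` (`dt_dc`, n x n) and the four anchor values of `q`
#'   (`dt_dq`, n x 4), computed by forward sensitivity propagation along
#'   the event sequence.
#' @return A named numeric vector of onset times (seconds, `Inf` for
#'   regions unseized at `t_max`); with `gradient = TRUE`, a list with
#'   elements `t`, `dt_dc`, `dt_dq`.
#' @seealso [simulate_dense()] for the brute-force integrator,
#'   [invert_excitabilities()] for the noiseless inverse.
#' @export
simulate_onsets <- function(W, q, c, t_max = Inf, gradient = FALSE) {
  stopifnot(is_connectome(W))
  if (!all(is.finite(c))) stop("excitabilities must be finite")
  r <- sim_onsets_cpp(unclass(W), q_anchors(q), as.double(c), t_max,
                      gradient)
  t <- stats::setNames(r$t, region_ids(W))
  if (!gradient) return(t)
  list(t = t, dt_dc = r$dt_dc, dt_dq = r$dt_dq)
}

#' Brute-force fixed-step integrator (oracle for the event-driven solver)
#'
#' Explicit Euler integration of the same threshold dynamics with the
#' Heaviside input evaluated at the left endpoint of each step. The onset
#' of a region is the first grid time at which its slow variable reaches 1.
#' Converges to [simulate_onsets()] as `dt -> 0`; kept deliberately
#' independent of the event-driven code path so the two can check each
#' other.
#'
#' @inheritParams simulate_onsets
#' @param dt integration step in seconds.
#' @return Named numeric vector of onset times (grid times; `Inf` for
#'   regions unseized at `t_max`).
#' @export
simulate_dense <- function(W, q, c, dt = 1e-3, t_max = 200) {
  stopifnot(is_connectome(W), dt > 0, is.finite(t_max))
  if (!all(is.finite(c))) stop("excitabilities must be finite")
  n <- nrow(W)
  Wm <- unclass(W)
  z <- numeric(n)
  seized <- rep(FALSE, n)
  onset <- rep(Inf, n)
  t <- 0
  while (t < t_max && !all(seized)) {
    y <- as.vector(Wm %*% as.numeric(seized))
    y <- pmin(y, 1)
    rate <- excitation_rate(q, c, y)
    z <- z + rate * dt
    t <- t + dt
    crossed <- !seized & z >= 1
    onset[crossed] <- t
    seized <- seized | crossed
  }
  stats::setNames(onset, region_ids(W))
}

#' Classify regions as seizing or non-seizing
#'
#' A region counts as seizing when its onset time is strictly below the
#' seizure time limit `t_lim`; onsets at or after `t_lim` (including the
#' `Inf` sentinel) are associated with the non-seizing state.
#'
#' @param t numeric vector of onset times (seconds, `Inf` allowed).
#' @param t_lim seizure time limit in seconds.
#' @return Factor with levels `"seizing"`, `"non-seizing"`.
#' @export
classify_states <- function(t, t_lim = 90) {
  stopifnot(is.numeric(t), t_lim > 0)
  factor(ifelse(t < t_lim, "seizing", "non-seizing"),
         levels = c("seizing", "non-seizing"))
}

#' Exact excitability inversion from complete, noiseless onset times
#'
#' For a fully observed, fully seizing network without observation noise,
#' each region's excitability is identified uniquely by its onset time:
#' the accumulated growth `sum_k f_q(c_i, y_i^(k)) * dt_k = 1` over the
#' constant-input intervals before `t_i` is continuous and strictly
#' increasing in `c_i` with range `(0, Inf)` (provided `f_q` is strictly
#' increasing in `c` over at least one interval), so a unique root exists.
#' The root is found by bisection after geometric expansion of the bracket
#' `[-50, 50]`, to an absolute tolerance of 1e-10.
#'
#' @param W a [connectome()].
#' @param q an [excitation_params()] object.
#' @param t complete vector of finite, positive onset times (seconds).
#' @return Numeric vector of excitabilities such that
#'   `simulate_onsets(W, q, c)` reproduces `t` to solver tolerance.
#' @export
invert_excitabilities <- function(W, q, t) {
  stopifnot(is_connectome(W))
  n <- nrow(W)
  if (length(t) != n) stop("length(t) must match the connectome size")
  if (any(!is.finite(t)))
    stop("exact inversion requires all onset times finite ",
         "(fully seizing, fully observed network)")
  if (any(t <= 0)) stop("onset times must be positive")
  Wm <- unclass(W)
  q4 <- q_anchors(q)
  # event times in increasing order define the piecewise-constant input
  events <- sort(unique(t))
  c_rec <- numeric(n)
  for (i in seq_len(n)) {
    # constant-input intervals [tau_k, tau_{k+1}) before t_i
    taus <- c(0, events[events < t[i]], t[i])
    taus <- unique(taus)
    dts <- diff(taus)
    ys <- vapply(taus[-length(taus)], function(tau) {
      min(1, sum(Wm[i, t <= tau + 1e-12]))
    }, numeric(1))
    # accumulated growth must equal 1 at the onset:
    # g(c) = sum_k exp(alpha_k + beta_k c) dt_k, beta_k >= 0
    ab <- vapply(ys, function(y) {
      alpha <- 0.5 * ((q4[1] + q4[3]) * (1 - y) + (q4[2] + q4[4]) * y)
      beta <- 0.5 * ((q4[3] - q4[1]) * (1 - y) + (q4[4] - q4[2]) * y)
      c(alpha, beta)
    }, numeric(2))
    g <- function(cc) sum(exp(ab[1, ] + ab[2, ] * cc) * dts) - 1
    if (all(ab[2, ] * dts < 1e-14)) {
      if (abs(g(0)) < 1e-8) {
        stop("excitability not identifiable: f_q does not depend on c ",
             "for region ", region_ids(W)[i])
      } else {
        stop("no solution: f_q does not depend on c for region ",
             region_ids(W)[i], " and the onset time is inconsistent")
      }
    }
    c_rec[i] <- bisect_increasing(g, -50, 50, tol = 1e-10)
  }
  stats::setNames(c_rec, region_ids(W))
}

# root of a continuous increasing function by bisection, with geometric
# expansion of the initial bracket until the root is enclosed
bisect_increasing <- function(g, lo, hi, tol = 1e-10, max_expand = 60) {
  glo <- g(lo); ghi <- g(hi)
  k <- 0
  while (glo > 0 && k < max_expand) { lo <- lo * 2; glo <- g(lo); k <- k + 1 }
  while (ghi < 0 && k < max_expand) { hi <- hi * 2; ghi <- g(hi); k <- k + 1 }
  if (glo > 0 || ghi < 0) stop("failed to bracket the root")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Onset-time I/O
#'
#' Two-column CSV `(region_id, onset_s)`; non-seizing regions are stored
#' with the string `"inf"`.
#'
#' @param t named numeric vector of onset times (`Inf` allowed).
#' @param path file path.
#' @return `read_onsets()` returns a named numeric vector;
#'   `write_onsets()` returns `path` invisibly.
#' @export
write_onsets <- function(t, path) {
  df <- data.frame(region_id = names(t),
                   onset_s = ifelse(is.finite(t), format(t, digits = 17),
                                    "inf"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_onsets
#' @export
read_onsets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- suppressWarnings(as.numeric(df$onset_s))
  v[tolower(trimws(df$onset_s)) %in% c("inf", "+inf", "infinity")] <- Inf
  if (any(is.na(v))) stop("unparseable onset time in ", path)
  stats::setNames(v, df$region_id)
}
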