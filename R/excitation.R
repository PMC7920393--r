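#' Excitation-function parameters
#'
#' Constructs the parameter vector of the excitation function `f_q(c, y)`,
#' the positive rate (1/s) at which a region's slow variable grows given its
#' excitability `c` and the summed weight `y` of its currently seizing
#' afferents. `f_q` is a bilinear interpolant in `(c, y)` through four anchor
#' values, followed by exponentiation. The anchors sit at `c = -1, 1` and
#' `y = 0, 1`; the values at the high-excitability anchors are declared as
#' `q_ba = q_aa + q_ba_star` and `q_bb = q_ab + q_bb_star` with
#' `q_ba_star, q_bb_star >= 0`, which guarantees that `f_q` is nondecreasing
#' in `c` (strictly increasing when either star component is positive).
#'
#' @param q_aa value of the log-rate at `(c, y) = (-1, 0)`.
#' @param q_ab value of the log-rate at `(c, y) = (-1, 1)`.
#' @param q_ba_star nonnegative increment so that the log-rate at `(1, 0)`
#'   is `q_aa + q_ba_star`.
#' @param q_bb_star nonnegative increment so that the log-rate at `(1, 1)`
#'   is `q_ab + q_bb_star`.
#' @return An object of class `"excitation_params"`: a named list with the
#'   four free parameters and the derived anchor values `q_ba`, `q_bb`.
#' @seealso [excitation_rate()], [simulate_onsets()]
#' @export
excitation_params <- function(q_aa, q_ab, q_ba_star, q_bb_star) {
  stopifnot(is.numeric(q_aa), is.numeric(q_ab),
            is.numeric(q_ba_star), is.numeric(q_bb_star),
            length(q_aa) == 1L, length(q_ab) == 1L,
            length(q_ba_star) == 1L, length(q_bb_star) == 1L,
            is.finite(c(q_aa, q_ab, q_ba_star, q_bb_star)))
  if (q_ba_star < 0 || q_bb_star < 0)
    stop("q_ba_star and q_bb_star must be nonnegative")
  structure(list(q_aa = q_aa, q_ab = q_ab,
                 q_ba_star = q_ba_star, q_bb_star = q_bb_star,
                 q_ba = q_aa + q_ba_star, q_bb = q_ab + q_bb_star),
            class = "excitation_params")
}

#' @export
print.excitation_params <- function(x, ...) {
  cat("Excitation parameters (bilinear-exponential rate):\n")
  cat(sprintf("  q_aa = %g, q_ab = %g, q_ba* = %g, q_bb* = %g\n",
              x$q_aa, x$q_ab, x$q_ba_star, x$q_bb_star))
  cat(sprintf("  anchors: q_ba = %g, q_bb = %g\n", x$q_ba, x$q_bb))
  invisible(x)
}

# internal: anchor vector (q_aa, q_ab, q_ba, q_bb) from an
# excitation_params object or a length-4 numeric in the free
# parameterization (q_aa, q_ab, q_ba*, q_bb*)
q_anchors <- function(q) {
  if (inherits(q, "excitation_params"))
    return(c(q$q_aa, q$q_ab, q$q_ba, q$q_bb))
  stopifnot(is.numeric(q), length(q) == 4L, all(is.finite(q)))
  if (q[3] < 0 || q[4] < 0)
    stop("q_ba_star and q_bb_star must be nonnegative")
  c(q[1], q[2], q[1] + q[3], q[2] + q[4])
}

#' Evaluate the excitation rate
#'
#' Computes `f_q(c, y) = exp(fhat_q(c, y))` where `fhat_q` is the bilinear
#' interpolant through the four anchors of `q`. Values of `c` outside
#' `[-1, 1]` are extrapolated with the same bilinear (linear in `c`) form;
#' standard-normal excitabilities routinely exceed the anchors and the
#' formula is algebraically valid there. `y` must lie in `[0, 1]`, which a
#' normalized connectome guarantees.
#'
#' @param q an [excitation_params()] object (or length-4 numeric
#'   `(q_aa, q_ab, q_ba_star, q_bb_star)`).
#' @param c excitability value(s).
#' @param y weighted seizing input in `[0, 1]`, recycled against `c`.
#' @return Positive rate(s), 1/s.
#' @export
excitation_rate <- function(q, c, y) {
  stopifnot(is.numeric(c), is.numeric(y), all(is.finite(c)), all(is.finite(y)))
  if (any(y < 0 | y > 1))
    stop("y must lie in [0, 1] (connectome normalization guarantees this)")
  excitation_rate_cpp(q_anchors(q), as.double(c), as.double(y))
}

#' Model constants
#'
#' The fixed constants of the method, all in seconds where dimensional:
#' `t_lim` (seizure time limit; regions seizing later are treated as
#' non-seizing), `sigma_t` (onset observation noise SD), `sigma_q`
#' (hyperprior scale of the excitation parameters), `t1` (alignment time of
#' the first observed onset), `T` (temporal resolution of the onset
#' prediction accuracy), `c_h` (high-excitability threshold), and `delta`
#' (band-power detection threshold, a five-fold power change).
#'
#' @param t_lim,sigma_t,sigma_q,t1,T,c_h,delta override any default.
#' @return Named list of constants.
#' @export
model_constants <- function(t_lim = 90, sigma_t = 5, sigma_q = 30,
                            t1 = 30, T = 5, c_h = 2, delta = 5) {
  con <- list(t_lim = t_lim, sigma_t = sigma_t, sigma_q = sigma_q,
              t1 = t1, T = T, c_h = c_h, delta = delta)
  stopifnot(all(vapply(con, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))))
  con
}
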