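# No-U-Turn sampler (Hoffman & Gelman 2014, Alg. 6) with dual-averaging
# step-size adaptation and windowed mass-matrix estimation during warmup.
# The metric is diagonal, optionally with a dense block over the first
# `dense_block` coordinates (used for the excitation hyperparameters,
# whose posterior is strongly correlated, while the excitabilities get a
# diagonal metric). `lp_grad` must return list(lp, grad) and is the only
# model-specific ingredient; the onset-time log posteriors supply
# analytic gradients from the forward sensitivities of the event solver.

nuts_sample <- function(lp_grad, init, warmup = 500, draws = 500,
                        adapt_delta = 0.8, max_treedepth = 10,
                        dense_block = 0L) {
  d <- length(init)
  nb <- min(dense_block, d)
  # metric state: inv_diag = posterior-variance estimate (inverse mass);
  # for the dense block, inv_block = covariance, chol_mass = chol(inv cov)
  inv_diag <- rep(1, d)
  inv_block <- if (nb > 0) diag(nb) else NULL
  chol_mass <- if (nb > 0) diag(nb) else NULL

  velocity <- function(p) {
    v <- p * inv_diag
    if (nb > 0) v[1:nb] <- as.vector(inv_block %*% p[1:nb])
    v
  }
  kinetic <- function(p) {
    k <- sum(p^2 * inv_diag)
    if (nb > 0)
      k <- k - sum(p[1:nb]^2 * inv_diag[1:nb]) +
        sum(p[1:nb] * (inv_block %*% p[1:nb]))
    0.5 * k
  }
  sample_p <- function() {
    p <- stats::rnorm(d) / sqrt(inv_diag)
    if (nb > 0) p[1:nb] <- as.vector(crossprod(chol_mass, stats::rnorm(nb)))
    p
  }
  set_metric <- function(v, S) {
    v[!is.finite(v) | v <= 0] <- 1
    inv_diag <<- v
    if (nb > 0) {
      S <- (S + t(S)) / 2
      ok <- all(is.finite(S)) && all(diag(S) > 0)
      if (ok) {
        M <- tryCatch(solve(S), error = function(e) NULL)
        ch <- if (!is.null(M)) tryCatch(chol(M), error = function(e) NULL)
        if (!is.null(ch)) {
          inv_block <<- S
          chol_mass <<- ch
          return(invisible())
        }
      }
      inv_block <<- diag(v[1:nb], nb)
      chol_mass <<- diag(1 / sqrt(v[1:nb]), nb)
    }
  }

  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop("non-finite log posterior at initialization")

  leapfrog <- function(th, p, g, eps) {
    p <- p + 0.5 * eps * g
    th <- th + eps * velocity(p)
    new <- lp_grad(th)
    p <- p + 0.5 * eps * new$grad
    list(theta = th, p = p, lp = new$lp, grad = new$grad)
  }
  joint <- function(lp, p) lp - kinetic(p)

  find_eps <- function() {
    eps <- 0.1
    p0 <- sample_p()
    h0 <- joint(cur$lp, p0)
    st <- leapfrog(theta, p0, cur$grad, eps)
    h1 <- joint(st$lp, st$p)
    if (!is.finite(h1)) h1 <- -Inf
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    for (i in 1:50) {
      eps <- eps * 2^a
      st <- leapfrog(theta, p0, cur$grad, eps)
      h1 <- joint(st$lp, st$p)
      if (!is.finite(h1)) h1 <- -Inf
      if (a * (h1 - h0) <= a * log(0.5)) break
    }
    eps
  }

  n_div <- 0L
  DELTA_MAX <- 1000

  build_tree <- function(th, p, g, logu, v, j, eps, h0) {
    if (j == 0) {
      st <- leapfrog(th, p, g, v * eps)
      hj <- if (is.finite(st$lp)) joint(st$lp, st$p) else -Inf
      if (!is.finite(hj)) hj <- -Inf
      n1 <- as.integer(logu <= hj)
      div <- (hj - logu) < -DELTA_MAX
      if (div) n_div <<- n_div + 1L
      a <- min(1, exp(hj - h0))
      if (!is.finite(a)) a <- 0
      list(thm = st$theta, pm = st$p, gm = st$grad,
           thp = st$theta, pp = st$p, gp = st$grad,
           th1 = st$theta, lp1 = st$lp, n1 = n1, s1 = !div,
           alpha = a, nalpha = 1L)
    } else {
      t1 <- build_tree(th, p, g, logu, v, j - 1, eps, h0)
      if (!t1$s1) return(t1)
      if (v == -1) {
        t2 <- build_tree(t1$thm, t1$pm, t1$gm, logu, v, j - 1, eps, h0)
        t1$thm <- t2$thm; t1$pm <- t2$pm; t1$gm <- t2$gm
      } else {
        t2 <- build_tree(t1$thp, t1$pp, t1$gp, logu, v, j - 1, eps, h0)
        t1$thp <- t2$thp; t1$pp <- t2$pp; t1$gp <- t2$gp
      }
      ntot <- t1$n1 + t2$n1
      if (ntot > 0 && stats::runif(1) < t2$n1 / ntot) {
        t1$th1 <- t2$th1; t1$lp1 <- t2$lp1
      }
      dth <- t1$thp - t1$thm
      t1$s1 <- isTRUE(t2$s1 &&
        sum(dth * velocity(t1$pm)) >= 0 && sum(dth * velocity(t1$pp)) >= 0)
      t1$n1 <- ntot
      t1$alpha <- t1$alpha + t2$alpha
      t1$nalpha <- t1$nalpha + t2$nalpha
      t1
    }
  }

  # dual-averaging state
  eps <- find_eps()
  mu <- log(10 * eps)
  eps_bar <- 1; H_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  da_iter <- 0L
  da_update <- function(accept_prob) {
    da_iter <<- da_iter + 1L
    H_bar <<- (1 - 1 / (da_iter + t0)) * H_bar +
      (adapt_delta - accept_prob) / (da_iter + t0)
    log_eps <- mu - sqrt(da_iter) / gamma * H_bar
    eta <- da_iter^(-kappa)
    eps_bar <<- exp(eta * log_eps + (1 - eta) * log(eps_bar))
    eps <<- exp(log_eps)
  }

  total <- warmup + draws
  out <- matrix(NA_real_, draws, d)
  lp_out <- numeric(draws)
  depths <- integer(total)
  # warmup schedule: fast step-size interval, expanding metric windows
  # (each ending with a metric update and step-size restart), terminal
  # fast interval
  init_fast <- min(75L, max(1L, floor(warmup * 0.15)))
  term_fast <- min(50L, max(1L, floor(warmup * 0.1)))
  win_ends <- integer(0)
  if (warmup - init_fast - term_fast > 20L) {
    pos <- init_fast
    size <- 25L
    repeat {
      nxt <- pos + size
      if (nxt + 2L * size > warmup - term_fast) {
        win_ends <- c(win_ends, warmup - term_fast)
        break
      }
      win_ends <- c(win_ends, nxt)
      pos <- nxt
      size <- size * 2L
    }
  }
  win_buf <- NULL
  best_lp <- cur$lp
  best_theta <- theta

  for (it in seq_len(total)) {
    p0 <- sample_p()
    h0 <- joint(cur$lp, p0)
    logu <- h0 - stats::rexp(1)
    thm <- theta; thp <- theta; pm <- p0; pp <- p0
    gm <- cur$grad; gp <- cur$grad
    th_new <- theta; lp_new <- cur$lp
    n <- 1L; s <- TRUE; j <- 0L
    alpha_sum <- 0; nalpha_sum <- 0L
    while (s && j < max_treedepth) {
      v <- if (stats::runif(1) < 0.5) -1 else 1
      if (v == -1) {
        tr <- build_tree(thm, pm, gm, logu, v, j, eps, h0)
        thm <- tr$thm; pm <- tr$pm; gm <- tr$gm
      } else {
        tr <- build_tree(thp, pp, gp, logu, v, j, eps, h0)
        thp <- tr$thp; pp <- tr$pp; gp <- tr$gp
      }
      if (tr$s1 && tr$n1 > 0 && stats::runif(1) < tr$n1 / n) {
        th_new <- tr$th1; lp_new <- tr$lp1
      }
      n <- n + tr$n1
      dth <- thp - thm
      s <- isTRUE(tr$s1 &&
        sum(dth * velocity(pm)) >= 0 && sum(dth * velocity(pp)) >= 0)
      alpha_sum <- alpha_sum + tr$alpha
      nalpha_sum <- nalpha_sum + tr$nalpha
      j <- j + 1L
    }
    depths[it] <- j
    theta <- th_new
    cur <- lp_grad(theta)

    if (it <= warmup) {
      da_update(alpha_sum / max(1L, nalpha_sum))
      if (cur$lp > best_lp) { best_lp <- cur$lp; best_theta <- theta }
      if (length(win_ends) && it > init_fast && it <= max(win_ends)) {
        win_buf <- rbind(win_buf, theta)
        if (it %in% win_ends) {
          # warmup-only rescue: a chain that has fallen into a region far
          # below the best log posterior seen so far (e.g. the flat
          # no-seizing plateau of the onset likelihood) is reset there,
          # and the window's draws are discarded so the poisoned
          # trajectory does not enter the metric estimate
          if (cur$lp < best_lp - 50) {
            theta <- best_theta
            cur <- lp_grad(theta)
          } else {
            nw <- nrow(win_buf)
            shrink <- nw / (nw + 5)
            v <- apply(win_buf, 2, stats::var) * shrink +
              1e-3 * (1 - shrink)
            S <- if (nb > 0)
              stats::cov(win_buf[, 1:nb, drop = FALSE]) * shrink +
                diag(1e-3 * (1 - shrink), nb) else NULL
            set_metric(v, S)
          }
          eps <- find_eps()
          mu <- log(10 * eps)
          eps_bar <- 1; H_bar <- 0; da_iter <- 0L
          win_buf <- NULL
        }
      }
      if (it == warmup) eps <- eps_bar
    } else {
      out[it - warmup, ] <- theta
      lp_out[it - warmup] <- cur$lp
    }
  }
  list(draws = out, lp = lp_out, step_size = eps,
       divergences = n_div, treedepth = depths)
}
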