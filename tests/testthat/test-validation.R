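test_that("state prediction accuracy counts draws against t_lim", {
  expect_equal(state_prediction_accuracy(c(10, 20, 30), TRUE), 1)
  expect_equal(state_prediction_accuracy(c(80, 85, 95, 100), FALSE), 0.5)
  # complementarity: the two truths partition the draws
  set.seed(31)
  for (i in 1:20) {
    draws <- runif(sample(1:9, 1), 0, 180)
    expect_equal(state_prediction_accuracy(draws, TRUE) +
                   state_prediction_accuracy(draws, FALSE), 1)
  }
})

test_that("onset prediction accuracy applies the border rule", {
  expect_equal(onset_prediction_accuracy(c(30, 30, 30), 30), 1)
  expect_equal(onset_prediction_accuracy(c(30, 34, 40), 30), 2 / 3)
  # truth too close to t_lim: excluded
  expect_true(is.na(onset_prediction_accuracy(c(80, 85), 86)))
  expect_true(is.na(onset_prediction_accuracy(c(80, 85), 85)))
  expect_equal(onset_prediction_accuracy(c(80, 91), 84.9), 0.5)
})

test_that("unweighted estimate replaces draws with the other observations", {
  est <- unweighted_estimate(c(40, 50, Inf), truth_seizing = TRUE,
                             t_true = 42)
  expect_equal(est$state_pa, 2 / 3)
  expect_equal(est$onset_pa, 1 / 3)
  est2 <- unweighted_estimate(c(40, 50), truth_seizing = TRUE)
  expect_equal(est2$state_pa, 1)
  expect_true(is.na(est2$onset_pa))
})

test_that("weighted estimate reduces to unweighted under equal weights", {
  set.seed(33)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    t_others <- ifelse(runif(k) < 0.3, Inf, runif(k, 5, 120))
    truth <- runif(1) < 0.5
    t_true <- if (truth) runif(1, 5, 80) else NA
    est <- unweighted_estimate(t_others, truth, t_true)
    w <- rep(runif(1, 0.1, 3), k)
    west <- weighted_estimate(t_others, w, truth, t_true)
    expect_equal(west$state_pa, est$state_pa)
    if (!is.na(est$onset_pa)) expect_equal(west$onset_pa, est$onset_pa)
    # scale invariance
    west2 <- weighted_estimate(t_others, w * 17, truth, t_true)
    expect_equal(west2$state_pa, west$state_pa)
  }
})

test_that("degenerate weights isolate a single informative neighbour", {
  west <- weighted_estimate(c(40, 200), c(1, 0), truth_seizing = TRUE)
  expect_equal(west$state_pa, 1)
  west0 <- weighted_estimate(c(40, 50), c(0, 0), truth_seizing = TRUE)
  expect_true(is.na(west0$state_pa))
})

test_that("precision-recall counts TP/FP/FN over the threshold sweep", {
  p <- c(A = 0.9, B = 0.6, C = 0.4, D = 0.05)
  # predictions exactly equal to the relevant set
  pr <- precision_recall_curve(p, c("A", "B"),
                               thresholds = 0.5, drop_empty = FALSE)
  expect_equal(pr$precision, 1); expect_equal(pr$recall, 1)
  # disjoint prediction
  pr0 <- precision_recall_curve(p, c("D"), thresholds = 0.5)
  expect_equal(pr0$precision, 0); expect_equal(pr0$recall, 0)
  # mixed case: relevant {A, C}, predicted {A, B}
  prm <- precision_recall_curve(p, c("A", "C"), thresholds = 0.5)
  expect_equal(prm$precision, 0.5); expect_equal(prm$recall, 0.5)
  # recall never increases with the threshold
  set.seed(4)
  pp <- setNames(runif(30), paste0("R", 1:30))
  curve <- precision_recall_curve(pp, paste0("R", 1:5), drop_empty = FALSE)
  expect_true(all(diff(curve$recall) <= 1e-12))
  # empty-prediction convention is flagged
  pr1 <- precision_recall_curve(p, "A", thresholds = 0.95,
                                drop_empty = FALSE)
  expect_true(pr1$no_predictions); expect_equal(pr1$precision, 1)
})

test_that("virtual resection of a single-driver seizure suppresses it", {
  # driver region 1 feeds all others; all other excitabilities are low
  n <- 8
  W <- matrix(0, n, n); W[2:n, 1] <- 1
  W <- connectome(W)
  q <- q_star()
  c_vec <- c(3.5, rep(-4, n - 1))
  c_draws <- matrix(rep(c_vec, each = 50), 50, n)
  colnames(c_draws) <- region_ids(W)
  vr <- virtual_resection(W, "R1", c_draws, q)
  expect_gt(vr$n_preop, 0)
  expect_equal(vr$n_postop, 0)
  expect_equal(vr$relative_reduction, 1)
  # resecting nothing changes nothing
  vr0 <- virtual_resection(W, character(0), c_draws, q)
  expect_equal(vr0$relative_reduction, 0)
  expect_equal(vr0$n_preop, vr0$n_postop)
  # the resected driver is not part of the post-operative count even
  # though it seized pre-operatively
  expect_equal(vr$n_preop, 1)
  agg <- aggregate_virtual_resection(list(vr, vr0))
  expect_equal(agg$relative_reduction, 0.5)
  expect_equal(aggregate_virtual_resection(list(vr, vr0), "min")$relative_reduction, 0)
})

test_that("resection CSV loader applies the strict 50% extent cut", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(region_id = c("A", "B", "C"),
                       resected_fraction = c(0.9, 0.5, 0.51)),
            f, row.names = FALSE)
  r <- read_resection(f, engel = "II")
  expect_equal(r$resected, c("A", "C"))
  expect_equal(r$engel, "II")
})

test_that("leave-one-out scores every observed region once", {
  W <- generate_network(8, 0.6, seed = 71)
  q <- q_star()
  gs <- generate_seizure(W, q, hidden_fraction = 0.25, seed = 72)
  loo <- run_loo(gs$obs, W, q, chains = 2, warmup = 200, draws = 200,
                 seed = 5)
  n_obs <- sum(gs$obs$status != "hidden")
  expect_equal(nrow(loo) + length(attr(loo, "excluded")), n_obs)
  expect_true(all(loo$state_pa_inference >= 0 & loo$state_pa_inference <= 1))
  ok <- !is.na(loo$onset_pa_inference)
  expect_true(all(loo$onset_pa_inference[ok] >= 0 &
                    loo$onset_pa_inference[ok] <= 1))
  # onset accuracy present exactly for eligible seizing regions
  eligible <- loo$truth_state == "seizing" &
    loo$truth_onset < 90 - 5
  expect_equal(!is.na(loo$onset_pa_inference), eligible)
})

test_that("inference beats the unweighted estimate on a hub-driven network", {
  # hub drives region 2 through a dominant afferent; most observed
  # regions do not seize, so the unweighted estimate votes non-seizing
  # while the network inference can see the hub connection
  n <- 10
  W <- matrix(0, n, n)
  W[2, 1] <- 0.95
  W[3:n, 1] <- 0.05
  W <- connectome(W)
  q <- q_star()
  c_vec <- c(3, 0.5, rep(-3, n - 2))
  t_true <- simulate_onsets(W, q, c_vec, t_max = 360)
  status <- ifelse(t_true < 90, "seizing", "non-seizing")
  obs <- seizure_observation(region_ids(W), status,
                             ifelse(t_true < 90, t_true, Inf))
  expect_equal(unname(status[2]), "seizing")
  i <- 2
  obs_i <- obs; obs_i$status[i] <- "hidden"; obs_i$onset_s[i] <- NA
  fit <- fit_seizure(obs_i, W, q, chains = 2, seed = 31)
  t_draws <- predict(fit, "onsets")[, i]
  inf_pa <- state_prediction_accuracy(t_draws, TRUE)
  others <- setdiff(which(status != "hidden"), i)
  est_pa <- unweighted_estimate(ifelse(t_true[others] < 90,
                                       t_true[others], Inf), TRUE)$state_pa
  expect_gt(inf_pa, est_pa)
})

test_that("permutation importance isolates the informative feature", {
  set.seed(91)
  n <- 300
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- X$x1
  # a perfect predictor of y = x1
  model <- structure(list(), class = "oracle_model")
  pfun <- function(m, nd) nd$x1
  imp <- permutation_feature_importance(model, X, y, K = 30, seed = 2,
                                        predict_fun = pfun)
  expect_gt(imp[["x1"]], 0.5)
  expect_lt(abs(imp[["x2"]]), 0.05)
  expect_lt(abs(imp[["x3"]]), 0.05)
  # column order does not matter
  imp2 <- permutation_feature_importance(model, X[, c(3, 1, 2)], y, K = 30,
                                         seed = 2, predict_fun = pfun)
  expect_equal(imp2[["x1"]], imp[["x1"]], tolerance = 0.02)
  # target independent of all features: importances vanish
  y0 <- rnorm(n)
  m0 <- lm(y0 ~ x1 + x2 + x3, data = X)
  imp0 <- permutation_feature_importance(m0, X, y0, K = 30, seed = 3)
  expect_true(all(abs(imp0) < 0.1))
})
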