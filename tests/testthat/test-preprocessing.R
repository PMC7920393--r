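test_that("connectome normalization follows the volume/percentile/sum recipe", {
  # uniform counts, equal volumes: every row sums to 1 afterwards
  n <- 4
  cnt <- matrix(1, n, n); diag(cnt) <- 0
  W <- normalize_connectome(cnt, rep(2, n))
  expect_equal(unname(rowSums(W)), rep(1, n))
  # hand-computed 2x2 case
  W2 <- normalize_connectome(matrix(c(0, 4, 2, 0), 2, 2, byrow = TRUE),
                             volumes = c(2, 1))
  expect_equal(unname(unclass(W2)), matrix(c(0, 1, 1, 0), 2, 2))
  # scale invariance in the counts
  set.seed(2)
  cnt <- matrix(rpois(36, 40), 6, 6); diag(cnt) <- 0
  vol <- runif(6, 500, 1500)
  expect_equal(unclass(normalize_connectome(cnt, vol)),
               unclass(normalize_connectome(cnt * 7, vol)))
  expect_error(normalize_connectome(matrix(0, 3, 3), rep(1, 3)), "zero")
  expect_error(normalize_connectome(cnt, rep(0, 6)), "positive")
})

test_that("hippocampus pair correction adds the 98th percentile", {
  set.seed(8)
  cnt <- matrix(rpois(64, 20), 8, 8); diag(cnt) <- 0
  vol <- runif(8, 1, 3)
  ids <- paste0("R", 1:8)
  wt <- sweep(cnt, 1, vol, "/"); diag(wt) <- 0
  p98 <- quantile(as.vector(wt), 0.98, names = FALSE)
  wt[2, 5] <- wt[2, 5] + p98
  wt[5, 2] <- wt[5, 2] + p98
  expected <- wt / max(rowSums(wt))
  W <- normalize_connectome(cnt, vol, hippocampus_pairs = list(c("R2", "R5")),
                            region_ids = ids)
  expect_equal(unname(unclass(W)), unname(expected))
})

test_that("band log-power separates bands and tracks power steps", {
  fs <- 256
  tt <- seq(0, 299, by = 1 / fs)
  # 50 Hz tone lands in the high band only
  tone <- sin(2 * pi * 50 * tt)
  bp <- band_logpower(tone, fs)
  expect_gt(mean(bp$logpower[, 2]) - mean(bp$logpower[, 1]), log(50))
  # 8 Hz tone with amplitude x sqrt(5) after t0: low band rises by log 5
  t0 <- 150
  amp <- ifelse(tt >= t0, sqrt(5), 1)
  x <- amp * sin(2 * pi * 8 * tt)
  bp <- band_logpower(x, fs)
  pre <- bp$time < t0 - 5; post <- bp$time > t0 + 5
  expect_equal(mean(bp$logpower[post, 1]) - mean(bp$logpower[pre, 1]),
               log(5), tolerance = 0.05)
  # stationary noise: per-band level is stable relative to a x5 step
  set.seed(1)
  bpn <- band_logpower(rnorm(length(tt)), fs)
  expect_lt(sd(bpn$logpower[, 1]), 0.2 * log(5))
  expect_lt(sd(bpn$logpower[, 2]), 0.2 * log(5))
  expect_error(band_logpower(tone, fs = 150), "Nyquist")
})

test_that("channel onset detection finds sustained power steps only", {
  fs <- 256
  dur <- 400
  onsets <- c(A = 200)
  recs <- generate_seeg_signal(onsets, fs = fs, duration = dur,
                               seizure_end = 260, gain = 10,
                               clinical_onset = 195, seed = 3)
  det <- detect_channel_onset(recs[[1]])
  expect_true(det$seizing)
  expect_lt(abs(det$onset_s - 200), 2)
  # no power change: non-seizing
  rec0 <- generate_seeg_signal(c(A = Inf), fs = fs, duration = dur,
                               clinical_onset = 195, seed = 4)[[1]]
  det0 <- detect_channel_onset(rec0)
  expect_false(det0$seizing)
  expect_true(is.na(det0$onset_s))
  # a 10 s burst is removed by the mask cleaning
  recb <- generate_seeg_signal(c(A = 200), fs = fs, duration = dur,
                               seizure_end = 210, gain = 10,
                               clinical_onset = 195, seed = 5)[[1]]
  expect_false(detect_channel_onset(recb)$seizing)
})

test_that("detection is invariant to a global amplitude gain", {
  recs <- generate_seeg_signal(c(A = 150), fs = 256, duration = 300,
                               seizure_end = 220, gain = 10,
                               clinical_onset = 145, seed = 6)
  r1 <- recs[[1]]
  r2 <- r1; r2$signal <- r2$signal * 37.5
  d1 <- detect_channel_onset(r1); d2 <- detect_channel_onset(r2)
  expect_equal(d1$seizing, d2$seizing)
  expect_equal(d1$onset_s, d2$onset_s)
})

test_that("channel-to-region assignment applies the ambiguity rule", {
  parc <- parcellation(
    c("A", "B"),
    list(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(3, 0, 0))))
  # inside A (d1 = 0), other region 3 mm off: ratio 6 >= 2 -> assigned
  expect_equal(assign_channel_to_region(c(1, 0, 0), parc), "A")
  # d1 = 2, d2 = 4: ratio 1.6 < 2 -> unassigned
  parc2 <- parcellation(c("A", "B"),
                        list(rbind(c(-2, 0, 0)), rbind(c(4, 0, 0))))
  expect_true(is.na(assign_channel_to_region(c(0, 0, 0), parc2)))
  # equidistant: unassigned
  parc3 <- parcellation(c("A", "B"),
                        list(rbind(c(-1, 0, 0)), rbind(c(1, 0, 0))))
  expect_true(is.na(assign_channel_to_region(c(0, 0, 0), parc3)))
  expect_error(assign_channel_to_region(c(0, 0, 0),
                                        parcellation("A", list(rbind(c(0, 0, 0))))),
               "two regions")
  expect_warning(
    assign_channel_to_region(c(30, 0, 0), parc), "mm")
})

test_that("region aggregation takes the lower-interpolation median", {
  expect_equal(aggregate_region_observation(40),
               list(status = "seizing", onset_s = 40, n_channels = 1L))
  # odd count with an Inf sentinel
  agg <- aggregate_region_observation(c(10, 20, Inf))
  expect_equal(agg$status, "seizing"); expect_equal(agg$onset_s, 20)
  # even split resolves to the seizing side
  agg <- aggregate_region_observation(c(15, Inf))
  expect_equal(agg$status, "seizing"); expect_equal(agg$onset_s, 15)
  # majority non-seizing
  agg <- aggregate_region_observation(c(15, Inf, Inf))
  expect_equal(agg$status, "non-seizing"); expect_equal(agg$onset_s, Inf)
})

test_that("aggregation matches the strict channel majority when one exists", {
  for (n_sz in 0:4) for (n_ns in 0:4) {
    if (n_sz + n_ns == 0 || n_sz == n_ns) next
    onsets <- c(seq_len(n_sz) * 10, rep(Inf, n_ns))
    agg <- aggregate_region_observation(onsets)
    expect_equal(agg$status == "seizing", n_sz > n_ns,
                 label = sprintf("majority %d seizing %d non", n_sz, n_ns))
  }
})

test_that("finalize_seizure aligns, truncates, and excludes correctly", {
  ids <- paste0("R", 1:5)
  obs <- finalize_seizure(c(R1 = 100, R2 = 130, R3 = 175), ids)
  expect_equal(obs$onset_s[1:2], c(30, 60))
  expect_equal(obs$status[1:3], c("seizing", "seizing", "non-seizing"))
  expect_equal(obs$status[4:5], c("hidden", "hidden"))
  # earliest onset lands exactly at t1 and nothing finite exceeds t_lim
  expect_equal(min(obs$onset_s[obs$status == "seizing"]), 30)
  expect_true(all(obs$onset_s[is.finite(obs$onset_s)] <= 90))
  # all channels non-seizing: excluded
  expect_null(finalize_seizure(c(R1 = Inf, R2 = Inf), ids))
  # single seizing region sits at exactly 30 s
  single <- finalize_seizure(c(R4 = 1234.5), ids)
  expect_equal(single$onset_s[4], 30)
})

test_that("seizure duration filter is strict at 30 s", {
  expect_true(seizure_duration_filter(65.95))
  expect_false(seizure_duration_filter(30))
  expect_false(seizure_duration_filter(29))
})

test_that("seizure observations round-trip through CSV", {
  obs <- seizure_observation(paste0("R", 1:4),
                             c("seizing", "non-seizing", "hidden", "seizing"),
                             c(30.5, Inf, NA, 62.25))
  f <- withr::local_tempfile(fileext = ".csv")
  write_seizure_observation(obs, f)
  back <- read_seizure_observation(f)
  expect_equal(back$status, obs$status)
  expect_equal(back$onset_s, obs$onset_s)
})
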