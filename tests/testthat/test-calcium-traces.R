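test_that("trace extraction averages ROI pixels per frame", {
  m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 1L
  st <- image_stack(array(7, dim = c(4, 4, 5)), 1)
  tr <- extract_traces(st, m)
  expect_equal(unname(tr$F[1, ]), rep(7, 5))

  # 2-pixel ROI with values 1 and 3 -> mean 2
  fr <- array(0, dim = c(2, 2, 1))
  fr[1, 1, 1] <- 1; fr[2, 1, 1] <- 3
  m2 <- matrix(0L, 2, 2); m2[1:2, 1] <- 1L
  expect_equal(unname(extract_traces(image_stack(fr), m2)$F[1, 1]), 2)

  # checkerboard ROI matches a brute-force pixel loop
  set.seed(9)
  fr3 <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  m3 <- matrix(0L, 8, 8)
  m3[(row(m3) + col(m3)) %% 2 == 0] <- 1L
  got <- extract_traces(image_stack(fr3), m3)$F
  for (t in 1:4) {
    vals <- c()
    for (r in 1:8) for (cc in 1:8) if (m3[r, cc] == 1L)
      vals <- c(vals, fr3[r, cc, t])
    expect_equal(unname(got[1, t]), mean(vals))
  }

  expect_error(extract_traces(image_stack(fr3), matrix(0L, 8, 8)), "no ROIs")
  expect_error(extract_traces(image_stack(fr3), matrix(1L, 4, 4)),
               "different shapes")
})

test_that("dF/F is zero for constant and linearly trending traces", {
  Tn <- 100
  tm <- trace_matrix(rbind(rep(50, Tn), 100 + 0.7 * seq_len(Tn)),
                     frame_interval = 1)
  nt <- normalize_traces(tm)
  expect_equal(unname(nt$dff[1, ]), rep(0, Tn))       # F = F0 exactly
  expect_lt(max(abs(nt$dff[2, ])), 1e-9)              # detrend kills ramps
  expect_false(any(nt$active))
})

test_that("boxcar transients are detected as spikes and gate the active flag", {
  Tn <- 200
  f <- rep(100, Tn)
  for (s in c(40, 100, 160)) f[s + 0:2] <- 150  # three isolated transients
  nt <- normalize_traces(trace_matrix(rbind(f), frame_interval = 1),
                         smooth_window = 1)
  # (F - F0)/F0 = 0.5 at the peaks (baseline percentile sits at 100; the
  # tiny residual slope from detrending perturbs it at the 1e-3 level)
  expect_equal(max(nt$dff[1, ]), 0.5, tolerance = 0.01)
  # verify the spike count with a direct local-maximum scan
  d <- nt$dff[1, ]
  scan <- sum(d[2:(Tn - 1)] > d[1:(Tn - 2)] & d[2:(Tn - 1)] >= d[3:Tn] &
                d[2:(Tn - 1)] >= pmax(0.25 * max(d), 0.05))
  expect_equal(length(nt$spikes[[1]]), 3)
  expect_equal(length(nt$spikes[[1]]), scan)
  expect_true(nt$active[1])
})

test_that("spike detection applies local-maximum and threshold rules", {
  # alternating trace: interior local maxima at frames 2, 4, 6 (1-based)
  expect_equal(detect_spikes(c(0, 1, 0, 1, 0, 1, 0)), c(2L, 4L, 6L))
  # absolute floor: everything below 0.05 is ignored
  expect_equal(length(detect_spikes(c(0, 0.04, 0, 0.04, 0))), 0)
  # monotone trace has no interior maximum
  expect_equal(length(detect_spikes(seq(0, 1, length.out = 10))), 0)
  # plateau counted once, at its leftmost frame
  expect_equal(detect_spikes(c(0, 1, 1, 1, 0)), 2L)
  expect_error(detect_spikes(c(0, 1)), "too short")
})

test_that("spike count is non-increasing in both thresholds", {
  set.seed(14)
  d <- abs(rnorm(300, 0, 0.2))
  for (i in 1:10) {
    r1 <- runif(1, 0, 0.5); r2 <- r1 + runif(1, 0, 0.5)
    a1 <- runif(1, 0, 0.2); a2 <- a1 + runif(1, 0, 0.2)
    expect_lte(length(detect_spikes(d, r2, a1)), length(detect_spikes(d, r1, a1)))
    expect_lte(length(detect_spikes(d, r1, a2)), length(detect_spikes(d, r1, a1)))
  }
})

test_that("dF/F is invariant to intensity rescaling", {
  set.seed(5)
  F <- matrix(100 + 20 * abs(rnorm(2 * 150)), 2, 150)
  n1 <- normalize_traces(trace_matrix(F))
  n2 <- normalize_traces(trace_matrix(3.7 * F))
  expect_equal(n1$dff, n2$dff, tolerance = 1e-12)
})

test_that("a half-length window reduces to the global percentile at central frames", {
  f <- 100 + seq_len(100)  # monotone trace
  tm <- trace_matrix(rbind(f))
  nt <- normalize_traces(tm, window_fraction = 0.5, smooth_window = 1)
  # detrending flattens the ramp; at central frames the window covers
  # everything, so F0 equals the global 8th percentile of the flat trace
  fd <- f - stats::lm.fit(cbind(1, seq_along(f)), f)$fitted.values + mean(f)
  expect_equal(unname(nt$F0[1, 50]),
               unname(quantile(fd, 0.08, type = 7)), tolerance = 1e-9)
})

test_that("non-positive baselines raise an error naming the ROI", {
  F <- rbind(a = rep(100, 50), b = rep(0, 50))
  expect_error(normalize_traces(trace_matrix(F, roi_labels = c("roiA", "roiB"))),
               "roiB")
})

test_that("active-ROI selection preserves labels and handles edge cases", {
  Tn <- 120
  f_active <- rep(100, Tn)
  for (s in c(20, 50, 80, 110)) f_active[s] <- 160
  f_quiet <- rep(100, Tn); f_quiet[60] <- 160
  tm <- trace_matrix(rbind(f_active, f_quiet, f_active),
                     roi_labels = c("A", "q", "B"))
  nt <- normalize_traces(tm, smooth_window = 1)
  sub <- select_active(nt)
  expect_equal(sub$roi_labels, c("A", "B"))
  expect_equal(nrow(sub$dff), sum(nt$active))
  # min_spikes = 0 keeps everything
  expect_equal(nrow(select_active(nt, min_spikes = 0)$dff), 3)
  # all inactive -> empty subset
  quiet <- normalize_traces(trace_matrix(rbind(rep(100, Tn))))
  expect_equal(nrow(select_active(quiet)$dff), 0)
})
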