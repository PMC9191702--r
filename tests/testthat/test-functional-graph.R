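test_that("cross-covariance matrix is a unit-diagonal correlation matrix", {
  set.seed(3)
  x <- rnorm(200)
  nt <- fake_norm(rbind(x, x, -x))
  M <- crosscov_matrix(nt)
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(M[1, 2], 1)
  expect_equal(M[1, 3], -1)
  expect_identical(M, t(M))
  expect_error(crosscov_matrix(fake_norm(rbind(x, rep(2, 200)),
                                         labels = c("u", "flat"))), "flat")
})

test_that("independent traces are nearly uncorrelated at lag 0", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    M <- crosscov_matrix(fake_norm(rbind(rnorm(1000), rnorm(1000))))
    if (abs(M[1, 2]) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("shuffle-null threshold is deterministic and honors the percentile", {
  set.seed(8)
  nt <- fake_norm(matrix(rnorm(6 * 300), 6, 300))
  t1 <- shuffle_null_threshold(nt, seed = 42)
  t2 <- shuffle_null_threshold(nt, seed = 42)
  expect_identical(t1, t2)
  expect_false(identical(t1, shuffle_null_threshold(nt, seed = 43)))

  # percentile 100 is the maximum of the pooled null values
  t100 <- shuffle_null_threshold(nt, percentile = 100, seed = 7)
  t99 <- shuffle_null_threshold(nt, percentile = 99, seed = 7)
  expect_gte(t100, t99)
  expect_lte(t100, 1)
})

test_that("functional graph thresholding is monotone with saturation bounds", {
  set.seed(12)
  nt <- fake_norm(matrix(rnorm(5 * 200), 5, 200))
  M <- crosscov_matrix(nt)
  expect_equal(n_edges(build_functional_graph(M, 1)), 0)
  expect_equal(n_edges(build_functional_graph(M, min(M) - 0.01)), 10)
  thrs <- seq(-1, 1, by = 0.25)
  ms <- vapply(thrs, function(t) n_edges(build_functional_graph(M, t)), 1L)
  expect_true(all(diff(ms) <= 0))
  # weights carry the matrix values on edges
  g <- build_functional_graph(M, 0)
  el <- edge_list(g)
  if (nrow(el) > 0)
    expect_equal(el$weight[1], M[as.character(el$source_label[1]),
                                 as.character(el$target_label[1])])
})

test_that("cross-covariance is invariant under a joint circular shift", {
  set.seed(31)
  X <- matrix(rnorm(4 * 250), 4, 250)
  sh <- function(v, k) c(v[(length(v) - k + 1):length(v)], v[1:(length(v) - k)])
  X2 <- t(apply(X, 1, sh, k = 57))
  expect_equal(crosscov_matrix(fake_norm(X)), crosscov_matrix(fake_norm(X2)),
               tolerance = 1e-12)
})

test_that("ramp classification reproduces hand-derived crossings", {
  # trapezoid: rises 0 -> 1 over frames 10..20 (0-based), falls to 0 by 45
  Tn <- 60
  f <- numeric(Tn)
  for (t0 in 10:20) f[t0 + 1] <- (t0 - 10) / 10
  for (t0 in 21:45) f[t0 + 1] <- 1 - (t0 - 20) / 25
  nt <- fake_norm(rbind(f), frame_interval = 1)
  rc <- classify_ramps(nt)
  expect_equal(rc$peak_time_s, 20)
  expect_equal(rc$ramp_up_s, 8)    # last at-or-below 0.2 before the peak: frame 12
  expect_equal(rc$ramp_down_s, 20) # first at-or-below 0.2 after the peak: frame 40

  # instantaneous spike: one frame up, one frame down
  g <- numeric(20); g[8] <- 1
  rs <- classify_ramps(fake_norm(rbind(g), frame_interval = 2))
  expect_equal(rs$ramp_up_s, 2)
  expect_equal(rs$ramp_down_s, 2)
  expect_equal(rs$peak_time_s, 14)

  # time-shifted copies share ramp classes but not peak times
  f2 <- c(numeric(5), f)[1:Tn]
  r2 <- classify_ramps(fake_norm(rbind(f, f2), frame_interval = 1))
  expect_equal(r2$ramp_up_s[1], r2$ramp_up_s[2])
  expect_equal(r2$ramp_down_s[1], r2$ramp_down_s[2])
  expect_equal(r2$peak_time_s[2] - r2$peak_time_s[1], 5)

  # never dipping below the band flags a missing ramp
  h <- 0.5 + c(seq(0, 0.5, length.out = 10), seq(0.45, 0, length.out = 10))
  w <- capture_warnings(rh <- classify_ramps(fake_norm(rbind(h),
                                                       frame_interval = 1)))
  expect_true(any(grepl("ramp-up undefined", w)))
  expect_true(is.na(rh$ramp_up_s))
})

test_that("ramp graphs require equal classes and pass the proximity gate", {
  reg <- data.frame(label = 1:3,
                    centroid_row = c(0, 0, 0),
                    centroid_col = c(0, 30, 500),
                    equiv_diameter = 4)
  ramps <- data.frame(label = 1:3, peak_time_s = 10,
                      ramp_up_s = c(5, 5, 5), ramp_down_s = c(10, 10, 10))
  # gate = 10 * mean diameter = 40: nodes 1-2 connect, node 3 is too far
  g <- build_ramp_graph(ramps, reg, distance_factor = 10)
  expect_equal(n_edges(g), 1)
  expect_equal(g$adjacency[1, 2], 1)

  # distance exactly at the gate connects; just above does not
  reg2 <- reg[1:2, ]; reg2$centroid_col <- c(0, 40)
  expect_equal(n_edges(build_ramp_graph(ramps[1:2, ], reg2, 10)), 1)
  reg2$centroid_col <- c(0, 40.001)
  expect_equal(n_edges(build_ramp_graph(ramps[1:2, ], reg2, 10)), 0)

  # all-distinct classes: empty edge set
  ramps2 <- ramps; ramps2$ramp_up_s <- c(5, 10, 15)
  expect_equal(n_edges(build_ramp_graph(ramps2, reg, 10)), 0)

  # missing class isolates the node with a warning
  ramps3 <- ramps; ramps3$ramp_down_s[2] <- NA
  expect_warning(g3 <- build_ramp_graph(ramps3, reg, 10), "isolated")
  expect_equal(sum(g3$adjacency[2, ]), 0)
})

test_that("ramp-graph edges match brute force on random layouts", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 12
    reg <- random_layout(n, field = 200)
    classes <- data.frame(label = 1:n, peak_time_s = 20,
                          ramp_up_s = sample(c(5, 10), n, replace = TRUE),
                          ramp_down_s = sample(c(5, 15, 25), n, replace = TRUE))
    g <- build_ramp_graph(classes, reg, distance_factor = 10)
    B <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- sqrt((reg$centroid_row[i] - reg$centroid_row[j])^2 +
                (reg$centroid_col[i] - reg$centroid_col[j])^2)
      same <- classes$ramp_up_s[i] == classes$ramp_up_s[j] &&
        classes$ramp_down_s[i] == classes$ramp_down_s[j]
      gate <- d <= 10 * (reg$equiv_diameter[i] + reg$equiv_diameter[j]) / 2
      if (same && gate) B[i, j] <- B[j, i] <- 1
    }
    expect_equal(unname(g$adjacency), B)
  }
})
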