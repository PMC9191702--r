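test_that("neighborhood similarity reproduces hand-computed configurations", {
  # all cells one phase: every score 1
  g <- cycle_graph(6)
  ph <- setNames(rep("G1", 6), 1:6)
  ns <- neighborhood_similarity(g, ph)
  expect_equal(ns$N_S, 1)
  expect_equal(ns$scores$score, rep(1, 6))

  # alternating 4-cycle: no neighbor ever matches
  g4 <- cycle_graph(4)
  ph4 <- setNames(c("A", "B", "A", "B"), 1:4)
  expect_equal(neighborhood_similarity(g4, ph4)$N_S, 0)

  # two disjoint same-phase pairs: score = 1 / 0.5 = 2
  g2 <- cell_graph(1:4, adjacency_from_edges(4, list(c(1, 2), c(3, 4))),
                   kind = "spatial_type2")
  ph2 <- setNames(c("A", "A", "B", "B"), 1:4)
  expect_equal(neighborhood_similarity(g2, ph2)$N_S, 2)

  # isolated cells are omitted from the average
  g5 <- cell_graph(1:3, adjacency_from_edges(3, list(c(1, 2))),
                   kind = "spatial_type2")
  ph5 <- setNames(c("A", "A", "A"), 1:3)
  ns5 <- neighborhood_similarity(g5, ph5)
  expect_true(is.na(ns5$scores$score[3]))
  expect_equal(ns5$N_S, 1)

  # no eligible cell: NA with warning
  expect_warning(r <- neighborhood_similarity(empty_graph(3),
                                              setNames(rep("A", 3), 1:3)),
                 "no eligible")
  expect_true(is.na(r$N_S))
})

test_that("excluded phases count in the population denominator by default", {
  # pair of A cells plus two isolated quiescent cells
  g <- cell_graph(1:4, adjacency_from_edges(4, list(c(1, 2))),
                  kind = "spatial_type2")
  ph <- setNames(c("A", "A", "Q", "Q"), 1:4)
  ns_all <- neighborhood_similarity(g, ph, include_phases = "A")
  expect_equal(ns_all$N_S, 1 / 0.5)  # population fraction of A is 2/4
  ns_elig <- neighborhood_similarity(g, ph, include_phases = "A",
                                     population = "eligible")
  expect_equal(ns_elig$N_S, 1)       # fraction over A cells only
})

test_that("similarity score is invariant to relabeling and system duplication", {
  set.seed(40)
  A <- random_adjacency(10, 0.35)
  g <- cell_graph(1:10, A, kind = "spatial_type2")
  ph <- setNames(sample(c("A", "B"), 10, replace = TRUE), 1:10)
  base <- neighborhood_similarity(g, ph)$N_S

  perm <- sample(10)
  g2 <- cell_graph(perm, A, kind = "spatial_type2")
  ph2 <- setNames(ph, perm)
  expect_equal(neighborhood_similarity(g2, ph2)$N_S, base)

  # duplicate the whole system: phases and fractions unchanged
  A2 <- rbind(cbind(A, matrix(0, 10, 10)), cbind(matrix(0, 10, 10), A))
  gd <- cell_graph(1:20, A2, kind = "spatial_type2")
  phd <- setNames(c(ph, ph), 1:20)
  expect_equal(neighborhood_similarity(gd, phd)$N_S, base)
})

test_that("random phase assignment gives similarity near one", {
  set.seed(90)
  A <- random_adjacency(40, 0.2)
  g <- cell_graph(1:40, A, kind = "spatial_type2")
  vals <- vapply(1:50, function(i) {
    ph <- setNames(sample(rep(c("A", "B"), 20)), 1:40)
    neighborhood_similarity(g, ph)$N_S
  }, 1)
  expect_equal(mean(vals), 1, tolerance = 0.1)
})

test_that("bin-mean subtraction annihilates bin-determined targets", {
  set.seed(61)
  ft <- make_feature_table(400, bin_signal_strength = 1, noise = 0, seed = 2)
  res <- quantile_bin_correct(ft$table,
                              bin_metrics = c("k", "k_n", "C", "E_l", "c_n",
                                              "w_n", "S_b"),
                              target_columns = "morphology")
  expect_lt(max(abs(res$corrected$morphology)), 1e-9)
  ve <- res$variance_explained
  expect_equal(ve$fraction[ve$factor == "network_bins"], 1, tolerance = 1e-9)

  # single cell sits alone in its bin: corrected value 0
  one <- ft$table[1, ]
  r1 <- quantile_bin_correct(one, bin_metrics = c("k", "C"),
                             target_columns = "morphology")
  expect_equal(r1$corrected$morphology, 0)
})

test_that("bin correction barely changes bin-independent noise", {
  set.seed(8)
  ft <- make_feature_table(10000, bin_signal_strength = 0, noise = 1, seed = 4)
  res <- quantile_bin_correct(ft$table,
                              bin_metrics = c("k", "k_n", "C", "E_l", "c_n",
                                              "w_n", "S_b"),
                              target_columns = "morphology")
  v_raw <- mean((ft$table$morphology - mean(ft$table$morphology))^2)
  v_cor <- mean((res$corrected$morphology - mean(res$corrected$morphology))^2)
  expect_gt(v_cor / v_raw, 0.95)
  expect_lte(v_cor / v_raw, 1)
})

test_that("edge-tied values fall into the lower bin and constants share one bin", {
  x <- c(1, 2, 3, 4, 5)
  tb <- data.frame(m = x, y = x)
  res <- quantile_bin_correct(tb, "m", n_bins = 5, target_columns = "y")
  # each quintile edge belongs to the bin below it
  edges <- res$bin_edges$m
  bins <- as.integer(res$bin_id)
  for (i in seq_along(x))
    expect_equal(bins[i], sum(x[i] > edges) + 1L)

  tbc <- data.frame(m = rep(3, 10), y = rnorm(10))
  resc <- quantile_bin_correct(tbc, "m", target_columns = "y")
  expect_equal(length(unique(resc$bin_id)), 1)
  expect_error(quantile_bin_correct(tb, "m", n_bins = 1, target_columns = "y"),
               "at least 2")
})

test_that("treatment correction subtracts per-condition means", {
  set.seed(12)
  ft <- make_feature_table(300, bin_signal_strength = 0.5, noise = 0.5,
                           treatment_effects = c(control = 0, vegf = 2),
                           seed = 9)
  res <- quantile_bin_correct(ft$table,
                              bin_metrics = c("k", "C"),
                              target_columns = "morphology",
                              treatment_column = "treatment")
  tc <- res$treatment_corrected$morphology
  for (cond in unique(ft$table$treatment))
    expect_equal(mean(tc[ft$table$treatment == cond]), 0, tolerance = 1e-9)
  expect_true(all(c("network_bins", "treatment") %in%
                    res$variance_explained$factor))
})

test_that("variance explained follows 1 - Vcorr/Vuncorr with population variances", {
  raw <- c(1, 2, 3, 4)
  expect_equal(variance_explained(raw, rep(0, 4)), 1)
  expect_equal(variance_explained(raw, raw), 0)
  expect_error(variance_explained(rep(2, 4), rep(0, 4)), "zero variance")

  # ANOVA decomposition: bin-mean signal variance a, noise variance b
  set.seed(10)
  n <- 20000
  bin <- sample(1:8, n, replace = TRUE)
  mu <- rnorm(8)
  mu <- (mu - mean(mu)) / sqrt(mean((mu - mean(mu))^2))
  a <- 2; b <- 0.5
  raw <- sqrt(a) * mu[bin] + rnorm(n, 0, sqrt(b))
  corrected <- raw - ave(raw, bin)
  expect_equal(variance_explained(raw, corrected), a / (a + b),
               tolerance = 0.03)
})

test_that("bin-mean correction never increases variance", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 200
    tb <- data.frame(m1 = rnorm(n), m2 = rnorm(n), y = rnorm(n))
    res <- quantile_bin_correct(tb, c("m1", "m2"), target_columns = "y")
    expect_gte(res$variance_explained$fraction, 0)
  }
})

test_that("Cohen's d matches hand arithmetic and is antisymmetric", {
  expect_equal(cohens_d(c(0, 1), c(1, 2)), -1 / sqrt(0.5))
  expect_equal(cohens_d(c(3, 5, 7), c(3, 5, 7)), 0)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1), c(1, 2)), "at least 2")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})

test_that("the representative cell minimizes distance to the cluster median", {
  X <- rbind(c(0, 0), c(1, 1), c(10, 10), c(0.9, 1.1))
  med <- apply(X, 2, median)
  expect_equal(representative_cell(X),
               which.min(rowSums(sweep(X, 2, med)^2)))
})
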