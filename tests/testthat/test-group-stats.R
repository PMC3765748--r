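# Group inference: t maps and their closed-form values, t-to-z conversion,
# cluster labelling against a flood-fill oracle, permutation correction, and
# summary-statistic t tests.

test_that("two-sample t map matches the pooled closed form", {
  g <- toy_grid(c(1L, 1L, 1L))
  A <- lapply(c(1, 2, 3), make_zmap, grid = g)
  B <- lapply(c(4, 5, 6), make_zmap, grid = g)
  sm <- two_sample_t_map(A, B)
  expect_equal(sm$t, -3.674235, tolerance = 1e-6)   # t.test(var.equal) oracle
  expect_equal(sm$df, 4)
  # identical groups -> t = 0 everywhere
  g2 <- toy_grid(c(4L, 3L, 2L))
  set.seed(1)
  M <- random_zmaps(4, g2)
  expect_equal(two_sample_t_map(M, M)$t, rep(0, 24))
  # swapping groups negates t; adding a constant map changes nothing
  set.seed(2)
  A2 <- random_zmaps(5, g2); B2 <- random_zmaps(5, g2)
  tAB <- two_sample_t_map(A2, B2)$t
  expect_equal(two_sample_t_map(B2, A2)$t, -tAB, tolerance = 1e-12)
  A3 <- lapply(A2, function(m) { m$values <- m$values + 7; m })
  B3 <- lapply(B2, function(m) { m$values <- m$values + 7; m })
  expect_equal(two_sample_t_map(A3, B3)$t, tAB, tolerance = 1e-9)
})

test_that("a planted group difference concentrates positive t in the hub", {
  g <- toy_grid(c(8L, 8L, 6L))
  hub <- rep(FALSE, 384); hub[100:149] <- TRUE
  set.seed(3)
  A <- random_zmaps(18, g, shift = hub * 1.0)
  B <- random_zmaps(18, g)
  sm <- two_sample_t_map(A, B)
  expect_gt(mean(sm$t[hub]), mean(sm$t[!hub]) + 1)
  expect_gt(mean(sm$t[hub]), 2)
})

test_that("paired t map matches the closed form and guards zero variance", {
  g <- toy_grid(c(1L, 1L, 1L))
  c1 <- lapply(c(2, 4, 6), make_zmap, grid = g)
  c2 <- lapply(c(1, 2, 3), make_zmap, grid = g)   # differences 1, 2, 3
  sm <- paired_t_map(c1, c2)
  expect_equal(sm$t, 3.464102, tolerance = 1e-6)
  expect_equal(sm$df, 2)
  # identical conditions -> 0; constant offset -> degenerate, z set to 0
  g2 <- toy_grid(c(3L, 3L, 2L))
  set.seed(4)
  M <- random_zmaps(5, g2)
  expect_equal(paired_t_map(M, M)$t, rep(0, 18))
  Mc <- lapply(M, function(m) { m$values <- m$values + 1; m })
  expect_warning(smc <- paired_t_map(Mc, M), "zero")
  expect_equal(smc$z, rep(0, 18))
  # subject order is checked
  M2 <- random_zmaps(5, g2)
  names_swapped <- rev(M2)
  expect_error(paired_t_map(M, names_swapped), "subject")
})

test_that("covariate regression recovers slopes and rejects degenerate input", {
  g <- toy_grid(c(1L, 1L, 1L))
  # all-zero difference maps -> slope t = 0
  Z0 <- lapply(rep(0, 6), make_zmap, grid = g)
  expect_equal(covariate_regression_map(Z0, 1:6)$t, 0)
  expect_error(covariate_regression_map(Z0, rep(2, 6)), "variance")
  # parameter recovery: slope 0.5, noise sd 0.1, n = 18
  set.seed(5)
  hits <- replicate(200, {
    x <- rnorm(18, 2.9, 1.2)
    y <- 0.5 * x + rnorm(18, sd = 0.1)
    reg <- covariate_regression_map(matrix(y, ncol = 1), x)
    reg$slope > 0.4 && reg$slope < 0.6
  })
  expect_gte(mean(hits), 0.95)
})

test_that("t-to-z conversion is monotone, antisymmetric and quadrature-exact", {
  expect_equal(t_to_z(0, 3), 0)
  expect_equal(t_to_z(2.3, 1e7), 2.3, tolerance = 0.05)
  expect_equal(t_to_z(-1.7, 9), -t_to_z(1.7, 9), tolerance = 1e-12)
  tt <- seq(-4, 4, by = 0.5)
  zz <- t_to_z(tt, 11)
  expect_true(all(diff(zz) > 0))
  # numeric CDF inversion oracle for t = 2, df = 10
  p <- integrate(function(u) dt(u, 10), -Inf, 2, rel.tol = 1e-12)$value
  expect_equal(t_to_z(2, 10), qnorm(p), tolerance = 1e-8)
  # large statistics stay finite and ordered
  expect_true(is.finite(t_to_z(60, 30)))
  expect_gt(t_to_z(60, 30), t_to_z(40, 30))
})

test_that("cluster labelling equals a brute-force flood fill", {
  set.seed(6)
  for (i in 1:12) {
    d <- c(9L, 8L, 7L)
    z3 <- array(rnorm(prod(d), sd = 1.5), d)
    conn <- sample(c(6L, 18L, 26L), 1)
    lab <- label_clusters(z3, z_threshold = 1.5, min_voxels = 1L,
                          connectivity = conn)
    ref <- oracle_components(z3 > 1.5, conn)
    expect_equal(partition_sets(lab), partition_sets(ref))
  }
})

test_that("cluster labelling thresholds, filters and orders by size", {
  d <- c(12L, 12L, 10L)
  z3 <- array(0, d)
  expect_equal(sum(label_clusters(z3) > 0), 0L)           # nothing survives
  z3[2:4, 2:4, 2:4] <- 4                                  # 27 voxels
  z3[8:10, 8:10, 6:8] <- 4                                # 27 voxels
  z3[6, 1, 1] <- 4                                        # below min_voxels
  lab <- label_clusters(z3, z_threshold = 2.3, min_voxels = 10L)
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  expect_equal(attr(lab, "sizes"), c(27L, 27L))
  big <- array(0, d); big[2:6, 2:6, 2:5] <- 3; big[9:10, 9:10, 8:9] <- 3
  lab2 <- label_clusters(big, min_voxels = 1L)
  expect_equal(attr(lab2, "sizes"), c(100L, 8L))          # size-descending
})

test_that("cluster reports carry mm3, peaks and world coordinates", {
  g <- toy_grid(c(12L, 12L, 10L), voxel_mm = 4)
  set.seed(7)
  vals <- rnorm(prod(g$dim), sd = 0.1)
  z3 <- array(vals, g$dim)
  z3[2:4, 2:4, 2:4] <- 4
  z3[3, 3, 3] <- 5                                        # peak
  sm <- hubfc:::new_stat_map(as.vector(z3), as.vector(z3), 34, "test",
                             g$mask, g$affine)
  lab <- label_clusters(sm, z_threshold = 2.3, min_voxels = 10L)
  rep1 <- cluster_report(sm, lab)
  expect_equal(rep1$n_voxels, 27L)
  expect_equal(rep1$cluster_mm3, 27 * 64)                 # 1728 on a 4 mm grid
  expect_equal(rep1$z_max, 5)
  world <- hubfc:::voxel_to_world(g$affine, cbind(2, 2, 2))
  expect_equal(c(rep1$peak_x, rep1$peak_y, rep1$peak_z), as.vector(world))
  # reporting convention: mm3 / voxel volume gives the voxel count
  expect_equal(7360 / 64, 115)
})

test_that("permutation correction attains the p floor on a huge effect", {
  g <- toy_grid(c(10L, 10L, 8L))
  set.seed(8)
  base <- random_zmaps(12, g, sd = 0.2)
  eff <- rep(0, prod(g$dim)); eff[200:240] <- 5
  cond1 <- lapply(seq_along(base), function(i) {
    m <- base[[i]]; m$values <- m$values + eff + rnorm(800, sd = 0.05)
    m$subject_id <- sprintf("s%02d", i); m
  })
  res <- permutation_cluster_correct(cond1, maps2 = base, test_kind = "paired",
                                     n_perm = 99L, seed = 9L)
  expect_gte(nrow(res$table_significant), 1L)
  # p follows the (1 + #{perm max >= size}) / (n_perm + 1) formula exactly,
  # with its floor at 1/(n_perm + 1)
  expect_equal(res$table$cluster_p,
               vapply(res$table$n_voxels, function(s)
                 (1 + sum(res$perm_max_size >= s)) / 100, numeric(1)))
  expect_gte(min(res$table$cluster_p), 0.01)
  expect_lte(min(res$table$cluster_p), 0.05)
})

test_that("permutation schemes reject undersized designs", {
  g <- toy_grid(c(4L, 4L, 3L))
  set.seed(10)
  M <- random_zmaps(6, g)
  expect_error(
    permutation_cluster_correct(M, group = rep(c("A", "B"), 3),
                                test_kind = "two_sample", n_perm = 499L),
    "permutation")
  expect_error(
    permutation_cluster_correct(M[1:4], maps2 = M[1:4], test_kind = "paired",
                                n_perm = 99L),
    "sign-flip")
  expect_error(
    permutation_cluster_correct(M, covariate = rnorm(6),
                                test_kind = "regression", n_perm = 99L),
    "sign-flip")
})

test_that("mean z extraction over a cluster behaves per definition", {
  g <- toy_grid(c(6L, 6L, 4L))
  cl <- array(FALSE, g$dim); cl[2:3, 2:3, 2] <- TRUE
  vals <- rep(2, prod(g$dim))
  maps <- list(make_zmap(vals, g, subject_id = "a", condition = "LP"),
               make_zmap(vals * 2, g, subject_id = "b", condition = "LP"))
  ex <- extract_mean_z(maps, cl)
  expect_equal(ex$mean_z, c(2, 4))
  one <- array(FALSE, g$dim); one[4, 4, 3] <- TRUE
  m1 <- make_zmap(seq_len(prod(g$dim)), g)
  idx <- which(one)
  expect_equal(extract_mean_z(list(m1), one)$mean_z, idx)
  expect_error(extract_mean_z(maps, array(FALSE, g$dim)), "empty")
})

test_that("summary-statistic t tests reproduce printed group comparisons", {
  # equal printed means force p = 1 exactly
  eq <- t_test_from_summary(5863, 1029, 18, 5863, 1198, 18)
  expect_equal(eq$p, 1)
  # top-third comparison lands on the printed significance
  top <- t_test_from_summary(5416, 932, 18, 4781, 783, 18)
  expect_lt(abs(top$p - 0.033), 0.005)
  expect_gt(top$t, 0)
  # total volume: reconstruction stays non-significant as printed
  tot <- t_test_from_summary(16977, 2868, 18, 16198, 2739, 18)
  expect_gt(tot$p, 0.05)
  # degenerate contracts
  z <- t_test_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(c(z$t, z$p), c(0, 1))
  expect_error(t_test_from_summary(3, 0, 5, 4, 0, 5), "undefined")
  # Welch equals pooled for equal n and SD
  w <- t_test_from_summary(10, 2, 12, 8, 2, 12, pooled = FALSE)
  p <- t_test_from_summary(10, 2, 12, 8, 2, 12, pooled = TRUE)
  expect_equal(w$t, p$t, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-9)
})

test_that("permutation p-values live on the achievable grid", {
  g <- toy_grid(c(8L, 8L, 6L))
  set.seed(11)
  A <- random_zmaps(8, g); B <- random_zmaps(8, g)
  res <- permutation_cluster_correct(c(A, B), group = rep(c("A", "B"), each = 8),
                                     test_kind = "two_sample",
                                     min_voxels = 1L, n_perm = 99L, seed = 12L)
  if (nrow(res$table)) {
    expect_true(all(res$table$cluster_p >= 1 / 100))
    expect_true(all(res$table$cluster_p <= 1))
  }
  expect_length(res$perm_max_size, 99L)
})
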