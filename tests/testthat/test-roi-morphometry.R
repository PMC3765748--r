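# Long-axis subdivision and section volumetry: axis estimation, the thirds
# partition, volume arithmetic, and group comparisons with covariates.

test_that("principal axis is exact for an axis-aligned box", {
  lb <- generate_label_volume(grid_shape = c(64L, 40L, 40L), voxel_mm = 1,
                              axis = c(1, 0, 0), length_mm = 30,
                              radius_mm = 2, center_mm = c(16, 0, 0),
                              shape = "box")
  pa <- principal_axis(lb, id = 2L)
  expect_equal(abs(pa$axis), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(pa$centroid, c(16, 0, 0), tolerance = 1e-8)
  # a sphere has no unique long axis
  sph <- generate_label_volume(grid_shape = c(40L, 40L, 40L), voxel_mm = 1,
                               axis = c(1, 0, 0), length_mm = 12,
                               radius_mm = 6, center_mm = c(10, 0, 0))
  expect_error(principal_axis(sph, id = 2L), "unique long axis")
  expect_error(principal_axis(array(0L, c(4, 4, 4)), diag(4), id = 1L),
               "3 voxels")
})

test_that("axis recovery stays within 5 degrees under rotation", {
  set.seed(1)
  for (th in c(pi / 6, pi / 4, 1.1)) {
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    lv <- generate_label_volume(grid_shape = c(56L, 56L, 48L),
                                axis = c(1, 0, 0), rotation = R,
                                center_mm = c(11, 0, 0), length_mm = 26,
                                radius_mm = 4.5)
    pa <- principal_axis(lv, id = 2L)
    ang <- acos(min(1, abs(sum(pa$axis * lv$meta$axis_right)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("thirds partition is disjoint, exhaustive and equal for boxes", {
  lb <- generate_label_volume(grid_shape = c(64L, 40L, 40L), voxel_mm = 1,
                              axis = c(1, 0, 0), length_mm = 30,
                              radius_mm = 2, center_mm = c(16, 0, 0),
                              shape = "box")
  ss <- split_thirds(lb, id = 2L)
  counts <- c(sum(ss$sections == 1L), sum(ss$sections == 2L),
              sum(ss$sections == 3L))
  expect_equal(counts, rep(160L, 3))                       # 480 / 3
  expect_equal(sum(counts), sum(lb$labels == 2L))          # partition
  # volumes sum to the parent volume exactly
  vol <- sapply(c("top", "middle", "bottom"), section_volume,
                sections = ss)
  expect_equal(sum(vol), sum(lb$labels == 2L) * 1)
})

test_that("ellipsoid thirds have a strictly largest middle section", {
  lv <- generate_label_volume()
  for (id in 1:2) {
    ss <- split_thirds(lv, id = id)
    v <- sapply(c("top", "middle", "bottom"), section_volume, sections = ss)
    expect_gt(v["middle"], v["top"])
    expect_gt(v["middle"], v["bottom"])
    expect_equal(sum(v), sum(lv$labels == id) *
                   hubfc:::affine_voxel_volume(lv$affine))
    # projection-based oracle: recompute sections by direct projection
    idx <- which(lv$labels == id)
    ijk <- arrayInd(idx, dim(lv$labels)) - 1L
    W <- hubfc:::voxel_to_world(lv$affine, ijk)
    pa <- principal_axis(lv, id = id)
    proj <- as.vector(sweep(W, 2, pa$centroid) %*% pa$axis)
    cuts <- min(proj) + (max(proj) - min(proj)) * c(1, 2) / 3
    ref <- findInterval(proj, cuts) + 1L     # 1 bottom .. 3 top (axis is +z)
    got <- ss$sections[idx]
    expect_equal(sum(got == 1L), sum(ref == 3L))   # top
    expect_equal(sum(got == 3L), sum(ref == 1L))   # bottom
  }
})

test_that("the 'top' section is the superior one", {
  lv <- generate_label_volume()
  ss <- split_thirds(lv, id = 2L)
  zmean <- sapply(1:3, function(code) {
    idx <- which(ss$sections == code)
    mean(hubfc:::voxel_to_world(lv$affine,
                                arrayInd(idx, dim(ss$sections)) - 1L)[, 3])
  })
  expect_equal(which.max(zmean), 1L)   # code 1 = top
  expect_equal(which.min(zmean), 3L)   # code 3 = bottom
})

test_that("section volume and bilateral arithmetic are exact", {
  arr <- array(0L, c(10, 10, 10))
  arr[1:10, 1:10, 1] <- 1L           # 100 voxels
  A <- diag(c(1.2, 1.2, 1.2, 1))
  expect_equal(section_volume(arr, which = 1L, affine = A), 172.8)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_equal(section_volume(one, which = 1L, affine = diag(4)), 1)
  expect_error(section_volume(arr, which = 2L, affine = A), "empty")
  expect_equal(bilateral_volume(2000, 3000), 5000)
  expect_error(bilateral_volume(2000, 0), "positive")
  expect_error(bilateral_volume(2000, NULL), "positive")
})

test_that("rotating the construction leaves section volumes within 2%", {
  base <- generate_label_volume(grid_shape = c(56L, 56L, 52L),
                                center_mm = c(14, 0, 2))
  th <- pi / 7
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  rot <- generate_label_volume(grid_shape = c(56L, 56L, 52L),
                               center_mm = c(14, 0, 2), rotation = R)
  for (sec in c("top", "middle", "bottom")) {
    v1 <- section_volume(split_thirds(base, id = 2L), sec)
    v2 <- section_volume(split_thirds(rot, id = 2L), sec)
    expect_lt(abs(v2 - v1) / v1, 0.02)
  }
})

test_that("mirror-symmetric labels give equal left/right section volumes", {
  lv <- generate_label_volume()
  for (sec in c("top", "middle", "bottom")) {
    vl <- section_volume(split_thirds(lv, id = 1L), sec)
    vr <- section_volume(split_thirds(lv, id = 2L), sec)
    expect_equal(vl, vr, tolerance = 0.02)
  }
})

test_that("group volume comparison matches t.test and handles covariates", {
  set.seed(2)
  a <- rnorm(10, 5000, 400); b <- a
  cmp <- compare_group_volumes(a, b)
  expect_equal(cmp$t, 0, tolerance = 1e-12)
  expect_equal(cmp$p, 1, tolerance = 1e-12)
  b2 <- rnorm(10, 4500, 400)
  ref <- t.test(a, b2, var.equal = TRUE)
  cmp2 <- compare_group_volumes(a, b2)
  expect_equal(cmp2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cmp2$p, ref$p.value, tolerance = 1e-10)
  # covariate adjustment reports the group coefficient
  covs <- data.frame(age = rnorm(20, 40, 10),
                     gender = factor(sample(c("F", "M"), 20, replace = TRUE)))
  cmp3 <- compare_group_volumes(a, b2, covariates = covs)
  fit <- lm(volume ~ group + age + gender,
            data = cbind(data.frame(volume = c(a, b2),
                                    group = factor(rep(c("A", "B"),
                                                       each = 10),
                                                   levels = c("B", "A"))),
                         covs))
  expect_equal(cmp3$t, summary(fit)$coefficients["groupA", 3],
               tolerance = 1e-10)
  # a covariate duplicating the group indicator is collinear
  dup <- data.frame(g2 = rep(c(1, 0), each = 10))
  expect_error(compare_group_volumes(a, b2, covariates = dup), "collinear")
})

test_that("simulated volumetry power matches the analytic t-test power", {
  small <- list(grid_shape = c(30L, 22L, 32L), length_mm = 24,
                radius_mm = 6.3, center_mm = c(8, -2, 3))
  nrep <- 50L
  pvals <- numeric(nrep)
  deltas <- numeric(nrep); sds <- numeric(nrep)
  for (r in seq_len(nrep)) {
    vols <- do.call(simulate_volumetry_cohort,
                    c(list(n_per_group = 18L, seed = 5000L + r), small))
    pat <- vols$top_mm3[vols$group == "patient"]
    ctl <- vols$top_mm3[vols$group == "control"]
    pvals[r] <- compare_group_volumes(pat, ctl)$p
    deltas[r] <- mean(pat) - mean(ctl)
    sds[r] <- sqrt((var(pat) + var(ctl)) / 2)
  }
  observed_power <- mean(pvals < 0.05)
  analytic <- power.t.test(n = 18, delta = mean(deltas), sd = mean(sds),
                           sig.level = 0.05)$power
  # simulation agrees with the closed-form power within binomial noise
  expect_lt(abs(observed_power - analytic),
            3 * sqrt(analytic * (1 - analytic) / nrep) + 0.02)
  # the planted inflation is recovered on average
  expect_gt(mean(deltas), 0)
})
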