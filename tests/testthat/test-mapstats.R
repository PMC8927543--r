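test_that("grid neighbours implement 26- and 6-connectivity", {
  coords <- toy_grid(3, 3, 1)
  nb26 <- grid_neighbors(coords, 26)
  nb6 <- grid_neighbors(coords, 6)
  centre <- which(coords[, 1] == 2 & coords[, 2] == 2)
  expect_length(nb26[[centre]], 8)
  expect_length(nb6[[centre]], 4)
  corner <- which(coords[, 1] == 1 & coords[, 2] == 1)
  expect_length(nb26[[corner]], 3)
  expect_length(nb6[[corner]], 2)
})

test_that("GLM t map matches a per-voxel lm oracle", {
  set.seed(1)
  n <- 24; v <- 15
  design <- data.frame(group = rep(0:1, each = n / 2), age = rnorm(n, 65, 8),
                       gender = sample(0:1, n, replace = TRUE))
  maps <- matrix(rnorm(n * v), n)
  tt <- glm_tstat_map(maps, design, contrast = c(1, 0, 0))
  for (j in c(1, 7, 15)) {
    fit <- lm(maps[, j] ~ group + age + gender, data = design)
    expect_equal(tt[j], unname(summary(fit)$coefficients["group", "t value"]),
                 tolerance = 1e-8)
  }
  # zero contrast -> zero map
  expect_true(all(glm_tstat_map(maps, design, c(0, 0, 0)) == 0))
  # noiseless group difference -> saturated flag
  sat <- matrix(0, n, 2)
  sat[design$group == 1, 1] <- 1
  sat[, 2] <- rnorm(n)
  ts <- glm_tstat_map(sat, design["group"], contrast = 1)
  expect_true(is.infinite(ts[1]))
  expect_true(attr(ts, "saturated")[1])
  expect_false(attr(ts, "saturated")[2])
})

test_that("TFCE matches the exhaustive threshold-sum oracle", {
  # single supra-threshold voxel: analytic discrete sum
  coords <- toy_grid(7)
  nb <- grid_neighbors(coords)
  stat <- c(0, 0, 0, 2, 0, 0, 0)
  dh <- 0.02
  enh <- tfce_transform(stat, nb, dh = dh)
  hs <- seq(dh, 2, by = dh)
  expect_equal(enh[4], sum(1^0.5 * hs^2 * dh), tolerance = 1e-9)
  expect_equal(enh[-4], rep(0, 6))
  # 1-D two-peak map vs oracle
  stat2 <- c(1, 2, 0.4, 0, 1.5, 2.5, 1, 0.2, 0, 0)
  nb2 <- grid_neighbors(toy_grid(10))
  dh2 <- 0.05
  expect_equal(tfce_transform(stat2, nb2, dh = dh2),
               brute_tfce(stat2, nb2, dh = dh2), tolerance = 1e-9)
  # small 3-D map vs oracle
  set.seed(2)
  coords3 <- toy_grid(4, 4, 3)
  nb3 <- grid_neighbors(coords3)
  stat3 <- pmax(rnorm(nrow(coords3)), 0)
  expect_equal(tfce_transform(stat3, nb3, dh = 0.03),
               brute_tfce(stat3, nb3, dh = 0.03), tolerance = 1e-9)
  # all-zero map stays zero
  expect_equal(tfce_transform(rep(0, 10), nb2), rep(0, 10))
  # negative tail: transform of the negated map, negated
  expect_equal(tfce_transform(-stat2, nb2, dh = dh2),
               -brute_tfce(stat2, nb2, dh = dh2), tolerance = 1e-9)
})

test_that("TFCE is monotone under uniform scaling", {
  set.seed(3)
  nb <- grid_neighbors(toy_grid(4, 4, 2))
  stat <- rnorm(32)
  e1 <- tfce_transform(stat, nb, dh = 0.05)
  e2 <- tfce_transform(2 * stat, nb, dh = 0.05)
  expect_true(all(abs(e2) >= abs(e1) - 1e-12))
})

test_that("permutation FWE detects a planted cluster and is reproducible", {
  set.seed(4)
  coords <- toy_grid(5, 5, 5)
  n <- 20; v <- 125
  design <- data.frame(group = rep(0:1, each = 10), age = rnorm(n, 65, 8),
                       gender = sample(0:1, n, replace = TRUE))
  block <- which(coords[, 1] <= 3 & coords[, 2] <= 3 & coords[, 3] <= 3)
  maps <- matrix(rnorm(n * v), n)
  maps[design$group == 1, block] <- maps[design$group == 1, block] + 2
  sm <- permutation_fwe(maps, design, c(1, 0, 0), coords, n_perm = 300,
                        seed = 5)
  expect_gte(mean(sm$p_fwe_pos[block] < 0.05), 0.95)
  expect_true(all(sm$p_fwe_pos >= 1 / 301 & sm$p_fwe_pos <= 1))
  sm2 <- permutation_fwe(maps, design, c(1, 0, 0), coords, n_perm = 300,
                         seed = 5)
  expect_identical(sm$p_fwe_pos, sm2$p_fwe_pos)
  # cluster table: the planted block is recovered at 6 mm voxels
  cl <- extract_clusters(sm$stat, sm$p_fwe_pos, coords, voxel_volume = 216)
  expect_gte(nrow(cl), 1)
  expect_equal(cl$size_mm3[1], cl$n_voxels[1] * 216)
  expect_true(cl$n_voxels[1] >= 0.9 * length(block))
})

test_that("exhaustive enumeration replaces sampling for tiny designs", {
  set.seed(6)
  n <- 5
  design <- data.frame(group = c(0, 0, 1, 1, 1))
  maps <- matrix(rnorm(n * 4), n)
  sm <- permutation_fwe(maps, design, 1, toy_grid(4), n_perm = 500, seed = 1)
  expect_true(sm$exhaustive)
  expect_equal(sm$n_perm, 120)
})

test_that("cluster extraction handles empty and multiple components", {
  coords <- toy_grid(10)
  stat <- rnorm(10)
  empty <- extract_clusters(stat, rep(1, 10), coords)
  expect_equal(nrow(empty), 0)
  p <- rep(1, 10); p[c(1, 2, 7, 8, 9)] <- 0.01
  cl <- extract_clusters(stat, p, coords, voxel_volume = 216)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$n_voxels, c(2, 3))
  # 3-voxel cluster at 6 mm isotropic = 648 mm^3
  expect_equal(cl$size_mm3[cl$n_voxels == 3], 648)
})
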