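test_that("reference network has the exact edge count and hubs", {
  a <- generate_reference_network(4, 1.0, seed = 1)
  expect_equal(sum(a) / 2, 6) # complete graph
  a <- generate_reference_network(50, 0.1, seed = 1)
  expect_equal(sum(a) / 2, 123) # round(0.1 * 1225)
  expect_true(all(diag(a) == 0))
  expect_identical(a, t(a))
  # heavy-tailed: the top node dominates the median degree
  deg <- rowSums(a)
  expect_gt(max(deg), 2 * median(deg))
  # determinism
  expect_identical(a, generate_reference_network(50, 0.1, seed = 1))
  expect_false(identical(a, generate_reference_network(50, 0.1, seed = 2)))
  expect_error(generate_reference_network(50, 1e-5), "fewer than one edge")
})

test_that("disrupt_network_metrics plants an exact, recoverable slope", {
  ref <- rowSums(generate_reference_network(80, 0.1, seed = 4))
  expect_equal(disrupt_network_metrics(ref, 0, 0), ref)
  ind <- disrupt_network_metrics(ref, -0.3, 0)
  expect_equal(kd_slope(ind, ref), -0.3, tolerance = 1e-12)
  # Monte Carlo with noise: mean recovered slope within 0.02
  slopes <- vapply(1:200, function(r)
    kd_slope(disrupt_network_metrics(ref, -0.3, 0.1 * sd(ref), seed = r),
             ref), 0)
  expect_lt(abs(mean(slopes) + 0.3), 0.02)
  expect_error(disrupt_network_metrics(ref, 1.2, 0), "kappa")
})

test_that("covariance_from_network is positive definite with known correlations", {
  v <- 3
  tri <- matrix(1L, v, v); diag(tri) <- 0L
  sig <- covariance_from_network(tri, 0.3, 1)
  r <- cov2cor(sig)
  expect_equal(unname(r[1, 2]), 0.3 / 1.3, tolerance = 1e-12)
  # empty graph: correlations all zero
  sig0 <- covariance_from_network(matrix(0L, 4, 4), 0.3, 1)
  expect_equal(unname(cov2cor(sig0)), diag(4))
  # eigen check against an independent eigensolver on a hub graph
  star <- matrix(0L, 6, 6); star[1, 2:6] <- 1L; star <- star + t(star)
  sig_s <- covariance_from_network(star, 0.3, 1)
  expect_gt(min(eigen(sig_s, symmetric = TRUE)$values), 0)
  # star with 25 leaves has lambda_min = -5: weight 1, load 1 is not PD
  big_star <- matrix(0L, 26, 26); big_star[1, 2:26] <- 1L
  big_star <- big_star + t(big_star)
  expect_error(covariance_from_network(big_star, 1, 1), "positive definite")
})

test_that("sample_bold matches its target covariance and is deterministic", {
  sig <- matrix(c(1, 0.3, 0.3, 1), 2)
  b <- sample_bold(sig, 50000, seed = 7)
  expect_lt(abs(cor(b$data[1, ], b$data[2, ]) - 0.3), 0.02)
  b2 <- sample_bold(sig, 50000, seed = 7)
  expect_identical(b$data, b2$data)
  # diagonal covariance: off-diagonal |r| < 3/sqrt(T) for >= 95% of pairs
  tlen <- 400
  bd <- sample_bold(diag(20), tlen, seed = 8)
  r <- cor(t(bd$data))
  offd <- abs(r[upper.tri(r)])
  expect_gte(mean(offd < 3 / sqrt(tlen)), 0.95)
})

test_that("generate_motion bounds FD below threshold except at spikes", {
  m0 <- generate_motion(50, jitter = 0)
  expect_equal(compute_fd(m0), rep(0, 50))
  m <- generate_motion(100, spike_volumes = 50, spike_mm = 0.8, seed = 2)
  fd <- compute_fd(m)
  expect_gte(fd[50], 0.8)
  expect_true(all(fd[-50] < 0.5))
  expect_error(generate_motion(100, spike_volumes = 1), "volume 1")
  expect_error(generate_motion(100, spike_volumes = 101), "beyond")
})

test_that("generate_cohort plants a deterministic, consistent cohort", {
  cfg <- cohort_config(n_control = 4, n_patient = 4, v = 64,
                       n_volumes = 130, seed = 5)
  co <- generate_cohort(cfg)
  expect_s3_class(co, "hd_cohort")
  expect_equal(nrow(co$phenotype), 8)
  expect_true(all(co$phenotype$fma_baseline[co$phenotype$group == "patient"]
                  >= 0))
  expect_true(all(co$phenotype$fma_followup[co$phenotype$group == "patient"]
                  <= 66))
  gt <- co$ground_truth
  expect_length(gt$kappa_true, 4)
  expect_true(all(gt$roi_voxel_ids %in% seq_len(64)))
  expect_gt(min(eigen(gt$reference_covariance, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  # bit-identical regeneration from the same master seed
  co2 <- generate_cohort(cfg)
  expect_identical(co$phenotype, co2$phenotype)
  expect_identical(co$subjects[[3]]$bold$data, co2$subjects[[3]]$bold$data)
})

test_that("behavioural coupling follows the configured sign and strength", {
  # zero coupling: planted degree and baseline score unrelated
  rhos <- vapply(1:12, function(s) {
    co <- generate_cohort(cohort_config(
      n_control = 3, n_patient = 80, v = 64, n_volumes = 130,
      coupling_baseline = 0, coupling_recovery = 0, seed = s))
    pat <- co$phenotype$group == "patient"
    cor(co$ground_truth$roi_degree_true, co$phenotype$fma_baseline[pat],
        method = "spearman")
  }, 0)
  expect_gte(mean(abs(rhos) < 0.3), 11 / 12)
  expect_lt(abs(mean(rhos)), 0.15)
  # strong negative coupling, noise -> 0: rho -> -1
  co <- generate_cohort(cohort_config(
    n_control = 3, n_patient = 30, v = 64, n_volumes = 130,
    coupling_baseline = -3, baseline_noise = 1e-6, seed = 2))
  pat <- co$phenotype$group == "patient"
  expect_lt(cor(co$ground_truth$roi_degree_true,
                co$phenotype$fma_baseline[pat], method = "spearman"), -0.95)
})

test_that("planted edges are recoverable from long noise-free series", {
  v <- 64
  a <- generate_reference_network(v, 0.1, seed = 9)
  load <- max(1, 1.1 * 0.3 * (abs(min(eigen(a, symmetric = TRUE,
                                            only.values = TRUE)$values)) - 1))
  sig <- covariance_from_network(a, 0.3, load)
  b <- sample_bold(sig, 2000, seed = 10)
  z <- correlation_matrix(b$data)
  net <- threshold_by_density(z, 0.1)
  hits <- sum(net$adjacency == 1 & a == 1) / sum(a)
  expect_gte(hits, 0.9)
})
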