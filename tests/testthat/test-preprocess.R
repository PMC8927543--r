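make_bold <- function(v = 8, tlen = 60, seed = 1, tr = 2.5) {
  set.seed(seed)
  bold_series(matrix(rnorm(v * tlen), v), toy_grid(v), tr = tr)
}

test_that("discard_initial drops exactly the first n volumes", {
  b <- make_bold(tlen = 230)
  expect_equal(ncol(discard_initial(b, 4)$data), 226)
  expect_equal(discard_initial(b, 4)$data, b$data[, 5:230])
  b5 <- make_bold(tlen = 5)
  expect_equal(ncol(discard_initial(b5, 4)$data), 1)
  expect_error(discard_initial(make_bold(tlen = 4), 4), "volumes")
})

test_that("compute_fd applies the 50x rotation scaling", {
  expect_equal(compute_fd(matrix(1, 10, 6)), rep(0, 10))
  m <- matrix(0, 2, 6)
  m[2, 1:3] <- c(0.1, 0.2, 0.1)
  m[2, 4:6] <- c(0.002, 0, 0.001)
  expect_equal(compute_fd(m), c(0, 0.4 + 50 * 0.003))
  # random-walk trace vs elementwise oracle
  set.seed(3)
  rw <- apply(matrix(rnorm(50 * 6, 0, 0.05), 50), 2, cumsum)
  fd <- compute_fd(rw)
  oracle <- sapply(2:50, function(t)
    sum(abs(rw[t, 1:3] - rw[t - 1, 1:3])) +
      50 * sum(abs(rw[t, 4:6] - rw[t - 1, 4:6])))
  expect_equal(fd, c(0, oracle))
  expect_error(compute_fd(matrix(c(NA, rep(1, 11)), 2)), "finite")
})

test_that("DVARS and SD series match their definitions", {
  x <- matrix(5, 4, 10)
  expect_warning(dv <- compute_dvars(x), "constant")
  expect_equal(dv, rep(0, 10))
  one <- matrix(c(0, 3, 3), 1)
  expect_equal(compute_dvars(one, normalize = FALSE), c(0, 3, 0))
  set.seed(4)
  g <- matrix(rnorm(200), 10, 20)
  raw <- compute_dvars(g, normalize = FALSE)
  oracle <- c(0, sapply(2:20, function(t) sqrt(mean((g[, t] - g[, t - 1])^2))))
  expect_equal(raw, oracle)
  # z-normalisation excludes the placeholder first volume
  z <- compute_dvars(g)
  expect_equal(mean(z[-1]), 0, tolerance = 1e-12)
  expect_equal(sd(z[-1]), 1, tolerance = 1e-12)
  # SD series: volume with doubled spread is the unique max
  xs <- matrix(rnorm(300), 15, 20)
  xs[, 7] <- xs[, 7] * 3
  sz <- compute_sd_series(xs)
  expect_equal(which.max(sz), 7)
  sraw <- compute_sd_series(xs, normalize = FALSE)
  expect_equal(sraw, apply(xs, 2, sd))
})

test_that("censor mask expands exceedances to i-2..i+2 with clipping", {
  fd <- rep(0, 10); fd[5] <- 0.7
  z0 <- rep(0, 10)
  expect_equal(which(build_censor_mask(fd, z0, z0)), 3:7)
  fd1 <- rep(0, 10); fd1[1] <- 0.7
  expect_equal(which(build_censor_mask(fd1, z0, z0)), 1:3)
  expect_equal(sum(build_censor_mask(rep(0, 10), z0, z0)), 0)
  # union of overlapping expansions
  fd2 <- rep(0, 30); fd2[c(20, 21)] <- 1
  expect_equal(which(build_censor_mask(fd2, rep(0, 30), rep(0, 30))), 18:23)
  # DVARS criterion triggers independently
  dz <- rep(0, 10); dz[8] <- 3
  expect_equal(which(build_censor_mask(rep(0, 10), dz, z0)), 6:10)
})

test_that("censoring is idempotent on retained volumes", {
  set.seed(9)
  b <- make_bold(v = 12, tlen = 120)
  motion <- generate_motion(120, spike_volumes = c(40, 80), spike_mm = 1,
                            seed = 2)
  cr <- censor_record(b$data, motion)
  keep <- !cr$censored
  cr2 <- censor_record(b$data[, keep, drop = FALSE],
                       motion[keep, , drop = FALSE])
  # FD at splice points can exceed, but the original exceedances are gone
  fd_keep <- compute_fd(motion)[keep]
  expect_true(all(fd_keep < 0.5))
  expect_equal(cr$n_retained, sum(keep))
})

test_that("nuisance regression projects out the regressors", {
  set.seed(5)
  tlen <- 40
  nuis <- list(motion = matrix(rnorm(tlen * 6), tlen),
               csf = rnorm(tlen), wm = rnorm(tlen), global = rnorm(tlen))
  # data equal to a regressor -> residuals ~ 0
  x <- matrix(rep(nuis$csf, each = 3), 3, byrow = FALSE)
  x <- rbind(nuis$csf, nuis$wm, t(nuis$motion)[1, , drop = FALSE])
  res <- regress_nuisance(x, nuis)
  expect_lt(max(abs(res)), 1e-10)
  # random data: residuals orthogonal to every regressor
  y <- matrix(rnorm(5 * tlen), 5)
  ry <- regress_nuisance(y, nuis)
  xmat <- cbind(1, nuis$motion, nuis$csf, nuis$wm, nuis$global)
  expect_lt(max(abs(ry %*% xmat)), 1e-8 * max(abs(y)) * max(abs(xmat)) * tlen)
  # affine rescaling of a regressor leaves residuals unchanged
  nuis2 <- nuis; nuis2$csf <- 5 * nuis$csf + 2
  expect_equal(regress_nuisance(y, nuis2), ry, tolerance = 1e-9)
  # collinearity -> warning, not error
  nuis3 <- nuis; nuis3$wm <- nuis$csf
  expect_warning(regress_nuisance(y, nuis3), "rank")
})

test_that("band-pass passes 0.05 Hz, rejects DC and the aliased band", {
  tr <- 2.5; tlen <- 226
  tt <- (seq_len(tlen) - 1) * tr
  # amplitude at the response frequency (frequency-response evaluation):
  # a 0.25 Hz tone sampled at 0.4 Hz arrives aliased at 0.15 Hz
  ampfit <- function(f_in, f_resp = f_in) {
    x <- sin(2 * pi * f_in * tt)
    y <- as.numeric(temporal_filter(matrix(x, 1), tr))
    b <- coef(lm(y ~ sin(2 * pi * f_resp * tt) + cos(2 * pi * f_resp * tt)))
    sqrt(sum(b[2:3]^2))
  }
  expect_gte(ampfit(0.05), 0.90)
  expect_lte(ampfit(0.25, 0.15), 0.05)
  const <- temporal_filter(matrix(7, 2, tlen), tr)
  expect_lt(max(abs(const)), 1e-8)
  # high-pass mode removes drift but keeps mid-band content
  drift <- matrix(seq(0, 1, length.out = tlen), 1)
  hp <- temporal_filter(drift, tr, type = "high")
  expect_lt(sd(hp), 0.1 * sd(drift))
  expect_gte(sd(temporal_filter(matrix(sin(2 * pi * 0.05 * tt), 1), tr,
                                type = "high")) / sd(sin(2 * pi * 0.05 * tt)),
             0.90)
})

test_that("scrubbing removes exactly the censored columns", {
  set.seed(6)
  x <- matrix(rnorm(10 * 226), 10)
  cen <- rep(FALSE, 226); cen[3:7] <- TRUE
  out <- apply_scrubbing(x, cen)
  expect_equal(ncol(out), 221)
  expect_identical(out, x[, -(3:7)])
  expect_identical(apply_scrubbing(x, rep(FALSE, 226)), x)
  expect_error(apply_scrubbing(x, rep(TRUE, 226)), "retained")
})

test_that("QC rule fails below 120 retained volumes", {
  expect_false(qc_check(119))
  expect_true(qc_check(120))
  expect_true(qc_check(226))
})

test_that("downsampling block-averages factor^3 neighbourhoods", {
  coords <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  vals <- matrix(seq_len(27), 27, 2)
  b <- bold_series(vals, coords, voxel_size = 2, tr = 2.5)
  d <- downsample_grid(b, 3)
  expect_equal(nrow(d$data), 1)
  expect_equal(unname(d$data[1, 1]), mean(1:27))
  expect_equal(d$voxel_size, 6)
  expect_identical(downsample_grid(b, 1), b)
  # constant image stays constant
  bc <- bold_series(matrix(4, 27, 3), coords, tr = 2.5)
  expect_true(all(downsample_grid(bc, 3)$data == 4))
})

test_that("full preprocessing chain runs, logs settings and applies QC", {
  cfg <- cohort_config(n_control = 3, n_patient = 3, v = 27,
                       n_volumes = 140, seed = 12)
  co <- generate_cohort(cfg)
  s <- co$subjects[[4]]
  pp <- preprocess_subject(s$bold, s$motion)
  expect_s3_class(pp, "hd_clean")
  expect_equal(ncol(pp$bold$data), pp$censor$n_retained)
  expect_true(all(c("fd_thr", "z_thr", "band", "order") %in% names(pp$log)))
  # spike volumes (post-discard indices) are censored
  sp <- s$spike_volumes - 4
  sp <- sp[sp >= 1]
  expect_true(all(pp$censor$censored[sp]))
})
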