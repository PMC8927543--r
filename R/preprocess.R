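#' Discard initial volumes
#'
#' Drops the first `n` volumes of a run (scanner equilibration), keeping the
#' remaining columns in order.
#'
#' @param bold a [bold_series].
#' @param n number of volumes to discard (default 4).
#' @return The shortened [bold_series].
#' @export
discard_initial <- function(bold, n = 4) {
  tlen <- ncol(bold$data)
  if (tlen <= n) stop("fewer than n + 1 volumes available", call. = FALSE)
  bold$data <- bold$data[, (n + 1):tlen, drop = FALSE]
  bold
}

#' Framewise displacement from a six-parameter motion trace
#'
#' `FD_t = sum |delta translations| + 50 * sum |delta rotations|`, the
#' rotational term scaled by 50 to convert radians to millimetre-like units.
#' Columns 1-3 are translations (mm), 4-6 rotations (radians). `FD_1 = 0` by
#' convention: the backward difference is undefined at the first volume.
#'
#' @param motion `T x 6` numeric matrix.
#' @return Numeric length-T vector of FD in mm.
#' @export
compute_fd <- function(motion) {
  motion <- as.matrix(motion)
  stop_if_not(ncol(motion) == 6, "motion must have 6 columns")
  stop_if_not(nrow(motion) >= 2, "need at least 2 volumes")
  if (!all(is.finite(motion))) stop("non-finite motion values", call. = FALSE)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE]))
}

# z-normalise a backward-difference series over t >= 2 (t = 1 is a
# placeholder, excluded from the mean/sd).
znorm_skip_first <- function(x) {
  body <- x[-1]
  s <- sd(body)
  if (!is.finite(s) || s == 0) {
    warning("constant series: z-scores undefined, returning zeros",
            call. = FALSE)
    return(rep(0, length(x)))
  }
  z <- (x - mean(body)) / s
  z[1] <- 0
  z
}

#' DVARS of a BOLD matrix
#'
#' Root-mean-square over mask voxels of the backward temporal difference,
#' per volume; `DVARS_1 := 0`. The returned series is z-normalised over
#' volumes 2..T (mean 0, sd 1); set `normalize = FALSE` for the raw series.
#'
#' @param data V x T matrix.
#' @param gm_mask logical or integer index of mask voxels (default: all).
#' @param normalize z-normalise the output (default TRUE).
#' @return Numeric length-T vector.
#' @export
compute_dvars <- function(data, gm_mask = NULL, normalize = TRUE) {
  stop_if_not(ncol(data) >= 2, "need at least 2 volumes")
  x <- if (is.null(gm_mask)) data else data[gm_mask, , drop = FALSE]
  stop_if_not(nrow(x) >= 1, "mask is empty")
  dv <- c(0, sqrt(colMeans((x[, -1, drop = FALSE] -
                              x[, -ncol(x), drop = FALSE])^2)))
  if (normalize) znorm_skip_first(dv) else dv
}

#' Per-volume intensity standard deviation
#'
#' Standard deviation of intensity across mask voxels for each volume,
#' z-normalised over volumes 2..T for symmetry with [compute_dvars()] (the
#' raw series is well defined at t = 1 but the first volume never triggers
#' censoring).
#'
#' @inheritParams compute_dvars
#' @return Numeric length-T vector.
#' @export
compute_sd_series <- function(data, gm_mask = NULL, normalize = TRUE) {
  x <- if (is.null(gm_mask)) data else data[gm_mask, , drop = FALSE]
  stop_if_not(nrow(x) >= 1, "mask is empty")
  s <- apply(x, 2, sd)
  if (normalize) znorm_skip_first(s) else s
}

#' Motion/artefact censoring mask
#'
#' Flags any volume with FD above `fd_thr`, or z-normalised DVARS or SD
#' above `z_thr`, then expands each flagged volume i to its four temporal
#' neighbours `{i-2, i-1, i, i+1, i+2}` (clipped to `[1, T]`).
#'
#' @param fd FD series (mm).
#' @param dvars_z,sd_z z-normalised DVARS and SD series.
#' @param fd_thr FD threshold in mm (default 0.5).
#' @param z_thr z threshold for DVARS and SD (default 2.3).
#' @return Logical length-T vector, `TRUE` where censored.
#' @export
build_censor_mask <- function(fd, dvars_z, sd_z, fd_thr = 0.5, z_thr = 2.3) {
  tlen <- length(fd)
  stop_if_not(length(dvars_z) == tlen && length(sd_z) == tlen,
              "series must have equal length")
  bad <- which(fd > fd_thr | dvars_z > z_thr | sd_z > z_thr)
  censored <- logical(tlen)
  for (i in bad) censored[max(1, i - 2):min(tlen, i + 2)] <- TRUE
  censored
}

#' Full censoring record for one subject
#'
#' Convenience wrapper producing the `censor_record` used by QC and
#' reporting: FD, z-normalised DVARS/SD, the expanded censor mask and the
#' retained-volume count.
#'
#' @param data V x T BOLD matrix (the data entering the censoring step).
#' @param motion `T x 6` motion trace aligned to `data`.
#' @param gm_mask mask voxels for DVARS/SD.
#' @param fd_thr,z_thr thresholds as in [build_censor_mask()].
#' @return A list of class `censor_record` with fields `fd`, `dvars_z`,
#'   `sd_z`, `censored`, `n_retained`.
#' @export
censor_record <- function(data, motion, gm_mask = NULL,
                          fd_thr = 0.5, z_thr = 2.3) {
  fd <- compute_fd(motion)
  dv <- compute_dvars(data, gm_mask)
  sdz <- compute_sd_series(data, gm_mask)
  censored <- build_censor_mask(fd, dv, sdz, fd_thr, z_thr)
  structure(list(fd = fd, dvars_z = dv, sd_z = sdz, censored = censored,
                 n_retained = sum(!censored)),
            class = "censor_record")
}

#' @export
print.censor_record <- function(x, ...) {
  cat(sprintf("<censor_record> %d/%d volumes retained (max FD %.3f mm)\n",
              x$n_retained, length(x$fd), max(x$fd)))
  invisible(x)
}

#' Regress nuisance signals out of every voxel
#'
#' Ordinary least squares of each voxel's series on an intercept plus the
#' nine nuisance regressors (six motion parameters, CSF, white matter,
#' global signal); residuals are returned. Collinear regressors are handled
#' by the pseudo-inverse with a warning.
#'
#' @param data V x T matrix.
#' @param nuisance list with `motion` (T x 6), `csf`, `wm`, `global`
#'   (length-T vectors); any element may be omitted.
#' @return Residual V x T matrix.
#' @export
regress_nuisance <- function(data, nuisance) {
  tlen <- ncol(data)
  xs <- list(intercept = rep(1, tlen))
  if (!is.null(nuisance$motion)) {
    stop_if_not(nrow(nuisance$motion) == tlen, "motion length mismatch")
    xs$motion <- as.matrix(nuisance$motion)
  }
  for (nm in c("csf", "wm", "global")) {
    if (!is.null(nuisance[[nm]])) {
      stop_if_not(length(nuisance[[nm]]) == tlen,
                  paste(nm, "length mismatch"))
      xs[[nm]] <- nuisance[[nm]]
    }
  }
  x <- do.call(cbind, xs)
  if (!all(is.finite(x))) stop("non-finite nuisance regressors",
                               call. = FALSE)
  stop_if_not(tlen > 10, "need more than 10 volumes for nuisance regression")
  q <- qr(x)
  if (q$rank < ncol(x))
    warning("rank-deficient nuisance set; using pseudo-inverse",
            call. = FALSE)
  # projection via SVD pseudo-inverse (robust to collinearity)
  sv <- svd(x)
  keep <- sv$d > max(sv$d) * 1e-10
  u <- sv$u[, keep, drop = FALSE]
  data - (data %*% u) %*% t(u)
}

#' Zero-phase Butterworth temporal filter
#'
#' Applies a 4th-order Butterworth band-pass (default 0.008-0.1 Hz) to
#' every voxel series with zero phase: the series is demeaned and its
#' spectrum multiplied by the squared Butterworth magnitude response — the
#' exact transfer function of a forward-backward pass, which doubles the
#' effective order and cancels phase distortion that would otherwise
#' corrupt the correlation structure. The frequency-domain application is
#' numerically exact even at the very low 0.008 Hz edge, where a recursive
#' realisation is nearly unstable. `type = "high"` gives the high-pass-only
#' stage (cut-off `low`).
#'
#' @param data V x T matrix.
#' @param tr repetition time in seconds.
#' @param low,high band edges in Hz.
#' @param order filter order (per direction; the zero-phase pass squares
#'   the response).
#' @param type "band" or "high".
#' @return Filtered V x T matrix.
#' @export
temporal_filter <- function(data, tr, low = 0.008, high = 0.1, order = 4,
                            type = c("band", "high")) {
  type <- match.arg(type)
  nyq <- 1 / (2 * tr)
  stop_if_not(low > 0 && low < nyq, "low cut-off outside (0, Nyquist)")
  if (type == "band")
    stop_if_not(high > low && high < nyq, "high cut-off outside (low, Nyquist)")
  tlen <- ncol(data)
  stop_if_not(tlen >= 16, "series too short for temporal filtering")
  # even periodic extension [x, reverse(x)] (period 2T): continuous at both
  # the junction and the wrap point, so circular filtering sees no jumps
  mu <- rowMeans(data)
  x <- data - mu
  xp <- cbind(x, x[, tlen:1, drop = FALSE])
  np <- ncol(xp)
  freqs <- (seq_len(np) - 1) / (np * tr)
  freqs <- pmin(freqs, 1 / tr - freqs) # two-sided spectrum
  hmag2 <- 1 / (1 + (freqs / low)^(-2 * order)) # high-pass |H|^2
  if (type == "band") hmag2 <- hmag2 / (1 + (freqs / high)^(2 * order))
  xf <- t(stats::mvfft(t(xp)))
  filt <- Re(t(stats::mvfft(t(xf * rep(hmag2, each = nrow(xp))),
                            inverse = TRUE))) / np
  out <- filt[, seq_len(tlen), drop = FALSE]
  dimnames(out) <- dimnames(data)
  out
}

#' Delete censored volumes
#'
#' Removes the censored columns, preserving the order (and values) of the
#' retained ones.
#'
#' @param data V x T matrix.
#' @param censored logical length-T censor mask.
#' @return V x T' matrix with censored columns removed.
#' @export
apply_scrubbing <- function(data, censored) {
  stop_if_not(length(censored) == ncol(data), "mask length mismatch")
  if (sum(!censored) < 2) stop("fewer than 2 retained volumes",
                               call. = FALSE)
  data[, !censored, drop = FALSE]
}

# Replace censored columns by linear interpolation between retained
# neighbours (constant extrapolation at the ends), giving the band-pass a
# uniform sampling grid before the censored columns are finally deleted.
interpolate_censored <- function(data, censored) {
  if (!any(censored)) return(data)
  tlen <- ncol(data)
  keep <- which(!censored)
  t(apply(data, 1, function(x)
    approx(keep, x[keep], xout = seq_len(tlen), rule = 2)$y))
}

#' Minimum-retained-volumes quality control
#'
#' A subject fails QC when fewer than `minimum` volumes survive censoring
#' (the default 120 guarantees five minutes of usable data at TR = 2.5 s).
#'
#' @param n_retained retained-volume count.
#' @param minimum minimum acceptable count (default 120).
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
qc_check <- function(n_retained, minimum = 120) {
  stop_if_not(n_retained >= 0, "n_retained must be non-negative")
  n_retained >= minimum
}

#' Block-mean spatial downsampling
#'
#' Aggregates `factor^3` grid neighbourhoods by their mean, as a stand-in
#' for resampling to a coarser grid; coordinates are re-indexed to the
#' coarse grid and the voxel size multiplied by `factor`. Voxels whose
#' block is only partially present are averaged over the voxels available.
#'
#' @param bold a [bold_series].
#' @param factor integer downsampling factor (1 = identity).
#' @return A [bold_series] on the coarse grid.
#' @export
downsample_grid <- function(bold, factor = 3) {
  stop_if_not(factor >= 1, "factor must be >= 1")
  if (factor == 1) return(bold)
  block <- (bold$coords - 1) %/% factor + 1
  key <- paste(block[, 1], block[, 2], block[, 3])
  groups <- split(seq_len(nrow(block)), key)
  newdata <- t(vapply(groups, function(ix)
    colMeans(bold$data[ix, , drop = FALSE]), numeric(ncol(bold$data))))
  newcoords <- t(vapply(groups, function(ix) block[ix[1], ], numeric(3)))
  bold_series(newdata, newcoords, voxel_size = bold$voxel_size * factor,
              tr = bold$tr)
}

#' Run the full scrubbing-based cleaning chain on one subject
#'
#' Fixed stage order: discard initial volumes, grand-mean intensity
#' normalisation (global mean 10,000), high-pass (0.008 Hz), nuisance
#' regression (6 motion + CSF + WM + global), censor detection on the data
#' entering this step, linear interpolation of censored volumes, zero-phase
#' band-pass (0.008-0.1 Hz), and final deletion of the censored volumes.
#' Interpolation restores uniform sampling so the band-pass retains its
#' frequency interpretation while the censored volumes still never enter
#' the connectivity estimate.
#'
#' @param bold a [bold_series].
#' @param motion `T x 6` motion trace (pre-discard length).
#' @param gm_mask,csf_mask,wm_mask voxel index/logical masks; `gm_mask`
#'   defaults to all voxels, the others to `NULL` (regressor skipped).
#' @param n_discard initial volumes to discard.
#' @param fd_thr,z_thr censoring thresholds.
#' @param low,high band-pass edges in Hz.
#' @param qc_minimum minimum retained volumes.
#' @return List of class `hd_clean`: `bold` (cleaned, censored volumes
#'   removed), `censor` (a `censor_record`), `qc_pass`, and `log` (the
#'   stage settings actually used).
#' @export
preprocess_subject <- function(bold, motion, gm_mask = NULL, csf_mask = NULL,
                               wm_mask = NULL, n_discard = 4, fd_thr = 0.5,
                               z_thr = 2.3, low = 0.008, high = 0.1,
                               qc_minimum = 120) {
  stop_if_not(nrow(motion) == ncol(bold$data),
              "motion trace must match the pre-discard volume count")
  b <- discard_initial(bold, n_discard)
  mot <- motion[(n_discard + 1):nrow(motion), , drop = FALSE]
  # grand-mean scaling to 10,000 (conventional; invisible to correlations)
  gm <- mean(b$data)
  if (gm > 0) b$data <- b$data * (10000 / gm)
  x <- temporal_filter(b$data, b$tr, low = low, type = "high")
  nuis <- list(motion = mot,
               csf = if (!is.null(csf_mask))
                 colMeans(b$data[csf_mask, , drop = FALSE]),
               wm = if (!is.null(wm_mask))
                 colMeans(b$data[wm_mask, , drop = FALSE]),
               global = colMeans(b$data))
  x <- regress_nuisance(x, nuis)
  cens <- censor_record(x, mot, gm_mask = gm_mask,
                        fd_thr = fd_thr, z_thr = z_thr)
  x <- interpolate_censored(x, cens$censored)
  x <- temporal_filter(x, b$tr, low = low, high = high, type = "band")
  x <- apply_scrubbing(x, cens$censored)
  b$data <- x
  structure(list(
    bold = b, censor = cens,
    qc_pass = qc_check(cens$n_retained, qc_minimum),
    log = list(n_discard = n_discard, grand_mean_target = 10000,
               fd_thr = fd_thr, z_thr = z_thr, band = c(low, high),
               filter = "butterworth order 4, zero-phase",
               censor_expansion = 2, qc_minimum = qc_minimum,
               order = c("discard", "grand-mean", "high-pass",
                         "nuisance", "censor-detect", "interpolate",
                         "band-pass", "scrub"))),
    class = "hd_clean")
}

#' @export
print.hd_clean <- function(x, ...) {
  cat(sprintf("<hd_clean> %d voxels x %d volumes retained; QC %s\n",
              nrow(x$bold$data), ncol(x$bold$data),
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}
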