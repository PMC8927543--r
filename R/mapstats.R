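#' Neighbour graph of a voxel grid
#'
#' Adjacency list linking voxels whose grid coordinates differ by at most
#' one step: 26-connectivity uses the Chebyshev metric (faces, edges,
#' corners), 6-connectivity the city-block metric (faces only).
#'
#' @param coords V x 3 integer grid coordinates.
#' @param connectivity 26 (default) or 6.
#' @return List of integer vectors (1-based neighbour indices).
#' @export
grid_neighbors <- function(coords, connectivity = 26) {
  stop_if_not(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  coords <- as.matrix(coords)
  v <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  index <- stats::setNames(seq_len(v), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lapply(seq_len(v), function(i) {
    nb <- sweep(offs, 2, coords[i, ], "+")
    hit <- index[paste(nb[, 1], nb[, 2], nb[, 3])]
    as.integer(sort(unname(hit[!is.na(hit)])))
  })
}

#' Per-voxel GLM t statistic for a group contrast
#'
#' Ordinary least squares of every voxel column on the design, returning
#' the t statistic of the requested contrast. Voxels with (numerically)
#' zero residual variance but a non-zero contrast are flagged saturated and
#' reported as `Inf` of the appropriate sign.
#'
#' @param maps subjects x V matrix.
#' @param design data frame or matrix of predictors (an intercept is added;
#'   character/factor columns are coded numerically).
#' @param contrast numeric vector over the design columns (intercept
#'   excluded), e.g. `c(1, 0, 0)` for the first predictor.
#' @return Numeric length-V vector with attribute `saturated`.
#' @export
glm_tstat_map <- function(maps, design, contrast) {
  maps <- as.matrix(maps)
  x <- design_matrix(design)
  n <- nrow(maps)
  stop_if_not(nrow(x) == n, "design rows must match subjects")
  p <- ncol(x)
  stop_if_not(n > p, "need more subjects than design columns")
  cvec <- c(0, contrast)
  stop_if_not(length(cvec) == p, "contrast length must match design columns")
  xtxi <- solve(crossprod(x))
  if (!all(is.finite(xtxi))) stop("rank-deficient design", call. = FALSE)
  bhat <- xtxi %*% crossprod(x, maps)
  res <- maps - x %*% bhat
  sigma2 <- colSums(res^2) / (n - p)
  eff <- as.numeric(crossprod(cvec, bhat))
  vc <- as.numeric(crossprod(cvec, xtxi %*% cvec))
  se <- sqrt(sigma2 * vc)
  tt <- eff / se
  saturated <- se < 1e-10 * (abs(eff) + 1e-300) & abs(eff) > 0
  tt[saturated] <- sign(eff[saturated]) * Inf
  tt[se == 0 & eff == 0] <- 0
  attr(tt, "saturated") <- saturated
  tt
}

design_matrix <- function(design) {
  if (is.matrix(design)) return(cbind(intercept = 1, design))
  d <- as.data.frame(design)
  d[] <- lapply(d, function(col)
    if (is.numeric(col)) col else as.numeric(factor(col)) - 1)
  cbind(intercept = 1, as.matrix(d))
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ...`, where `e(h, v)` is the size of the supra-threshold
#' connected component containing v. The negative tail is enhanced by
#' applying the same transform to the negated map, and returned with a
#' negative sign, so the output is signed like the input.
#'
#' @param stat numeric length-V statistic map.
#' @param neighbors adjacency list from [grid_neighbors()] (or coordinates,
#'   from which 26-connectivity neighbours are built).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(abs(stat)) / 100`.
#' @return Numeric length-V signed enhanced map.
#' @export
tfce_transform <- function(stat, neighbors, E = 0.5, H = 2, dh = NULL) {
  if (is.matrix(neighbors) || is.data.frame(neighbors))
    neighbors <- grid_neighbors(neighbors)
  mx <- max(abs(stat))
  if (mx == 0) return(numeric(length(stat)))
  if (is.null(dh)) dh <- mx / 100
  stop_if_not(dh > 0, "dh must be positive")
  pos <- .cpp_tfce(pmax(stat, 0), neighbors, E, H, dh)
  neg <- .cpp_tfce(pmax(-stat, 0), neighbors, E, H, dh)
  pos - neg
}

#' Permutation inference with TFCE and family-wise error correction
#'
#' Freedman-Lane scheme: the maps are residualised on the nuisance
#' covariates, residual rows are permuted, the reduced-model fit is added
#' back, and the full-model contrast t map plus its TFCE enhancement are
#' recomputed; the maximum enhanced statistic per permutation forms the
#' null. `p_fwe(v) = (1 + #{perm max >= observed})/(n_perm + 1)` — the
#' add-one convention keeps the p values valid (never exactly 0). Both
#' contrast directions are reported. When the requested permutation count
#' reaches the number of distinct row permutations, all of them are
#' enumerated instead (noted in the result).
#'
#' @param maps subjects x V matrix.
#' @param design data frame/matrix; first column is the predictor of
#'   interest, remaining columns are nuisance covariates.
#' @param contrast direction over design columns as in [glm_tstat_map()].
#' @param neighbors adjacency list or V x 3 coordinates for TFCE.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param E,H,dh TFCE parameters (dh defaults to max/100 per map).
#' @return Object of class `stat_map`: `stat`, `tfce`, `p_fwe_pos`,
#'   `p_fwe_neg`, `max_null_pos`, `max_null_neg`, `n_perm`, `exhaustive`.
#' @export
permutation_fwe <- function(maps, design, contrast, neighbors,
                            n_perm = 5000, seed = 1, E = 0.5, H = 2,
                            dh = NULL) {
  maps <- as.matrix(maps)
  if (is.matrix(neighbors) || is.data.frame(neighbors))
    neighbors <- grid_neighbors(neighbors)
  x <- design_matrix(design)
  n <- nrow(maps)
  stop_if_not(nrow(x) == n, "design rows must match subjects")
  cvec <- c(0, contrast)
  nz <- which(cvec != 0)
  z <- x[, -nz, drop = FALSE] # reduced (nuisance) model
  hz <- z %*% solve(crossprod(z), t(z))
  fitted_red <- hz %*% maps
  resid_red <- maps - fitted_red

  tfce_of <- function(tt) {
    mx <- max(abs(tt[is.finite(tt)]), 0)
    tt[!is.finite(tt)] <- sign(tt[!is.finite(tt)]) * mx
    step <- dh %||% (max(abs(tt)) / 100)
    if (max(abs(tt)) == 0) return(numeric(length(tt)))
    list(pos = .cpp_tfce(pmax(tt, 0), neighbors, E, H, step),
         neg = .cpp_tfce(pmax(-tt, 0), neighbors, E, H, step))
  }

  t_obs <- glm_tstat_map(maps, design, contrast)
  obs <- tfce_of(t_obs)

  exhaustive <- FALSE
  nf <- suppressWarnings(factorial(n))
  if (is.finite(nf) && nf <= n_perm) {
    perms <- asplit(perm_all(n), 1)
    n_perm <- length(perms)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  }

  max_pos <- numeric(n_perm)
  max_neg <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ystar <- fitted_red + resid_red[perms[[b]], , drop = FALSE]
    tt <- glm_tstat_map(ystar, design, contrast)
    en <- tfce_of(tt)
    max_pos[b] <- max(en$pos)
    max_neg[b] <- max(en$neg)
  }
  p_pos <- vapply(obs$pos, function(o) (1 + sum(max_pos >= o)) / (n_perm + 1),
                  0)
  p_neg <- vapply(obs$neg, function(o) (1 + sum(max_neg >= o)) / (n_perm + 1),
                  0)
  structure(list(stat = t_obs, tfce = obs$pos - obs$neg,
                 p_fwe_pos = p_pos, p_fwe_neg = p_neg,
                 max_null_pos = max_pos, max_null_neg = max_neg,
                 n_perm = n_perm, exhaustive = exhaustive),
            class = "stat_map")
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> %d voxels, %d permutations%s; min p_fwe: %.4g (pos) %.4g (neg)\n",
    length(x$stat), x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
    min(x$p_fwe_pos), min(x$p_fwe_neg)))
  invisible(x)
}

#' Cluster table of significant voxels
#'
#' Connected components (26-connectivity by default) of the voxels with
#' `p_fwe < alpha`; per cluster the peak statistic, its grid coordinate,
#' and the size in voxels and mm^3.
#'
#' @param stat length-V statistic map.
#' @param p_fwe length-V corrected p values.
#' @param coords V x 3 grid coordinates.
#' @param alpha significance level (default 0.05).
#' @param connectivity 26 or 6.
#' @param voxel_volume volume of one voxel in mm^3 (default 216 = 6 mm
#'   isotropic).
#' @return Data frame with one row per cluster: `cluster`, `n_voxels`,
#'   `size_mm3`, `peak_x`, `peak_y`, `peak_z`, `peak_stat`, `min_p`.
#' @export
extract_clusters <- function(stat, p_fwe, coords, alpha = 0.05,
                             connectivity = 26, voxel_volume = 216) {
  stop_if_not(length(stat) == length(p_fwe), "maps must be aligned")
  nb <- grid_neighbors(coords, connectivity)
  lab <- .cpp_components(nb, p_fwe < alpha)
  ks <- setdiff(sort(unique(lab)), 0)
  if (!length(ks)) {
    return(data.frame(cluster = integer(), n_voxels = integer(),
                      size_mm3 = numeric(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      peak_stat = numeric(), min_p = numeric()))
  }
  rows <- lapply(ks, function(k) {
    ix <- which(lab == k)
    pk <- ix[which.max(abs(stat[ix]))]
    data.frame(cluster = k, n_voxels = length(ix),
               size_mm3 = length(ix) * voxel_volume,
               peak_x = coords[pk, 1], peak_y = coords[pk, 2],
               peak_z = coords[pk, 3], peak_stat = stat[pk],
               min_p = min(p_fwe[ix]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_voxels), , drop = FALSE]
}
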