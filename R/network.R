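#' Fisher-z correlation matrix of voxel time series
#'
#' Pairwise Pearson correlations of the rows of `data`, Fisher
#' z-transformed (`z = atanh(r)` with `|r|` capped at `1 - 1e-7` so
#' duplicated series stay finite). Zero-variance voxels are flagged and all
#' their edges set to `-Inf`, so density thresholding never selects them;
#' the diagonal is `NA` and excluded from ranking.
#'
#' @param data V x T matrix (T >= 3).
#' @return V x V symmetric matrix of Fisher-z values with attribute
#'   `zero_variance` (logical length-V).
#' @export
correlation_matrix <- function(data) {
  stop_if_not(ncol(data) >= 3, "need at least 3 volumes")
  v <- nrow(data)
  sds <- apply(data, 1, sd)
  zero_var <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(t(data)))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  if (any(zero_var)) {
    z[zero_var, ] <- -Inf
    z[, zero_var] <- -Inf
  }
  diag(z) <- NA_real_
  attr(z, "zero_variance") <- zero_var
  z
}

#' Threshold a Fisher-z matrix at a fixed link density
#'
#' Retains the `L = round(density * V(V-1)/2)` strongest edges by signed z
#' (most-positive correlations first; set `absolute = TRUE` to rank by
#' `|z|`). Ties are broken by ascending `(i, j)` lexicographic order and the
#' rounding is half-up, so the edge set is deterministic across platforms.
#' Fixing the density rather than the correlation threshold equates network
#' cost across subjects.
#'
#' @param z_matrix V x V symmetric Fisher-z matrix (diagonal ignored).
#' @param density fraction of possible links to keep, in (0, 1].
#' @param coords optional V x 3 voxel grid coordinates carried on the result.
#' @param voxel_size grid step in mm.
#' @param absolute rank by `|z|` instead of signed z.
#' @return Object of class `functional_network`: list with binary symmetric
#'   `adjacency`, `density`, `coords`, `voxel_size`.
#' @export
threshold_by_density <- function(z_matrix, density, coords = NULL,
                                 voxel_size = 6, absolute = FALSE) {
  stop_if_not(density > 0 && density <= 1, "density must be in (0, 1]")
  v <- nrow(z_matrix)
  n_pairs <- v * (v - 1) / 2
  n_edges <- round_half_up(density * n_pairs)
  if (n_edges < 1) stop("density implies fewer than one edge", call. = FALSE)
  ut <- which(upper.tri(z_matrix))
  zv <- z_matrix[ut]
  if (absolute) zv <- abs(zv)
  zv[!is.finite(zv) & zv > 0] <- Inf # +Inf kept orderable; -Inf sinks
  # order: decreasing z, ties by ascending linear index = ascending (i, j)
  ord <- order(-zv, ut)
  keep <- ut[ord[seq_len(n_edges)]]
  a <- matrix(0L, v, v)
  a[keep] <- 1L
  a <- a + t(a)
  structure(list(adjacency = a, density = density,
                 coords = coords, voxel_size = voxel_size),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, %d edges (density %.3g)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density))
  invisible(x)
}

# Pairwise Euclidean distances between grid coordinates, in grid units.
coord_distances <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Distance-excluded degree map
#'
#' Counts, per voxel, the links to voxels farther than `exclusion_distance`
#' grid units away (Euclidean centre-to-centre; `chebyshev = TRUE` switches
#' to the maximum-coordinate metric). Short links are dominated by motion
#' and point-spread artefacts, so links within two adjacent voxels are
#' excluded by default; the edges remain in the network object itself.
#'
#' @param network a `functional_network` with coordinates.
#' @param exclusion_distance links at distance <= this (grid units) are not
#'   counted (default 2; 0 counts every link).
#' @param chebyshev use the Chebyshev metric instead of Euclidean.
#' @return Object of class `degree_map`: `values` (length-V counts),
#'   `exclusion_distance`, `density`, `coords`, `voxel_size`.
#' @export
degree_map <- function(network, exclusion_distance = 2, chebyshev = FALSE) {
  stop_if_not(!is.null(network$coords), "network carries no coordinates")
  a <- network$adjacency
  if (exclusion_distance > 0) {
    d <- if (chebyshev) {
      cmax <- network$coords
      dd <- matrix(0, nrow(cmax), nrow(cmax))
      for (k in 1:3) dd <- pmax(dd, abs(outer(cmax[, k], cmax[, k], "-")))
      dd
    } else coord_distances(network$coords)
    a <- a * (d > exclusion_distance)
  }
  structure(list(values = unname(rowSums(a)),
                 exclusion_distance = exclusion_distance,
                 density = network$density, coords = network$coords,
                 voxel_size = network$voxel_size),
            class = "degree_map")
}

#' @export
print.degree_map <- function(x, ...) {
  cat(sprintf(
    "<degree_map> %d voxels, mean degree %.2f (exclusion %g grid units)\n",
    length(x$values), mean(x$values), x$exclusion_distance))
  invisible(x)
}

#' ROI-seeded degree map
#'
#' For each voxel outside the ROI, the number of links (surviving the same
#' distance exclusion as [degree_map()]) to any ROI voxel; each ROI voxel
#' receives the count of its own extra-ROI links. The map therefore
#' satisfies the double-counting identity: the sum over non-ROI voxels
#' equals the sum over ROI voxels.
#'
#' @param network a `functional_network` with coordinates.
#' @param roi_mask logical length-V vector or integer indices of ROI voxels.
#' @param exclusion_distance as in [degree_map()].
#' @return A `degree_map`.
#' @export
roi_degree_map <- function(network, roi_mask, exclusion_distance = 2) {
  v <- nrow(network$adjacency)
  roi <- if (is.logical(roi_mask)) which(roi_mask) else as.integer(roi_mask)
  stop_if_not(length(roi) >= 1, "ROI is empty")
  if (length(roi) >= v) stop("ROI covers all voxels", call. = FALSE)
  a <- network$adjacency
  if (exclusion_distance > 0) {
    d <- coord_distances(network$coords)
    a <- a * (d > exclusion_distance)
  }
  vals <- numeric(v)
  outside <- setdiff(seq_len(v), roi)
  vals[outside] <- unname(rowSums(a[outside, roi, drop = FALSE]))
  vals[roi] <- unname(rowSums(a[roi, outside, drop = FALSE]))
  structure(list(values = vals, exclusion_distance = exclusion_distance,
                 density = network$density, coords = network$coords,
                 voxel_size = network$voxel_size, roi = roi),
            class = "degree_map")
}

#' Mean degree within a cluster
#'
#' @param map a `degree_map` (or plain numeric vector).
#' @param cluster_mask logical vector or integer indices of cluster voxels.
#' @return Scalar mean of the map over the cluster.
#' @export
mean_degree_in_cluster <- function(map, cluster_mask) {
  vals <- if (inherits(map, "degree_map")) map$values else map
  ix <- if (is.logical(cluster_mask)) which(cluster_mask)
        else as.integer(cluster_mask)
  if (!length(ix)) stop("empty cluster", call. = FALSE)
  mean(vals[ix])
}
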