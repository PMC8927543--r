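#' @useDynLib hubdisrupt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor lm pchisq pf pnorm pt quantile resid rnorm runif
#'   sd var median complete.cases plogis approx
#' @importFrom utils head read.csv write.csv read.table write.table
NULL

# Round-half-up: edge counts must be identical across platforms, and R's
# round() ties to even.
round_half_up <- function(x) floor(x + 0.5)

#' Derive a per-unit seed from a master seed
#'
#' All stochastic components of the package draw their seeds from one master
#' seed through this counter scheme, so that per-subject streams are
#' reproducible yet distinct: `seed_k = (master * 10007 + k) mod (2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param counter non-negative integer counter (e.g. subject index).
#' @return An integer seed suitable for [set.seed()].
#' @export
fan_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 10007 + as.numeric(counter)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Construct a BOLD series container
#'
#' A voxel-by-time matrix together with the voxel grid coordinates, the grid
#' step in millimetres and the repetition time.
#'
#' @param data numeric V x T matrix (voxels in rows, volumes in columns).
#' @param coords integer V x 3 matrix of voxel grid indices (1-based).
#' @param voxel_size grid step in mm (scalar, isotropic).
#' @param tr repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, coords, voxel_size = 6, tr = 2.5) {
  data <- as.matrix(data)
  coords <- as.matrix(coords)
  stop_if_not(nrow(data) == nrow(coords),
              "data and coords must describe the same voxels")
  stop_if_not(ncol(coords) == 3, "coords must be V x 3")
  stop_if_not(!anyDuplicated(as.data.frame(coords)),
              "voxel coordinates must be unique")
  stop_if_not(tr > 0, "tr must be positive")
  structure(list(data = data, coords = coords,
                 voxel_size = voxel_size, tr = tr),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d voxels x %d volumes, %g mm grid, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$voxel_size, x$tr))
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

# Lay out V voxels on a compact 3-D grid (used by the synthetic generator so
# that degree maps and TFCE have true spatial structure).
default_grid_coords <- function(v) {
  side <- ceiling(v^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                             z = seq_len(side)))
  g[seq_len(v), , drop = FALSE]
}
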