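#' Write a BOLD series as 4-D NIfTI
#'
#' Voxels are placed at their grid coordinates (unoccupied grid cells are
#' zero-filled); the voxel size (mm) and repetition time (s) go into the
#' header pixdim.
#'
#' @param bold a [bold_series].
#' @param path output `.nii` / `.nii.gz` path.
#' @return Invisibly, the path.
#' @export
write_bold_nifti <- function(bold, path) {
  dims <- apply(bold$coords, 2, max)
  arr <- array(0, dim = c(dims, ncol(bold$data)))
  for (i in seq_len(nrow(bold$coords))) {
    arr[bold$coords[i, 1], bold$coords[i, 2], bold$coords[i, 3], ] <-
      bold$data[i, ]
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(bold$voxel_size, 3), bold$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a voxel-set mask as 3-D NIfTI
#'
#' @param coords V x 3 grid coordinates of mask voxels.
#' @param path output path.
#' @param dims grid dimensions (defaults to the coordinate maxima).
#' @param voxel_size mm per grid step.
#' @return Invisibly, the path.
#' @export
write_mask_nifti <- function(coords, path, dims = NULL, voxel_size = 6) {
  coords <- as.matrix(coords)
  if (is.null(dims)) dims <- apply(coords, 2, max)
  arr <- array(0L, dim = dims)
  arr[coords] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D NIfTI into a BOLD series
#'
#' Extracts the time series of the voxels in `mask` (a 3-D array, a path to
#' a mask NIfTI on the same grid, or `NULL` for every non-constant-zero
#' voxel... every voxel). Grid step and TR are taken from the header.
#'
#' @param path 4-D NIfTI path.
#' @param mask optional mask: 3-D array/logical, or path to a mask NIfTI.
#' @return A [bold_series].
#' @export
read_bold_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stop_if_not(length(d) == 4, "expected a 4-D NIfTI")
  pd <- RNifti::pixdim(img)
  if (is.character(mask)) mask <- as.array(RNifti::readNifti(mask)) > 0
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (!all(dim(mask) == d[1:3]))
    stop(sprintf("mask grid %s does not match BOLD grid %s",
                 paste(dim(mask), collapse = "x"),
                 paste(d[1:3], collapse = "x")), call. = FALSE)
  coords <- which(mask > 0, arr.ind = TRUE)
  colnames(coords) <- NULL
  mat <- t(apply(coords, 1, function(xyz) img[xyz[1], xyz[2], xyz[3], ]))
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  bold_series(mat, coords, voxel_size = pd[1], tr = tr)
}

#' Read a six-column motion trace
#'
#' Whitespace-delimited text, comment lines starting with `#` ignored.
#' Column order follows the package convention (translations mm, then
#' rotations radians) documented in the file header written by
#' [write_cohort()].
#'
#' @param path text file path.
#' @return `T x 6` numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path, comment.char = "#"))
  stop_if_not(ncol(m) == 6, "motion file must have 6 columns")
  dimnames(m) <- NULL
  m
}

#' Read and validate a phenotype table
#'
#' CSV with header columns `subject_id`, `group`, `age`, `gender` and
#' optional `side`, `fma_baseline`, `fma_followup`. Subject ids must be
#' unique and motor scores within the 0-66 scale; missing follow-up is
#' allowed (the recovery ratio is then absent, not an error).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_phenotype <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "gender")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("phenotype table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$subject_id))
    stop("duplicate subject_id in phenotype table", call. = FALSE)
  for (col in intersect(c("fma_baseline", "fma_followup"), names(d))) {
    v <- d[[col]]
    bad <- !is.na(v) & (v < 0 | v > 66)
    if (any(bad))
      stop(sprintf("%s outside the 0-66 scale for %s", col,
                   paste(d$subject_id[bad], collapse = ", ")), call. = FALSE)
  }
  d
}
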