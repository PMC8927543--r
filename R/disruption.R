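#' Normative reference profile from control subjects
#'
#' Voxel-wise mean of the control-group nodal-metric vectors — the
#' referential topology each individual is regressed against.
#'
#' @param hc_metric_vectors list (or matrix, subjects in rows) of
#'   equal-length nodal vectors from at least two control subjects.
#' @return Numeric vector of voxel-wise means.
#' @export
reference_profile <- function(hc_metric_vectors) {
  m <- if (is.list(hc_metric_vectors)) do.call(rbind, hc_metric_vectors)
       else as.matrix(hc_metric_vectors)
  stop_if_not(nrow(m) >= 2, "need at least 2 control subjects")
  colMeans(m)
}

#' Fit the hub-disruption index
#'
#' Ordinary least-squares regression (with intercept) of the difference
#' `individual - reference` on `reference` across voxels. The slope is the
#' hub-disruption index: 0 when the individual matches the reference
#' topology, negative when high-metric voxels (hubs) lose relative to
#' low-metric voxels. The intercept is retained because the fit is affine —
#' omitting it would bias slopes toward -1 for mean-shifted profiles.
#'
#' @param individual numeric nodal-metric vector for one subject.
#' @param reference normative reference vector (same length, >= 3,
#'   non-constant).
#' @return Object of class `kd_fit` with components `kd` (the slope),
#'   `intercept`, `fitted`, `residuals`, `individual`, `reference`,
#'   `r_squared`.
#' @export
kd_fit <- function(individual, reference) {
  stop_if_not(length(individual) == length(reference),
              "vectors must have equal length")
  stop_if_not(length(reference) >= 3, "need at least 3 voxels")
  if (var(reference) == 0)
    stop("reference profile is constant: slope undefined", call. = FALSE)
  y <- individual - reference
  slope <- cov(y, reference) / var(reference)
  intercept <- mean(y) - slope * mean(reference)
  fitted <- intercept + slope * reference
  res <- y - fitted
  r2 <- if (var(y) > 0) 1 - var(res) / var(y) else 1
  structure(list(kd = slope, intercept = intercept, fitted = fitted,
                 residuals = res, individual = individual,
                 reference = reference, r_squared = r2),
            class = "kd_fit")
}

#' Hub-disruption slope
#'
#' Scalar convenience wrapper around [kd_fit()].
#'
#' @inheritParams kd_fit
#' @return The fitted slope.
#' @export
kd_slope <- function(individual, reference) {
  kd_fit(individual, reference)$kd
}

#' @export
print.kd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<kd_fit> hub-disruption index = %.*f (intercept %.*f, R^2 %.3f)\n",
              digits, x$kd, digits, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.kd_fit <- function(object, ...) {
  c(intercept = object$intercept, kd = object$kd)
}

#' @export
residuals.kd_fit <- function(object, ...) object$residuals

#' @export
summary.kd_fit <- function(object, ...) {
  n <- length(object$reference)
  se <- sqrt(sum(object$residuals^2) / (n - 2) /
               ((n - 1) * var(object$reference)))
  tval <- object$kd / se
  out <- list(kd = object$kd, intercept = object$intercept, se = se,
              t = tval, p = 2 * pt(-abs(tval), n - 2), n = n,
              r_squared = object$r_squared)
  class(out) <- "summary.kd_fit"
  out
}

#' @export
print.summary.kd_fit <- function(x, ...) {
  cat(sprintf(
    "Hub-disruption index over %d voxels\n  kd = %.4f (se %.4f, t = %.2f, p = %.3g), intercept = %.4f, R^2 = %.3f\n",
    x$n, x$kd, x$se, x$t, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
plot.kd_fit <- function(x, ...) {
  graphics::plot(x$reference, x$individual - x$reference,
                 xlab = "reference nodal value",
                 ylab = "individual - reference",
                 main = sprintf("hub-disruption index = %.3f", x$kd), ...)
  graphics::abline(x$intercept, x$kd, col = "red")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Hub-disruption profiles for a cohort
#'
#' Computes the disruption slope for every subject, metric and density.
#' Patients are regressed against the full control-group mean; each control
#' against the leave-one-out mean excluding that control (self-inclusion
#' deflates control slopes toward 0 and biases the group contrast;
#' `hc_reference = "full"` disables this).
#'
#' @param metric_values named numeric structure: a list indexed
#'   `[[subject]][[metric]][[density]]` of nodal vectors, or a long data
#'   frame with columns `subject`, `metric`, `density`, `node`, `value`.
#' @param groups character vector per subject, `"HC"` for controls.
#' @param hc_reference `"loo"` (default) or `"full"`.
#' @return Long data frame of class `kd_profiles`: `subject`, `group`,
#'   `metric`, `density`, `kd`.
#' @export
kd_profiles <- function(metric_values, groups, hc_reference = c("loo", "full")) {
  hc_reference <- match.arg(hc_reference)
  if (is.data.frame(metric_values)) {
    metric_values <- long_to_nested(metric_values)
  }
  subjects <- names(metric_values)
  stop_if_not(length(groups) == length(subjects),
              "groups must match subjects")
  hc_ix <- which(groups == "HC")
  stop_if_not(length(hc_ix) >= 2, "need at least 2 HC subjects")
  metrics <- names(metric_values[[1]])
  densities <- names(metric_values[[1]][[1]])
  out <- list()
  for (m in metrics) for (d in densities) {
    vecs <- lapply(metric_values, function(s) s[[m]][[d]])
    hc_mat <- do.call(rbind, vecs[hc_ix])
    full_ref <- colMeans(hc_mat)
    for (si in seq_along(subjects)) {
      ref <- if (groups[si] == "HC" && hc_reference == "loo") {
        colMeans(hc_mat[setdiff(seq_along(hc_ix), match(si, hc_ix)), ,
                        drop = FALSE])
      } else full_ref
      out[[length(out) + 1]] <- data.frame(
        subject = subjects[si], group = groups[si], metric = m,
        density = as.numeric(d), kd = kd_slope(vecs[[si]], ref),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("kd_profiles", "data.frame")
  res
}

long_to_nested <- function(df) {
  need <- c("subject", "metric", "density", "node", "value")
  stop_if_not(all(need %in% names(df)), "long format needs columns subject, metric, density, node, value")
  subj <- unique(df$subject)
  lapply(stats::setNames(subj, subj), function(s) {
    ds <- df[df$subject == s, ]
    lapply(split(ds, ds$metric), function(dm) {
      lapply(split(dm, dm$density), function(dd)
        dd$value[order(dd$node)])
    })
  })
}

#' Nodal metrics across densities for a set of cleaned subjects
#'
#' Builds the functional network of each subject at each link density and
#' computes the five nodal metrics, returning the nested structure consumed
#' by [kd_profiles()].
#'
#' @param data_list named list of cleaned V x T matrices (one per subject).
#' @param densities link densities (default 1-10%).
#' @param partition_mode `"per-subject"` (default) detects modules on each
#'   subject's own network; `"none"` uses a single-module partition
#'   (participation coefficient then 0 everywhere).
#' @param seed seed for module detection.
#' @return Nested list `[[subject]][[metric]][[density]]`.
#' @export
cohort_metrics <- function(data_list, densities = seq(0.01, 0.10, by = 0.01),
                           partition_mode = c("per-subject", "none"),
                           seed = 1) {
  partition_mode <- match.arg(partition_mode)
  lapply(data_list, function(x) {
    z <- correlation_matrix(x)
    per_density <- lapply(densities, function(d) {
      net <- threshold_by_density(z, d)
      part <- if (partition_mode == "per-subject")
        detect_modules(net$adjacency, seed = seed)
      else rep(1L, nrow(net$adjacency))
      nodal_metrics(net$adjacency, partition = part)
    })
    names(per_density) <- as.character(densities)
    mets <- c("D", "BC", "CC", "E", "PC")
    out <- lapply(stats::setNames(mets, mets), function(m)
      lapply(per_density, function(tab) tab[[m]]))
    out
  })
}
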