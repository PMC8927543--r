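#' Analysis configuration for the end-to-end pipeline
#'
#' @param cohort a [cohort_config()] (the synthetic study conditions) or an
#'   already-generated `hd_cohort`.
#' @param densities link densities for the disruption-index profile.
#' @param analysis_density density for the local degree analysis.
#' @param exclusion_distance short-link exclusion for degree maps, grid
#'   units.
#' @param n_perm permutations for the voxel-wise group comparison.
#' @param alpha family-wise significance level.
#' @param stages pipeline stages to execute, in order.
#' @param seed master seed for the analysis stages.
#' @return List of class `hd_run_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            densities = seq(0.01, 0.10, by = 0.01),
                            analysis_density = 0.10,
                            exclusion_distance = 2,
                            n_perm = 500, alpha = 0.05,
                            stages = c("preprocess", "network", "kd",
                                       "localdegree", "association"),
                            seed = 1) {
  stop_if_not(length(densities) >= 1 && all(densities > 0 & densities <= 1),
              "densities must lie in (0, 1]")
  cfg <- as.list(environment())
  class(cfg) <- "hd_run_config"
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Simulate (or accept) a cohort, clean every subject's series, build
#' functional networks, estimate hub-disruption profiles with group
#' inference, compare voxel-wise degree maps by permutation + TFCE, and
#' test the ROI degree-behaviour associations. Returns a machine-readable
#' report; every tunable setting actually used is echoed under `$log`.
#'
#' @param config a [pipeline_config()].
#' @return List of class `hd_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  cohort <- if (inherits(cfg$cohort, "hd_cohort")) cfg$cohort
            else generate_cohort(cfg$cohort)
  report <- list(log = c(cfg[c("densities", "analysis_density",
                               "exclusion_distance", "n_perm", "alpha",
                               "seed")],
                         list(cohort_seed = cohort$config$seed,
                              package_version =
                                as.character(utils::packageVersion("hubdisrupt")))))

  ## preprocess + QC
  stage <- "preprocess"
  clean <- if (stage %in% cfg$stages) {
    lapply(cohort$subjects, function(s)
      preprocess_subject(s$bold, s$motion))
  } else {
    lapply(cohort$subjects, function(s)
      list(bold = discard_initial(s$bold, 4), qc_pass = TRUE,
           censor = list(n_retained = ncol(s$bold$data) - 4)))
  }
  qc_pass <- vapply(clean, function(x) isTRUE(x$qc_pass), TRUE)
  report$qc <- list(n_subjects = length(clean),
                    n_pass = sum(qc_pass),
                    retained = vapply(clean, function(x)
                      x$censor$n_retained, 0))
  keep <- which(qc_pass)
  pheno <- cohort$phenotype[keep, , drop = FALSE]
  data_list <- stats::setNames(
    lapply(clean[keep], function(x) x$bold$data), pheno$subject_id)
  coords <- cohort$subjects[[1]]$bold$coords
  groups <- pheno$group
  is_pat <- groups != "HC"

  ## disruption-index profile + group ANCOVA
  if ("kd" %in% cfg$stages) {
    mv <- cohort_metrics(data_list, densities = cfg$densities,
                         seed = cfg$seed)
    prof <- kd_profiles(mv, groups)
    report$kd <- lapply(split(prof, prof$metric), function(pm) {
      mat <- do.call(rbind, lapply(split(pm, pm$subject), function(d)
        d$kd[order(d$density)]))
      mat <- mat[pheno$subject_id, , drop = FALSE]
      test <- rm_ancova_group(mat, is_pat, age = pheno$age,
                              gender = pheno$gender)
      list(mean_kd_hc = mean(mat[!is_pat, ]),
           mean_kd_patient = mean(mat[is_pat, ]),
           F = test$F, df2 = test$df2, p = test$p)
    })
    report$kd_profiles <- prof
  }

  ## voxel-wise degree comparison (permutation + TFCE + FWE)
  dmaps <- NULL
  if (any(c("localdegree", "association") %in% cfg$stages)) {
    dmaps <- t(vapply(data_list, function(x) {
      z <- correlation_matrix(x)
      net <- threshold_by_density(z, cfg$analysis_density, coords = coords)
      degree_map(net, cfg$exclusion_distance)$values
    }, numeric(nrow(coords))))
  }
  if ("localdegree" %in% cfg$stages) {
    design <- data.frame(group = as.numeric(is_pat), age = pheno$age,
                         gender = pheno$gender)
    sm <- permutation_fwe(dmaps, design, contrast = c(1, 0, 0),
                          neighbors = coords, n_perm = cfg$n_perm,
                          seed = cfg$seed)
    cl <- extract_clusters(sm$stat, pmin(sm$p_fwe_pos, sm$p_fwe_neg),
                           coords, alpha = cfg$alpha,
                           voxel_volume = cohort$subjects[[1]]$bold$voxel_size^3)
    report$localdegree <- list(stat_map = sm, clusters = cl)
  }

  ## ROI degree-behaviour association
  if ("association" %in% cfg$stages) {
    roi <- cohort$ground_truth$roi_voxel_ids
    roi_deg <- vapply(seq_len(nrow(dmaps)), function(i)
      mean_degree_in_cluster(dmaps[i, ], roi), 0)
    pb <- pheno[is_pat, ]
    deg_p <- roi_deg[is_pat]
    cov_p <- pb[, c("age", "gender")]
    a_base <- partial_spearman(deg_p, pb$fma_baseline, cov_p)
    has_fu <- !is.na(pb$fma_followup)
    rfma <- rfma_ratio(pb$fma_baseline[has_fu], pb$fma_followup[has_fu])
    a_rec <- partial_spearman(deg_p[has_fu], rfma,
                              cov_p[has_fu, , drop = FALSE])
    report$association <- list(
      rho_baseline = a_base$rho, p_baseline = a_base$p,
      rho_recovery = a_rec$rho, p_recovery = a_rec$p,
      roi_degree = roi_deg)
  }

  class(report) <- "hd_report"
  report
}

#' @export
print.hd_report <- function(x, ...) {
  cat("<hd_report>\n")
  cat(sprintf("  QC: %d/%d subjects retained\n", x$qc$n_pass,
              x$qc$n_subjects))
  if (!is.null(x$kd)) {
    for (m in names(x$kd)) {
      k <- x$kd[[m]]
      cat(sprintf("  kd_%s: HC %.3f vs patient %.3f, F(1,%d) = %.2f, p = %.3g\n",
                  m, k$mean_kd_hc, k$mean_kd_patient, k$df2, k$F, k$p))
    }
  }
  if (!is.null(x$localdegree))
    cat(sprintf("  local degree: %d significant cluster(s)\n",
                nrow(x$localdegree$clusters)))
  if (!is.null(x$association))
    cat(sprintf("  ROI association: rho(baseline) = %.3f, rho(recovery) = %.3f\n",
                x$association$rho_baseline, x$association$rho_recovery))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Large per-voxel members are reduced to summaries; the full object stays
#' in R.
#'
#' @param report an `hd_report`.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_report_json <- function(report, path) {
  slim <- report
  class(slim) <- NULL
  if (!is.null(slim$localdegree)) {
    sm <- slim$localdegree$stat_map
    slim$localdegree <- list(
      n_perm = sm$n_perm,
      min_p_fwe = min(pmin(sm$p_fwe_pos, sm$p_fwe_neg)),
      clusters = slim$localdegree$clusters)
  }
  slim$kd_profiles <- NULL
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
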