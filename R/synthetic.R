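#' Generate a hub-bearing reference network
#'
#' Builds an undirected binary network with a heavy-tailed (hub-bearing)
#' degree sequence and an exact edge count of `round(density * v*(v-1)/2)`.
#' A preferential-attachment scaffold is grown first and then adjusted to
#' the exact edge count: surplus edges are removed uniformly at random,
#' missing edges are added with endpoint probability proportional to degree
#' so the rich-get-richer profile is preserved. Hubs are essential here: the
#' hub-disruption index is a slope over the nodal-metric range, and a
#' flat-degree graph makes that regression degenerate.
#'
#' @param v number of nodes (10 to ~500).
#' @param target_density fraction of possible edges in (0, 0.5] (1 for the
#'   complete graph is also accepted).
#' @param seed integer seed; same seed, same adjacency.
#' @return A `v x v` binary symmetric adjacency matrix with zero diagonal.
#' @export
generate_reference_network <- function(v, target_density, seed = 1) {
  stop_if_not(v >= 4, "v must be at least 4")
  stop_if_not(target_density > 0 && target_density <= 1,
              "target_density must be in (0, 1]")
  n_pairs <- v * (v - 1) / 2
  n_edges <- round_half_up(target_density * n_pairs)
  if (n_edges < 1) stop("density implies fewer than one edge", call. = FALSE)
  set.seed(seed)
  if (n_edges == n_pairs) {
    a <- matrix(1L, v, v); diag(a) <- 0L
    return(a)
  }
  m <- max(1L, round_half_up(n_edges / v))
  g <- igraph::sample_pa(v, m = m, directed = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  a[a > 1] <- 1L
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  cur <- sum(a) / 2
  if (cur > n_edges) {
    el <- which(upper.tri(a) & a == 1L)
    drop <- sample(el, cur - n_edges)
    a[drop] <- 0L
    a <- a * t(a) # re-symmetrise via lower copy below
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
  }
  while (sum(a) / 2 < n_edges) {
    deg <- rowSums(a)
    i <- sample.int(v, 1, prob = deg + 1)
    open <- which(a[i, ] == 0L & seq_len(v) != i)
    if (!length(open)) next
    j <- open[sample.int(length(open), 1, prob = deg[open] + 1)]
    a[i, j] <- a[j, i] <- 1L
  }
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0L
  a
}

#' Disrupt a nodal-metric profile with a known slope
#'
#' Produces an "individual" nodal profile whose regression of
#' `(individual - reference)` on `reference` has expected slope `kappa`:
#' `ind_i = mean(ref) + (1 + kappa) * (ref_i - mean(ref)) + eps_i`.
#' Negative `kappa` compresses the profile toward its mean — hubs lose the
#' most, which is exactly the hub-selective degradation the disruption index
#' is designed to detect.
#'
#' @param reference_nodal numeric vector of reference nodal values.
#' @param kappa planted disruption slope in (-1, 1).
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of the same length as `reference_nodal`.
#' @export
disrupt_network_metrics <- function(reference_nodal, kappa, noise_sd = 0,
                                    seed = 1) {
  stop_if_not(kappa > -1 && kappa < 1, "kappa must be in (-1, 1)")
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  set.seed(seed)
  m <- mean(reference_nodal)
  m + (1 + kappa) * (reference_nodal - m) +
    rnorm(length(reference_nodal), 0, noise_sd)
}

#' Spatial covariance implied by a binary network
#'
#' Maps an adjacency matrix to a covariance with unit-diagonal adjacency
#' convention: `Sigma = diagonal_load * I + edge_weight * (A + I)`, so every
#' voxel has variance `diagonal_load + edge_weight` and linked pairs have
#' correlation `edge_weight / (diagonal_load + edge_weight)`; unlinked pairs
#' are exactly uncorrelated. Positive definiteness is verified by
#' eigendecomposition and violation is an error reporting the minimal
#' eigenvalue.
#'
#' @param adjacency binary symmetric adjacency matrix.
#' @param edge_weight covariance placed on each edge (> 0).
#' @param diagonal_load extra diagonal variance; must be large enough for
#'   positive definiteness.
#' @return A positive-definite covariance matrix.
#' @export
covariance_from_network <- function(adjacency, edge_weight = 0.3,
                                    diagonal_load = 1) {
  stop_if_not(edge_weight > 0, "edge_weight must be positive")
  v <- nrow(adjacency)
  sigma <- diagonal_load * diag(v) + edge_weight * (adjacency + diag(v))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf(
      "covariance is not positive definite (min eigenvalue %.3g); increase diagonal_load",
      min(ev)), call. = FALSE)
  }
  sigma
}

# Smallest diagonal load that keeps covariance_from_network() safely positive
# definite for this adjacency (10% margin over the spectral bound).
auto_diagonal_load <- function(adjacency, edge_weight) {
  lmin <- min(eigen(adjacency, symmetric = TRUE, only.values = TRUE)$values)
  max(1, 1.1 * edge_weight * (abs(lmin) - 1))
}

#' Sample a BOLD-like series from a spatial covariance
#'
#' Draws `n_volumes` Gaussian volumes with the given voxel-by-voxel
#' covariance (zero mean plus an optional constant intensity offset). An
#' optional AR(1) coefficient adds temporal autocorrelation; the default is
#' temporally white, since the downstream correlation and thresholding logic
#' is what the generator exists to exercise, not hemodynamics.
#'
#' @param covariance V x V positive-definite matrix.
#' @param n_volumes number of volumes T (>= 10).
#' @param tr repetition time in seconds.
#' @param seed integer seed.
#' @param coords optional V x 3 grid coordinates (a compact grid by default).
#' @param offset constant added to every sample (intensity units).
#' @param ar1 AR(1) coefficient in [0, 1) for temporal autocorrelation.
#' @param voxel_size grid step in mm.
#' @return A [bold_series] with `V` rows and `n_volumes` columns.
#' @export
sample_bold <- function(covariance, n_volumes, tr = 2.5, seed = 1,
                        coords = NULL, offset = 0, ar1 = 0, voxel_size = 6) {
  stop_if_not(n_volumes >= 10, "n_volumes must be at least 10")
  v <- nrow(covariance)
  set.seed(seed)
  ch <- tryCatch(chol(covariance),
                 error = function(e) stop("covariance is not positive definite",
                                          call. = FALSE))
  z <- matrix(rnorm(v * n_volumes), v, n_volumes)
  if (ar1 > 0) {
    for (t in 2:n_volumes) z[, t] <- ar1 * z[, t - 1] + sqrt(1 - ar1^2) * z[, t]
  }
  x <- crossprod(ch, z) + offset
  if (is.null(coords)) coords <- default_grid_coords(v)
  bold_series(x, coords, voxel_size = voxel_size, tr = tr)
}

#' Generate a six-parameter rigid-body motion trace
#'
#' Columns 1-3 are translations in mm, columns 4-6 rotations in radians
#' (this order is fixed throughout the package and written in the header of
#' exported motion files). The baseline is a bounded random walk whose
#' framewise displacement stays below 0.5 mm everywhere; each spike volume
#' receives a level shift in x-translation so FD meets or exceeds `spike_mm`
#' exactly at the requested volumes.
#'
#' @param n_volumes number of volumes T.
#' @param spike_volumes integer volumes (each in `[2, T]`) receiving a spike.
#' @param spike_mm spike magnitude in mm (> 0 when spikes are requested).
#' @param seed integer seed.
#' @param jitter half-width of the per-volume baseline steps (mm for
#'   translations; `jitter/100` radians for rotations). 0 gives a still head.
#' @return A `T x 6` numeric matrix.
#' @export
generate_motion <- function(n_volumes, spike_volumes = integer(),
                            spike_mm = 0.8, seed = 1, jitter = 0.01) {
  spike_volumes <- as.integer(spike_volumes)
  if (length(spike_volumes)) {
    stop_if_not(spike_mm > 0, "spike_mm must be positive")
    if (any(spike_volumes < 2))
      stop("spike at volume 1 is undefined (FD is a backward difference)",
           call. = FALSE)
    stop_if_not(all(spike_volumes <= n_volumes), "spike beyond last volume")
  }
  set.seed(seed)
  steps <- cbind(
    matrix(runif(3 * n_volumes, -jitter, jitter), n_volumes, 3),
    matrix(runif(3 * n_volumes, -jitter / 100, jitter / 100), n_volumes, 3))
  steps[1, ] <- 0
  sgn <- 1
  for (tv in spike_volumes) {
    steps[tv, 1] <- steps[tv, 1] + sgn * spike_mm
    sgn <- -sgn
  }
  apply(steps, 2, cumsum)
}

#' Configuration for the synthetic cohort
#'
#' Defaults mirror the study design the package targets: 32 reference
#' controls and 28 patients, 230 volumes at TR = 2.5 s, networks built at
#' 10% link density, and patient networks that are hub-disrupted versions of
#' a shared reference with per-patient slopes drawn around -0.3. The
#' baseline motor score decreases with the planted ROI degree and the
#' recovery ratio increases with it, matching the sign structure under
#' study.
#'
#' @param n_control,n_patient group sizes (>= 3 each).
#' @param v number of gray-matter voxels (nodes).
#' @param n_volumes volumes per run (pre-discard).
#' @param tr repetition time, seconds.
#' @param density generating link density.
#' @param edge_weight,diagonal_load covariance parameters; `diagonal_load =
#'   NULL` picks the smallest safe load per network (see
#'   [covariance_from_network()]).
#' @param kappa_mean,kappa_sd distribution of the planted per-patient
#'   disruption slope (truncated to (-0.9, 0.9)).
#' @param roi_size voxels in the planted ROI (a hub and its nearest grid
#'   neighbours).
#' @param coupling_baseline latent-logit slope of baseline score per SD of
#'   ROI degree (negative: more severe impairment with higher ROI degree).
#' @param coupling_recovery slope of the recovery ratio per SD of ROI degree.
#' @param baseline_noise,recovery_noise Gaussian noise SDs of the two
#'   behavioural couplings.
#' @param recovery_mean mean recovery ratio.
#' @param spike_prob probability a subject has motion spikes (default 1:
#'   essentially every scan in a patient cohort carries some spikes).
#' @param max_spikes maximum spikes per affected subject.
#' @param spike_mm spike magnitude, mm.
#' @param artifact_scale size of the image-intensity artefact accompanying
#'   each motion spike, as a multiple of the voxel SD (motion corrupts the
#'   image itself, which is what the DVARS/SD censoring criteria detect).
#' @param intensity_offset constant BOLD intensity offset (arbitrary units).
#' @param ar1 temporal AR(1) coefficient of the BOLD noise.
#' @param seed master seed; every stream below fans out via [fan_seed()].
#' @return A list of class `hd_config`.
#' @export
cohort_config <- function(n_control = 32, n_patient = 28, v = 150,
                          n_volumes = 230, tr = 2.5, density = 0.10,
                          edge_weight = 0.3, diagonal_load = NULL,
                          kappa_mean = -0.3, kappa_sd = 0.3,
                          roi_size = 24,
                          coupling_baseline = -1.5, coupling_recovery = 0.25,
                          baseline_noise = 0.2, recovery_noise = 0.06,
                          recovery_mean = 0.5,
                          spike_prob = 1, max_spikes = 4, spike_mm = 0.8,
                          artifact_scale = 6,
                          intensity_offset = 1000, ar1 = 0, seed = 1) {
  stop_if_not(n_control >= 3 && n_patient >= 3,
              "at least 3 subjects per group")
  stop_if_not(n_volumes >= 124, "n_volumes must be at least 124")
  cfg <- as.list(environment())
  class(cfg) <- "hd_config"
  cfg
}

# Truncated-normal draw for the per-patient slope.
draw_kappa <- function(n, mean, sd) {
  k <- rnorm(n, mean, sd)
  pmin(0.9, pmax(-0.9, k))
}

# Rewire an adjacency toward the degree sequence implied by slope kappa,
# preserving the total edge count. Heuristic: strip edges from over-target
# nodes, then reconnect under-target pairs (degree-preferential), falling
# back to arbitrary open pairs so the count is always restored.
rewire_to_kappa <- function(adjacency, kappa, seed) {
  set.seed(seed)
  v <- nrow(adjacency)
  a <- adjacency
  d <- rowSums(a)
  m <- mean(d)
  target <- pmax(0, pmin(v - 1, round_half_up(m + (1 + kappa) * (d - m))))
  removed <- 0L
  for (it in seq_len(10 * sum(d))) {
    surplus <- rowSums(a) - target
    over <- which(surplus > 0)
    if (!length(over)) break
    i <- over[which.max(surplus[over])]
    nb <- which(a[i, ] == 1L)
    if (!length(nb)) break
    j <- nb[sample.int(length(nb), 1)]
    a[i, j] <- a[j, i] <- 0L
    removed <- removed + 1L
  }
  while (removed > 0L) {
    deficit <- target - rowSums(a)
    under <- which(deficit > 0)
    placed <- FALSE
    if (length(under) >= 2) {
      i <- under[sample.int(length(under), 1, prob = deficit[under])]
      open <- setdiff(under[a[i, under] == 0L], i)
      if (length(open)) {
        j <- open[sample.int(length(open), 1)]
        a[i, j] <- a[j, i] <- 1L
        placed <- TRUE
      }
    }
    if (!placed) { # fall back: any open pair, keeps the edge count exact
      openu <- which(upper.tri(a) & a == 0L)
      pick <- openu[sample.int(length(openu), 1)]
      a[pick] <- 1L
      a[lower.tri(a)] <- t(a)[lower.tri(a)]
    }
    removed <- removed - 1L
  }
  a
}

#' Generate a two-group synthetic cohort with planted ground truth
#'
#' Controls are sampled from a shared hub-bearing reference covariance;
#' each patient from a covariance whose network has been rewired toward a
#' per-patient disruption slope `kappa`. The baseline motor score (0-66) is
#' a logistic squashing of a latent that decreases with the patient's planted
#' ROI degree, and the follow-up score encodes a recovery ratio that
#' increases with ROI degree, so both association signs are recoverable
#' end-to-end. Motion traces carry known spikes; ages and genders are drawn
#' from the same distribution in both groups.
#'
#' @param config an [cohort_config()] object.
#' @return An object of class `hd_cohort`: list with `subjects` (each having
#'   `bold`, `motion`, phenotype fields), `phenotype` (data frame), and
#'   `ground_truth` (reference adjacency/covariance, `kappa_true`,
#'   `roi_voxel_ids`, behavioural couplings, seed).
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- config
  seed <- cfg$seed
  a_ref <- generate_reference_network(cfg$v, cfg$density,
                                      seed = fan_seed(seed, 1))

  # Voxel-level hubs cluster spatially in real cortex, so nodes are laid out
  # with degree decreasing from the grid centre; the planted ROI is the
  # central hub block.
  grid <- default_grid_coords(cfg$v)
  centre <- colMeans(grid)
  grid_by_centre <- grid[order(sqrt(rowSums(
    (grid - matrix(centre, cfg$v, 3, byrow = TRUE))^2))), , drop = FALSE]
  by_degree <- order(-rowSums(a_ref))
  coords <- matrix(0L, cfg$v, 3)
  coords[by_degree, ] <- grid_by_centre
  roi <- by_degree[seq_len(cfg$roi_size)]

  set.seed(fan_seed(seed, 2))
  kappa <- draw_kappa(cfg$n_patient, cfg$kappa_mean, cfg$kappa_sd)
  n <- cfg$n_control + cfg$n_patient
  set.seed(fan_seed(seed, 3))
  ages <- round(pmin(85, pmax(30, rnorm(n, 65, 8))))
  genders <- ifelse(runif(n) < 0.5, "M", "F")
  spiky <- runif(n) < cfg$spike_prob
  n_spk <- 1L + (sample.int(cfg$max_spikes, n, replace = TRUE) - 1L)

  # Patient networks first, so one diagonal load can serve the whole cohort:
  # a per-subject load would tie the correlation strength to the disruption
  # level and confound the planted effect.
  patient_nets <- lapply(seq_len(cfg$n_patient), function(k)
    rewire_to_kappa(a_ref, kappa[k],
                    seed = fan_seed(seed, 100 + cfg$n_control + k)))
  load_all <- cfg$diagonal_load %||%
    max(vapply(c(list(a_ref), patient_nets), auto_diagonal_load,
               0, edge_weight = cfg$edge_weight))
  sigma_ref <- covariance_from_network(a_ref, cfg$edge_weight, load_all)
  roi_deg <- vapply(patient_nets, function(a_i) {
    # ground-truth ROI degree under the same short-link exclusion the
    # degree-map analysis applies
    net_i <- structure(list(adjacency = a_i, density = cfg$density,
                            coords = coords, voxel_size = 6),
                       class = "functional_network")
    mean(degree_map(net_i, 2)$values[roi])
  }, 0)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    is_pat <- i > cfg$n_control
    if (is_pat) {
      k <- i - cfg$n_control
      sig_i <- covariance_from_network(patient_nets[[k]], cfg$edge_weight,
                                       load_all)
    } else {
      sig_i <- sigma_ref
    }
    bold <- sample_bold(sig_i, cfg$n_volumes, tr = cfg$tr,
                        seed = fan_seed(seed, 200 + i), coords = coords,
                        offset = cfg$intensity_offset, ar1 = cfg$ar1)
    spikes <- integer()
    if (spiky[i]) {
      set.seed(fan_seed(seed, 300 + i))
      spikes <- sort(sample(10:(cfg$n_volumes - 5), n_spk[i]))
      # motion corrupts the images too: a large intensity artefact at each
      # spike volume is what the DVARS/SD criteria exist to catch
      bold$data[, spikes] <- bold$data[, spikes] +
        matrix(rnorm(length(spikes) * cfg$v, 0,
                     cfg$artifact_scale * sqrt(mean(diag(sig_i)))),
               cfg$v, length(spikes))
    }
    motion <- generate_motion(cfg$n_volumes, spikes, cfg$spike_mm,
                              seed = fan_seed(seed, 400 + i))
    subjects[[i]] <- list(
      subject_id = sprintf("S%03d", i),
      group = if (is_pat) "patient" else "HC",
      side = if (is_pat) "right" else NA_character_,
      age = ages[i], gender = genders[i],
      bold = bold, motion = motion, spike_volumes = spikes)
  }

  # behaviour: baseline decreases, recovery ratio increases with ROI degree
  set.seed(fan_seed(seed, 5))
  z <- as.numeric(scale(roi_deg))
  if (any(!is.finite(z))) z <- rep(0, length(roi_deg)) # degenerate: no spread
  latent <- cfg$coupling_baseline * z +
    rnorm(cfg$n_patient, 0, cfg$baseline_noise)
  fma_baseline <- round(66 * plogis(latent), 1)
  fma_baseline <- pmax(fma_baseline, 1) # ratio defined only for baseline > 0
  rec <- cfg$recovery_mean + cfg$coupling_recovery * z +
    rnorm(cfg$n_patient, 0, cfg$recovery_noise)
  fma_followup <- round(pmin(66, pmax(0, fma_baseline * (1 + rec))), 1)
  for (k in seq_len(cfg$n_patient)) {
    i <- cfg$n_control + k
    subjects[[i]]$fma_baseline <- fma_baseline[k]
    subjects[[i]]$fma_followup <- fma_followup[k]
  }

  phenotype <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = vapply(subjects, `[[`, "", "group"),
    side = vapply(subjects, `[[`, "", "side"),
    age = vapply(subjects, `[[`, 0, "age"),
    gender = vapply(subjects, `[[`, "", "gender"),
    fma_baseline = vapply(subjects, function(s) s$fma_baseline %||% NA_real_,
                          0),
    fma_followup = vapply(subjects, function(s) s$fma_followup %||% NA_real_,
                          0),
    stringsAsFactors = FALSE)

  structure(list(
    subjects = subjects,
    phenotype = phenotype,
    config = cfg,
    ground_truth = list(
      reference_adjacency = a_ref,
      reference_covariance = sigma_ref,
      kappa_true = kappa,
      roi_voxel_ids = roi,
      roi_degree_true = roi_deg,
      patient_networks = patient_nets,
      behavior_coupling = c(baseline = cfg$coupling_baseline,
                            recovery = cfg$coupling_recovery),
      seed = seed)),
    class = "hd_cohort")
}

#' @export
print.hd_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "<hd_cohort> %d HC + %d patients; V = %d voxels, T = %d volumes, ",
    "TR = %g s\n  planted kappa: mean %.2f (sd %.2f); ROI of %d voxels at ",
    "the strongest hub\n"),
    cfg$n_control, cfg$n_patient, cfg$v, cfg$n_volumes, cfg$tr,
    cfg$kappa_mean, cfg$kappa_sd, cfg$roi_size))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Per-subject 4-D NIfTI (grid and TR in the header), whitespace-delimited
#' motion traces (header comment documents the column order: translations in
#' mm then rotations in radians), a phenotype CSV and the ground truth as
#' JSON.
#'
#' @param cohort an `hd_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    write_bold_nifti(s$bold, file.path(dir, paste0(s$subject_id, "_bold.nii")))
    con <- file(file.path(dir, paste0(s$subject_id, "_motion.txt")), "w")
    writeLines("# columns: trans_x_mm trans_y_mm trans_z_mm rot_x_rad rot_y_rad rot_z_rad",
               con)
    write.table(format(s$motion, digits = 8), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    close(con)
  }
  write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"),
            row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(kappa_true = gt$kappa_true,
         roi_voxel_ids = gt$roi_voxel_ids,
         roi_degree_true = gt$roi_degree_true,
         behavior_coupling = as.list(gt$behavior_coupling),
         seed = gt$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
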