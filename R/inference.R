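#' Motor recovery ratio
#'
#' Relative change of the upper-extremity motor score from baseline to
#' follow-up: `(followup - baseline) / baseline`. Positive values indicate
#' improvement, negative deterioration; undefined at baseline 0.
#'
#' @param baseline,followup scores on the 0-66 scale (baseline > 0).
#' @return Dimensionless ratio (vectorised).
#' @export
rfma_ratio <- function(baseline, followup) {
  if (any(baseline <= 0)) stop("recovery ratio undefined for baseline <= 0",
                               call. = FALSE)
  (followup - baseline) / baseline
}

#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-tailed p value, computed from group means, SDs and sizes (for
#' demographic-table comparisons where only summaries are available).
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stop_if_not(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  stop_if_not(sd1 > 0 && sd2 > 0, "SDs must be positive")
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Pearson chi-squared test of a 2 x 2 table
#'
#' Without continuity correction, df = 1, two-tailed.
#'
#' @param a,b first row counts; `c_`,`d` second row counts.
#' @return List with `chisq`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  stop_if_not(all(counts >= 0) && sum(counts) > 0, "invalid counts")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared undefined: a margin is zero", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(res$statistic), p = unname(res$p.value))
}

#' Group effect of a repeated-measures ANCOVA over link densities
#'
#' The between-subject group effect of the classical split-plot model is the
#' one-way ANCOVA on each subject's density-averaged score; with age and
#' gender as covariates this yields F on (1, N - 4) degrees of freedom and
#' needs no sphericity machinery (the within-subject density factor is not
#' an endpoint here).
#'
#' @param kd subjects x densities numeric matrix (or a `kd_profiles` data
#'   frame filtered to one metric, reshaped internally).
#' @param group factor/character of length N (exactly 2 levels).
#' @param age,gender optional numeric covariates of length N (gender may be
#'   "M"/"F").
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
rm_ancova_group <- function(kd, group, age = NULL, gender = NULL) {
  if (inherits(kd, "kd_profiles") || is.data.frame(kd)) {
    stop_if_not(length(unique(kd$metric)) == 1,
                "filter kd_profiles to a single metric first")
    kd <- do.call(rbind, lapply(split(kd, kd$subject), function(d)
      d$kd[order(d$density)]))
  }
  kd <- as.matrix(kd)
  y <- rowMeans(kd)
  g <- factor(group)
  stop_if_not(nlevels(g) == 2, "group must have exactly 2 levels")
  stop_if_not(all(table(g) >= 3), "need at least 3 subjects per group")
  dat <- data.frame(y = y, g = g)
  form <- y ~ g
  if (!is.null(age)) { dat$age <- as.numeric(age); form <- stats::update(form, . ~ . + age) }
  if (!is.null(gender)) {
    dat$gender <- if (is.numeric(gender)) gender
                  else as.numeric(factor(gender)) - 1
    form <- stats::update(form, . ~ . + gender)
  }
  fit <- lm(form, data = dat)
  if (any(!is.finite(coef(fit))))
    stop("rank-deficient ANCOVA design", call. = FALSE)
  tg <- summary(fit)$coefficients["g" %+% levels(g)[2], ]
  df2 <- fit$df.residual
  list(F = unname(tg["t value"]^2), df1 = 1, df2 = df2,
       p = unname(tg["Pr(>|t|)"]))
}

`%+%` <- function(a, b) paste0(a, b)

#' Covariate-adjusted Spearman correlation
#'
#' Ranks x and y, residualises both on an intercept plus the covariates,
#' and correlates the residuals; p from the t approximation on
#' `n - 2 - k` degrees of freedom (k covariates). With no covariates this
#' is exactly the plain Spearman coefficient.
#'
#' @param x,y numeric vectors (n >= 5, no missing values).
#' @param covariates optional vector, matrix or data frame of covariates
#'   (character columns such as "M"/"F" are coded numerically).
#' @return List with `rho`, `p`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stop_if_not(n >= 5, "need at least 5 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  k <- 0
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cv[] <- lapply(cv, function(col)
      if (is.numeric(col)) col else as.numeric(factor(col)) - 1)
    cv <- as.matrix(cv)
    stop_if_not(nrow(cv) == n, "covariates length mismatch")
    k <- ncol(cv)
    z <- cbind(1, cv)
    h <- z %*% solve(crossprod(z), t(z))
    rx <- rx - h %*% rx
    ry <- ry - h %*% ry
  }
  rho <- cor(as.numeric(rx), as.numeric(ry))
  df <- n - 2 - k
  tval <- rho * sqrt(df / max(1e-300, 1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), df), df = df)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stop_if_not(m >= 1, "m must be at least 1")
  alpha / m
}
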