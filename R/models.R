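#' Fit the family-cofactor phenotype model to one feature
#'
#' Ordinary least squares of `y = rho * beta + fam (+ age) + eps`, with the
#' phenotype indicator `rho` (1 for the CALD brother, 0 for the non-CALD
#' brother), fixed family indicator variables, and optionally age in years.
#' The two-sided p-value uses the t distribution at
#' `n - n_families - 1` residual degrees of freedom (one fewer with age).
#'
#' With one brother pair per family and no age term, the phenotype
#' estimate equals the mean of the within-family (CALD minus non-CALD)
#' differences, and the t statistic equals the paired t-test statistic.
#'
#' If the design leaves zero residual variance the fit is flagged
#' `degenerate`: the estimate is still returned but its standard error and
#' p-value are undefined (`NA`). If age is constant given family (no
#' within-family age variation) the age term is dropped with a warning.
#'
#' @param y Numeric values, one per sibling sample. If named, names are
#'   matched to sample ids; otherwise values are taken in the order of the
#'   cohort's non-control rows.
#' @param cohort A cohort tibble.
#' @param include_age Add age (years) as a covariate (used for DNA
#'   methylation).
#' @return An object of class `feature_fit` with elements `estimate`,
#'   `std_error`, `statistic`, `df`, `p_value`, `residual_var`,
#'   `degenerate`, `age_estimate` (NA unless `include_age`), `n`,
#'   `coefficients`.
#' @seealso [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_feature_model <- function(y, cohort, include_age = FALSE) {
  ald <- cohort[cohort$phenotype != "control", ]
  if (dplyr::n_distinct(ald$family) < 2) {
    stop("need at least 2 families", call. = FALSE)
  }
  if (!is.null(names(y))) {
    missing_s <- setdiff(ald$sample, names(y))
    if (length(missing_s) > 0) {
      stop("values missing for sample(s): ",
           paste(missing_s, collapse = ", "), call. = FALSE)
    }
    y <- y[ald$sample]
  } else {
    stopifnot(length(y) == nrow(ald))
  }
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)

  fit <- ols_scan_engine(matrix(y, nrow = 1), ald, include_age = include_age)
  structure(list(
    estimate = fit$estimate, std_error = fit$std_error,
    statistic = fit$statistic, df = fit$df, p_value = fit$p_value,
    residual_var = fit$residual_var, degenerate = fit$degenerate,
    age_estimate = fit$age_estimate, age_std_error = fit$age_std_error,
    n = nrow(ald), n_families = dplyr::n_distinct(ald$family),
    include_age = fit$include_age
  ), class = "feature_fit")
}

#' @export
print.feature_fit <- function(x, ...) {
  cat(sprintf(
    "# feature_fit: beta=%.4g se=%.4g t=%.4g df=%d p=%.4g%s\n",
    x$estimate, x$std_error, x$statistic, x$df, x$p_value,
    if (x$degenerate) " (degenerate: zero residual variance)" else ""))
  invisible(x)
}

# Vectorized OLS over a features-x-samples matrix with the shared
# phenotype + family (+ age) design. Returns per-feature estimates for the
# phenotype coefficient (and age when included).
ols_scan_engine <- function(Y, ald_cohort, include_age = FALSE) {
  samples <- ald_cohort$sample
  n <- length(samples)
  rho <- as.numeric(ald_cohort$phenotype == "CALD")
  fam <- factor(ald_cohort$family)
  X <- stats::model.matrix(~fam)
  age_dropped <- FALSE
  if (include_age) {
    Xa <- cbind(X, age = ald_cohort$age)
    if (qr(Xa)$rank < ncol(Xa)) {
      warning("age is collinear with family; age term dropped",
              call. = FALSE)
      include_age <- FALSE
      age_dropped <- TRUE
    } else {
      X <- Xa
    }
  }
  X <- cbind(X, rho = rho)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)

  xtx_inv <- solve(crossprod(X))
  H <- xtx_inv %*% t(X)          # p x n; coefficients = H %*% y
  coefs <- Y %*% t(H)            # features x p
  res <- Y - coefs %*% t(X)
  df <- n - p
  rss <- rowSums(res^2)
  sigma2 <- rss / df
  scale_ <- pmax(rowMeans(Y^2), 1)
  degenerate <- sigma2 < 1e-16 * scale_

  est <- unname(coefs[, p])
  sigma2 <- unname(sigma2)
  degenerate <- unname(degenerate)
  se <- sqrt(sigma2 * xtx_inv[p, p])
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  se[degenerate] <- NA_real_
  tstat[degenerate] <- NA_real_
  pval[degenerate] <- NA_real_

  age_est <- rep(NA_real_, nrow(Y))
  age_se <- rep(NA_real_, nrow(Y))
  if (include_age) {
    ai <- which(colnames(X) == "age")
    age_est <- unname(coefs[, ai])
    age_se <- sqrt(sigma2 * xtx_inv[ai, ai])
    age_se[degenerate] <- NA_real_
  }
  list(estimate = est, std_error = se, statistic = tstat, df = df,
       p_value = pval, residual_var = sigma2, degenerate = degenerate,
       age_estimate = age_est, age_std_error = age_se,
       include_age = include_age, age_dropped = age_dropped)
}

# platform transform: returns list(Y = model-scale matrix, extra columns)
platform_transform <- function(values, platform) {
  switch(platform,
    rna = {
      lib <- colSums(values)
      cpm <- t(t(values) / lib * 1e6)
      log2(cpm + 0.5)
    },
    dnam = log2(values / (1 - values)),   # M-values
    lipid = ,
    protein = log2(values)
  )
}

#' Per-feature phenotype scan over a platform matrix
#'
#' Applies the platform transform — `log2(CPM + 0.5)` with total-count
#' library normalization for rna, M-values (`log2(beta/(1-beta))`) for
#' dnam, `log2` abundance for lipid and protein — then fits
#' [fit_feature_model()]'s design to every feature at once. Age enters as
#' a covariate for dnam. Features with missing values are dropped (count
#' reported), as are rna features with all-zero counts and lipid/protein
#' features with non-positive abundances.
#'
#' `log2fc` is the phenotype estimate on the transformed (log2) scale;
#' dnam rows additionally carry `delta_beta`, the CALD minus non-CALD
#' group-mean methylation difference on the original beta scale.
#'
#' @param x An [feature_matrix()] (or wide tibble with `feature_id`).
#' @param cohort A cohort tibble; all non-control samples must be columns
#'   of `x`.
#' @param platform Platform tag; defaults to the matrix's own tag.
#' @param include_age Defaults to `TRUE` for dnam, else `FALSE`.
#' @param adjust_method Multiple-testing method for `p_adjusted`
#'   (default `"bonferroni"`, see [adjust_pvalues()]).
#' @return A tibble of class `modifier_scan`, one row per retained
#'   feature: `feature_id`, `platform`, `estimate`, `std_error`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `log2fc`,
#'   `residual_var`, `degenerate` (plus `delta_beta` for dnam), ordered
#'   by ascending p then id.
#' @export
run_platform_scan <- function(x, cohort, platform = NULL,
                              include_age = NULL,
                              adjust_method = "bonferroni") {
  if (is.null(platform)) platform <- omic_platform(x)
  if (is.null(platform)) stop("platform must be given", call. = FALSE)
  if (is.null(include_age)) include_age <- platform == "dnam"

  ald <- cohort[cohort$phenotype != "control", ]
  x_tbl <- tibble::as_tibble(as.data.frame(x))
  missing_s <- setdiff(ald$sample, names(x_tbl))
  if (length(missing_s) > 0) {
    stop("matrix lacks cohort sample(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(x_tbl[ald$sample])
  rownames(values) <- x_tbl$feature_id

  drop_na <- rowSums(!is.finite(values)) > 0
  drop_flat <- rep(FALSE, nrow(values))
  if (platform == "rna") drop_flat <- rowSums(values) == 0
  if (platform %in% c("lipid", "protein")) drop_flat <- rowSums(values <= 0) > 0
  drop <- drop_na | drop_flat
  if (any(drop)) {
    message(sum(drop), " feature(s) dropped (missing, all-zero or non-positive)")
  }
  values <- values[!drop, , drop = FALSE]

  Y <- platform_transform(values, platform)
  fit <- ols_scan_engine(Y, ald, include_age = include_age)

  out <- tibble::tibble(
    feature_id = rownames(values),
    platform = platform,
    estimate = fit$estimate,
    std_error = fit$std_error,
    statistic = fit$statistic,
    df = fit$df,
    p_value = fit$p_value,
    p_adjusted = adjust_pvalues(fit$p_value, adjust_method),
    log2fc = fit$estimate,
    residual_var = fit$residual_var,
    degenerate = fit$degenerate
  )
  if (include_age || platform == "dnam") {
    out$age_estimate <- fit$age_estimate
    out$age_std_error <- fit$age_std_error
  }
  if (platform == "dnam") {
    cald <- ald$sample[ald$phenotype == "CALD"]
    noncald <- ald$sample[ald$phenotype == "non-CALD"]
    out$delta_beta <- rowMeans(values[, cald, drop = FALSE]) -
      rowMeans(values[, noncald, drop = FALSE])
  }
  out <- out[order(out$p_value, out$feature_id), ]
  structure(out, platform = platform, include_age = fit$include_age,
            n_dropped = sum(drop),
            class = c("modifier_scan", class(out)))
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni is `min(1, m * p)`; `bh` is the Benjamini-Hochberg step-up
#' false-discovery-rate adjustment with monotonicity enforcement (both via
#' [stats::p.adjust()]).
#'
#' @param p Numeric p-values in \[0, 1\] (`NA` allowed).
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(tolower(method), c("bonferroni", "bh"))
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[method])
}

#' Filter CpGs on nominal significance and methylation difference
#'
#' Keeps CpGs with `p_value < p_threshold` and an absolute group-mean
#' beta difference above `delta_beta_threshold` (defaults: p < 0.0005 and
#' delta beta > 5%).
#'
#' @param fits A dnam [run_platform_scan()] result (carries `delta_beta`),
#'   or any tibble with `feature_id` and `p_value`.
#' @param x The dnam beta matrix (used with `cohort` to compute
#'   `delta_beta` when `fits` lacks it).
#' @param cohort A cohort tibble (only needed to compute `delta_beta`).
#' @param p_threshold Nominal p cutoff, default `5e-4`.
#' @param delta_beta_threshold Absolute delta-beta cutoff, default `0.05`.
#' @return The retained rows of `fits`, with `delta_beta` attached.
#' @export
filter_cpgs <- function(fits, x = NULL, cohort = NULL,
                        p_threshold = 5e-4, delta_beta_threshold = 0.05) {
  fits <- tibble::as_tibble(fits)
  if (!"delta_beta" %in% names(fits)) {
    stopifnot(!is.null(x), !is.null(cohort))
    x_tbl <- tibble::as_tibble(as.data.frame(x))
    ald <- cohort[cohort$phenotype != "control", ]
    values <- as.matrix(x_tbl[ald$sample])
    rownames(values) <- x_tbl$feature_id
    cald <- ald$sample[ald$phenotype == "CALD"]
    noncald <- ald$sample[ald$phenotype == "non-CALD"]
    db <- rowMeans(values[, cald, drop = FALSE]) -
      rowMeans(values[, noncald, drop = FALSE])
    fits$delta_beta <- db[fits$feature_id]
  }
  keep <- !is.na(fits$p_value) & fits$p_value < p_threshold &
    abs(fits$delta_beta) > delta_beta_threshold
  fits[keep, ]
}

#' Call differentially methylated regions from per-CpG fits
#'
#' Candidate regions are maximal runs of nominally significant CpGs
#' (`p_value < p_threshold`) on one chromosome with consecutive gaps of at
#' most `max_gap` bp, a shared direction of methylation change (runs split
#' where `delta_beta` changes sign), and at least `min_cpgs` members. Each
#' candidate's combined p comes from Stouffer's method over member
#' z-scores (for k members of equal p the combined z is `sqrt(k)` times
#' the member z); region FDR is Benjamini-Hochberg across candidates.
#' Reported DMRs pass `fdr < fdr_threshold` and
#' `|mean delta_beta| > delta_beta_threshold`.
#'
#' @param cpg_fits A dnam [run_platform_scan()] result (needs `p_value`
#'   and `delta_beta`).
#' @param coords Tibble `feature_id`, `chrom`, `pos` (1-based CpG
#'   positions), e.g. [omic_coords()] of the scanned matrix.
#' @param max_gap Maximum gap between member CpGs in bp (default 1000).
#' @param min_cpgs Minimum member CpGs (default 3).
#' @param fdr_threshold Region FDR cutoff (default 0.05).
#' @param delta_beta_threshold Region mean methylation-change cutoff
#'   (default 0.10).
#' @param p_threshold Nominal member-CpG p cutoff (default 5e-4).
#' @return Tibble of DMRs: `chrom`, `start`, `end`, `n_cpgs`, `cpg_ids`
#'   (list), `combined_z`, `combined_p`, `fdr`, `delta_beta` (mean),
#'   `direction`.
#' @export
call_dmrs <- function(cpg_fits, coords, max_gap = 1000, min_cpgs = 3,
                      fdr_threshold = 0.05, delta_beta_threshold = 0.10,
                      p_threshold = 5e-4) {
  stopifnot(all(c("feature_id", "p_value", "delta_beta") %in% names(cpg_fits)))
  d <- dplyr::inner_join(tibble::as_tibble(cpg_fits),
                         tibble::as_tibble(coords), by = "feature_id")
  d <- d[!is.na(d$p_value) & d$p_value < p_threshold & d$delta_beta != 0, ]
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    n_cpgs = integer(), cpg_ids = list(), combined_z = numeric(),
    combined_p = numeric(), fdr = numeric(), delta_beta = numeric(),
    direction = character())
  if (nrow(d) == 0) return(empty)
  d <- d[order(d$chrom, d$pos), ]

  cands <- list()
  for (ch in unique(d$chrom)) {
    v <- d[d$chrom == ch, ]
    brk <- c(FALSE, diff(v$pos) > max_gap |
               sign(v$delta_beta[-1]) != sign(v$delta_beta[-nrow(v)]))
    run_id <- cumsum(brk)
    for (r in unique(run_id)) {
      m <- v[run_id == r, ]
      if (nrow(m) < min_cpgs) next
      z <- stats::qnorm(m$p_value / 2, lower.tail = FALSE)
      zc <- sum(z) / sqrt(nrow(m))
      cands[[length(cands) + 1L]] <- tibble::tibble(
        chrom = ch, start = min(m$pos), end = max(m$pos),
        n_cpgs = nrow(m), cpg_ids = list(m$feature_id),
        combined_z = zc,
        combined_p = 2 * stats::pnorm(zc, lower.tail = FALSE),
        delta_beta = mean(m$delta_beta),
        direction = if (m$delta_beta[1] > 0) "up" else "down"
      )
    }
  }
  if (length(cands) == 0) return(empty)
  out <- dplyr::bind_rows(cands)
  out$fdr <- adjust_pvalues(out$combined_p, "bh")
  out <- out[out$fdr < fdr_threshold &
               abs(out$delta_beta) > delta_beta_threshold, ]
  out <- out[order(out$combined_p, out$chrom, out$start), ]
  out[c("chrom", "start", "end", "n_cpgs", "cpg_ids", "combined_z",
        "combined_p", "fdr", "delta_beta", "direction")]
}

#' Compare affected (ALD) samples against unrelated controls
#'
#' Two-group ordinary least squares on the transformed values (group
#' indicator ALD vs control, no family term — controls are unrelated),
#' equivalent to the classical pooled-variance two-sample comparison.
#' Intended for the lipid platform, where unrelated controls exist.
#'
#' @param x An [feature_matrix()] holding both sibling and control
#'   samples.
#' @param cohort A cohort tibble with at least two controls.
#' @param platform Platform tag; defaults to the matrix's own tag.
#' @param adjust_method See [adjust_pvalues()]; default Bonferroni.
#' @return A tibble of class `modifier_scan`: per feature `estimate`
#'   (= `log2fc` of ALD over control), `std_error`, `statistic`, `df`
#'   (`n - 2`), `p_value`, `p_adjusted`, and volcano coordinates
#'   `neg_log10_p_adjusted`.
#' @export
ald_vs_control_scan <- function(x, cohort, platform = NULL,
                                adjust_method = "bonferroni") {
  if (is.null(platform)) platform <- omic_platform(x)
  controls <- cohort_controls(cohort)
  if (length(controls) < 2) stop("need at least 2 controls", call. = FALSE)
  x_tbl <- tibble::as_tibble(as.data.frame(x))
  samples <- intersect(cohort$sample, names(x_tbl))
  missing_s <- setdiff(cohort$sample, samples)
  if (length(missing_s) > 0) {
    stop("matrix lacks cohort sample(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  values <- as.matrix(x_tbl[samples])
  rownames(values) <- x_tbl$feature_id
  drop <- rowSums(!is.finite(values)) > 0
  if (platform == "rna") drop <- drop | rowSums(values) == 0
  if (platform %in% c("lipid", "protein")) drop <- drop | rowSums(values <= 0) > 0
  values <- values[!drop, , drop = FALSE]

  Y <- platform_transform(values, platform)
  ald <- as.numeric(cohort$phenotype[match(samples, cohort$sample)] != "control")
  X <- cbind(1, ald = ald)
  n <- ncol(Y)
  xtx_inv <- solve(crossprod(X))
  coefs <- Y %*% t(xtx_inv %*% t(X))
  res <- Y - coefs %*% t(X)
  df <- n - 2L
  sigma2 <- unname(rowSums(res^2) / df)
  degenerate <- sigma2 < 1e-16 * unname(pmax(rowMeans(Y^2), 1))
  est <- unname(coefs[, 2])
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tstat <- est / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  se[degenerate] <- NA_real_
  tstat[degenerate] <- NA_real_
  pval[degenerate] <- NA_real_

  out <- tibble::tibble(
    feature_id = rownames(values), platform = platform,
    estimate = est, std_error = se, statistic = tstat, df = df,
    p_value = pval,
    p_adjusted = adjust_pvalues(pval, adjust_method),
    log2fc = est,
    neg_log10_p_adjusted = -log10(adjust_pvalues(pval, adjust_method)),
    residual_var = sigma2, degenerate = degenerate
  )
  out <- out[order(out$p_value, out$feature_id), ]
  structure(out, platform = platform, comparison = "ald_vs_control",
            class = c("modifier_scan", class(out)))
}
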