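# Sequential sum-of-squares engine shared by the per-feature and
# matrix-wide variance partitions. Entry order: family -> age ->
# phenotype -> phenotype:age; fractions are term SS over total SS.
sequential_ss <- function(Y, ald_cohort, include_age = FALSE) {
  n <- nrow(ald_cohort)
  rho <- as.numeric(ald_cohort$phenotype == "CALD")
  fam <- factor(ald_cohort$family)
  terms <- list(family = stats::model.matrix(~fam)[, -1, drop = FALSE])
  if (include_age) terms$age <- cbind(age = ald_cohort$age)
  terms$phenotype <- cbind(rho = rho)
  if (include_age) terms$`phenotype:age` <- cbind(rho_age = rho * ald_cohort$age)

  Yt <- t(Y)                      # samples x features
  center <- colMeans(Yt)
  total_ss <- colSums(sweep(Yt, 2, center)^2)

  X <- matrix(1, n, 1)
  rss_prev <- total_ss
  ss <- matrix(NA_real_, length(terms), ncol(Yt),
               dimnames = list(names(terms), NULL))
  for (k in seq_along(terms)) {
    X <- cbind(X, terms[[k]])
    res <- qr.resid(qr(X), Yt)
    rss <- colSums(res^2)
    ss[k, ] <- rss_prev - rss
    rss_prev <- rss
  }
  rbind(ss, residual = rss_prev, total = total_ss)
}

#' Partition a feature's variance into model components
#'
#' Decomposes the total sum of squares by sequential (type I) entry of
#' the model terms in the order family, age, phenotype, phenotype-by-age
#' (age terms only when `include_age`), with the remainder as residual.
#' Entering family before phenotype is conservative for the phenotype
#' fraction. Fractions are term SS over total SS and sum to one.
#'
#' @inheritParams fit_feature_model
#' @return One-row tibble with columns `family`, `age`, `phenotype`,
#'   `phenotype_age`, `residual` (age columns `NA` when not included) and
#'   `undefined` (`TRUE` for constant input, where fractions do not
#'   exist).
#' @export
partition_variance <- function(y, cohort, include_age = FALSE) {
  ald <- cohort[cohort$phenotype != "control", ]
  if (!is.null(names(y))) y <- y[ald$sample]
  stopifnot(length(y) == nrow(ald))
  ss <- sequential_ss(matrix(y, nrow = 1), ald, include_age = include_age)
  total <- ss["total", 1]
  if (!is.finite(total) || total <= 0) {
    return(tibble::tibble(family = NA_real_, age = NA_real_,
                          phenotype = NA_real_, phenotype_age = NA_real_,
                          residual = NA_real_, undefined = TRUE))
  }
  fr <- ss[, 1] / total
  tibble::tibble(
    family = fr[["family"]],
    age = if (include_age) fr[["age"]] else NA_real_,
    phenotype = fr[["phenotype"]],
    phenotype_age = if (include_age) fr[["phenotype:age"]] else NA_real_,
    residual = fr[["residual"]],
    undefined = FALSE
  )
}

#' Partition variance for every feature of a platform matrix
#'
#' Applies [partition_variance()]'s decomposition to each feature of a
#' transformed platform matrix (same transforms as
#' [run_platform_scan()]). Age terms are included for dnam.
#'
#' @inheritParams run_platform_scan
#' @return Tibble with one row per retained feature: `feature_id`,
#'   `platform`, the fraction columns of [partition_variance()], and
#'   `undefined`.
#' @export
partition_variance_scan <- function(x, cohort, platform = NULL,
                                    include_age = NULL) {
  if (is.null(platform)) platform <- omic_platform(x)
  if (is.null(include_age)) include_age <- platform == "dnam"
  ald <- cohort[cohort$phenotype != "control", ]
  x_tbl <- tibble::as_tibble(as.data.frame(x))
  values <- as.matrix(x_tbl[ald$sample])
  rownames(values) <- x_tbl$feature_id
  drop <- rowSums(!is.finite(values)) > 0
  if (platform == "rna") drop <- drop | rowSums(values) == 0
  if (platform %in% c("lipid", "protein")) drop <- drop | rowSums(values <= 0) > 0
  values <- values[!drop, , drop = FALSE]
  Y <- platform_transform(values, platform)

  ss <- sequential_ss(Y, ald, include_age = include_age)
  total <- ss["total", ]
  undef <- !is.finite(total) | total <= 0
  frac <- function(term) {
    out <- ifelse(undef, NA_real_, ss[term, ] / total)
    unname(out)
  }
  tibble::tibble(
    feature_id = rownames(values),
    platform = platform,
    family = frac("family"),
    age = if (include_age) frac("age") else NA_real_,
    phenotype = frac("phenotype"),
    phenotype_age = if (include_age) frac("phenotype:age") else NA_real_,
    residual = frac("residual"),
    undefined = undef
  )
}

subset_label <- function(left_out) {
  if (length(left_out) == 0) "all_families"
  else paste0("wo_", paste(sort(left_out), collapse = "_"))
}

#' Re-run the phenotype scan over leave-families-out cohort subsets
#'
#' For every family subset obtained by leaving out up to `max_leave_out`
#' families, restricts the cohort and matrix to the retained families
#' (platform transforms, e.g. rna library sizes, are recomputed on the
#' retained samples only), re-runs [run_platform_scan()] and collects the
#' features significant at `p_threshold`. With 6 families and
#' `max_leave_out = 2` this yields 1 + 6 + 15 = 22 labeled runs.
#'
#' @inheritParams run_platform_scan
#' @param max_leave_out Maximum number of families left out (>= 0); at
#'   least two families must remain.
#' @param p_threshold Nominal significance cutoff for hit sets (default
#'   0.05).
#' @return Tibble of class `subset_hits`: `label` (`all_families`,
#'   `wo_<fam>`, `wo_<fam>_<fam>`, ...), `left_out` (list), `n_families`,
#'   `hits` (list of significant feature ids), `scan` (list of the full
#'   scan tibbles).
#' @export
leave_families_out_scan <- function(x, cohort, max_leave_out = 2,
                                    p_threshold = 0.05, platform = NULL,
                                    include_age = NULL) {
  if (is.null(platform)) platform <- omic_platform(x)
  ald <- cohort[cohort$phenotype != "control", ]
  fams <- sort(unique(ald$family))
  if (length(fams) - max_leave_out < 2) {
    stop("at least two families must remain after leave-out", call. = FALSE)
  }
  combos <- list(character(0))
  for (k in seq_len(max_leave_out)) {
    combos <- c(combos, utils::combn(fams, k, simplify = FALSE))
  }
  out <- purrr::map(combos, function(lo) {
    keep <- cohort[cohort$phenotype == "control" |
                     !(cohort$family %in% lo), ]
    keep_cohort <- cohort_design(unclass_cohort(keep))
    scan <- run_platform_scan(x, keep_cohort, platform = platform,
                              include_age = include_age)
    hits <- scan$feature_id[!is.na(scan$p_value) &
                              scan$p_value < p_threshold]
    tibble::tibble(
      label = subset_label(lo),
      left_out = list(sort(lo)),
      n_families = length(fams) - length(lo),
      hits = list(sort(hits)),
      scan = list(scan)
    )
  })
  out <- dplyr::bind_rows(out)
  structure(out, p_threshold = p_threshold, platform = platform,
            class = c("subset_hits", class(out)))
}

#' Upset partition of leave-out hit sets
#'
#' Applies the same exact disjoint-partition semantics as
#' [intersect_discordant_sets()] to the per-subset significant feature
#' sets: each feature is counted once, under the precise combination of
#' subset labels whose hit sets contain it.
#'
#' @param hit_sets A [leave_families_out_scan()] result, or any tibble
#'   with a `label` column and a `hits` list-column.
#' @return An `upset_partition` (see [intersect_discordant_sets()]);
#'   elements are feature ids.
#' @export
upset_summary <- function(hit_sets) {
  long <- tidyr::unnest(
    tibble::as_tibble(hit_sets)[c("label", "hits")],
    cols = "hits")
  if (nrow(long) == 0) {
    return(intersect_discordant_sets(
      tibble::tibble(family = character(), category = character(),
                     variant_id = character())))
  }
  intersect_discordant_sets(tibble::tibble(
    family = long$label, category = "hits", variant_id = long$hits))
}
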