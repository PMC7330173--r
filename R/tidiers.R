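#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-feature family-cofactor fit
#'
#' @param x A [fit_feature_model()] result.
#' @param ... Unused.
#' @return One row per reported term (`phenotype`, and `age` when
#'   included): `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.feature_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = "phenotype",
    estimate = x$estimate,
    std.error = x$std_error,
    statistic = x$statistic,
    p.value = x$p_value
  )
  if (x$include_age) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "age", estimate = x$age_estimate,
      std.error = x$age_std_error,
      statistic = x$age_estimate / x$age_std_error,
      p.value = 2 * stats::pt(-abs(x$age_estimate / x$age_std_error), x$df)
    ))
  }
  out
}

#' Glance at a single-feature family-cofactor fit
#'
#' @param x A [fit_feature_model()] result.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `n.families`, `df.residual`, `sigma`,
#'   `degenerate`.
#' @export
glance.feature_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    n.families = x$n_families,
    df.residual = x$df,
    sigma = sqrt(x$residual_var),
    degenerate = x$degenerate
  )
}

#' Tidy an upset partition
#'
#' @param x An [intersect_discordant_sets()] / [upset_summary()] result.
#' @param ... Unused.
#' @return The partition tibble (`category`, `families`, `degree`, `n`),
#'   without the element list-column.
#' @export
tidy.upset_partition <- function(x, ...) {
  x$partition[c("category", "families", "degree", "n")]
}

#' Tidy a segregation report
#'
#' @param x A [segregation_check()] result.
#' @param ... Unused.
#' @return The per-family tibble with the variant id attached.
#' @export
tidy.segregation_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(variant_id = x$variant_id), x$families)
}

#' Glance at a segregation report
#'
#' @param x A [segregation_check()] result.
#' @param ... Unused.
#' @return One-row tibble: `variant_id`, `n_informative`, `n_discordant`,
#'   `perfectly_segregates`, `shared_by_all_cald`.
#' @export
glance.segregation_report <- function(x, ...) {
  tibble::tibble(
    variant_id = x$variant_id,
    n_informative = sum(x$families$informative),
    n_discordant = sum(x$families$discordant),
    perfectly_segregates = x$perfectly_segregates,
    shared_by_all_cald = x$shared_by_all_cald
  )
}
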