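apoe_haplotype <- function(a429358, a7412) {
  # haplotype (rs429358, rs7412) -> epsilon allele
  key <- paste(a429358, a7412)
  switch(key,
    "T T" = "ε2",
    "T C" = "ε3",
    "C C" = "ε4",
    "C T" = "ε1",
    stop("APOE alleles must be T or C", call. = FALSE)
  )
}

format_apoe <- function(h1, h2) {
  e <- sort(c(h1, h2))
  paste(e, collapse = "/")
}

#' Call the APOE epsilon genotype from rs429358 and rs7412
#'
#' The common APOE isoforms are haplotypes of two coding SNPs: with
#' (rs429358, rs7412) alleles, T-T is \eqn{\epsilon}2, T-C is
#' \eqn{\epsilon}3, C-C is \eqn{\epsilon}4 and the rare C-T is
#' \eqn{\epsilon}1. Unphased diploid genotypes resolve uniquely whenever
#' at most one site is heterozygous. The double-heterozygote is ambiguous
#' (\eqn{\epsilon}2/\eqn{\epsilon}4 or \eqn{\epsilon}1/\eqn{\epsilon}3):
#' it is reported as \eqn{\epsilon}2/\eqn{\epsilon}4 — the
#' \eqn{\epsilon}1 haplotype being vanishingly rare — and flagged.
#'
#' @param gt_rs429358,gt_rs7412 Unphased base genotypes, e.g. `"T/C"`
#'   (allele order within a genotype does not matter). Vectorized.
#' @return Tibble with one row per input: `rs429358`, `rs7412`,
#'   `genotype` (e.g. `"ε3/ε4"`), `ambiguous`.
#' @export
#' @examples
#' call_apoe("T/T", "C/C")  # epsilon3/epsilon3
#' call_apoe("T/C", "C/C")  # epsilon3/epsilon4
call_apoe <- function(gt_rs429358, gt_rs7412) {
  stopifnot(length(gt_rs429358) == length(gt_rs7412))
  bad <- !grepl("^[TC][/|][TC]$", c(gt_rs429358, gt_rs7412))
  if (any(bad)) {
    stop("APOE alleles must be T or C, got '",
         paste(unique(c(gt_rs429358, gt_rs7412)[bad]), collapse = "', '"),
         "'", call. = FALSE)
  }
  parse_gt <- function(g) strsplit(gsub("|", "/", g, fixed = TRUE),
                                   "/", fixed = TRUE)[[1]]
  out <- purrr::map2(gt_rs429358, gt_rs7412, function(g1, g2) {
    a <- parse_gt(g1)
    b <- parse_gt(g2)
    het1 <- a[1] != a[2]
    het2 <- b[1] != b[2]
    if (het1 && het2) {
      tibble::tibble(genotype = format_apoe("ε2", "ε4"),
                     ambiguous = TRUE)
    } else if (!het1) {
      tibble::tibble(
        genotype = format_apoe(apoe_haplotype(a[1], b[1]),
                               apoe_haplotype(a[2], b[2])),
        ambiguous = FALSE)
    } else {
      tibble::tibble(
        genotype = format_apoe(apoe_haplotype(a[1], b[1]),
                               apoe_haplotype(a[2], b[2])),
        ambiguous = FALSE)
    }
  })
  dplyr::bind_cols(
    tibble::tibble(rs429358 = gt_rs429358, rs7412 = gt_rs7412),
    dplyr::bind_rows(out)
  )
}

alt_count <- function(gt) {
  c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt]
}

#' Check phenotype segregation of a candidate variant
#'
#' Reports, per family, whether the brothers' genotypes differ and which
#' brother carries more alternate alleles, plus two cohort-level
#' booleans: `perfectly_segregates` (every family discordant in the same
#' direction) and `shared_by_all_cald` (all CALD patients share one
#' genotype that no non-CALD patient carries). Families with a missing
#' genotype are marked uninformative.
#'
#' @param variant_id The variant to check.
#' @param geno Long variant tibble.
#' @param cohort A cohort tibble.
#' @return List of class `segregation_report` with `variant_id`,
#'   `families` (tibble `family`, `gt_cald`, `gt_noncald`, `informative`,
#'   `discordant`, `direction`), `perfectly_segregates` and
#'   `shared_by_all_cald`.
#' @export
segregation_check <- function(variant_id, geno, cohort) {
  g <- geno[geno$variant_id == variant_id, c("sample", "gt")]
  if (nrow(g) == 0) stop("variant '", variant_id, "' not in table",
                         call. = FALSE)
  pairs <- cohort_pairs(cohort)
  gt_of <- function(s) {
    v <- g$gt[g$sample == s]
    if (length(v) == 0) "missing" else v[1]
  }
  fam <- purrr::map(seq_len(nrow(pairs)), function(i) {
    gc <- gt_of(pairs$cald[i])
    gn <- gt_of(pairs$noncald[i])
    informative <- gc != "missing" && gn != "missing"
    disc <- informative && gc != gn
    dir <- if (!disc) NA_character_ else {
      d <- alt_count(gc) - alt_count(gn)
      if (d > 0) "CALD" else "non-CALD"
    }
    tibble::tibble(family = pairs$family[i], gt_cald = gc, gt_noncald = gn,
                   informative = informative, discordant = disc,
                   direction = dir)
  })
  fam <- dplyr::bind_rows(fam)

  perfect <- all(fam$informative) && all(fam$discordant) &&
    dplyr::n_distinct(fam$direction) == 1L
  cald_gts <- fam$gt_cald
  shared <- all(fam$informative) &&
    dplyr::n_distinct(cald_gts) == 1L &&
    !any(fam$gt_noncald == cald_gts[1])

  structure(list(variant_id = variant_id, families = fam,
                 perfectly_segregates = perfect,
                 shared_by_all_cald = shared),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("# segregation_report: %s\n", x$variant_id))
  print(x$families)
  cat(sprintf("perfectly_segregates: %s; shared_by_all_cald: %s\n",
              x$perfectly_segregates, x$shared_by_all_cald))
  invisible(x)
}
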