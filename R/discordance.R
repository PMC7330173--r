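#' The four discordance categories
#' @return Character vector of the category labels.
#' @export
discordance_categories <- function() {
  c("dominant_damaging", "dominant_protective",
    "recessive_damaging", "recessive_protective")
}

#' Classify a sibling genotype pair into a discordance category
#'
#' The carrier genotype defines the genotypic mode (heterozygous carrier:
#' dominant; homozygous carrier: recessive) and the carrier's phenotype
#' defines the direction (CALD carrier: damaging; non-CALD carrier:
#' protective):
#'
#' * `(0/1, 0/0)` dominant damaging; `(0/0, 0/1)` dominant protective
#' * CALD `1/1` with non-CALD `0/0` or `0/1`: recessive damaging
#' * non-CALD `1/1` with CALD `0/0` or `0/1`: recessive protective
#' * every other called pair (including concordant pairs): `"none"`
#'
#' Dominant categories are strict (`0/1` vs `0/0`) and the homozygous
#' carrier always classifies as recessive, so the four categories are
#' mutually exclusive. Missing genotypes return `NA` (the pair is not
#' classifiable and the family is skipped for that variant).
#'
#' @param gt_cald,gt_noncald Genotype calls of the CALD and non-CALD
#'   brother: `"0/0"`, `"0/1"`, `"1/1"` or `"missing"`. Vectorized.
#' @return Character vector over
#'   `c(discordance_categories(), "none")`, `NA` where either input is
#'   missing.
#' @export
#' @examples
#' classify_pair_genotype("0/1", "0/0")  # dominant_damaging
#' classify_pair_genotype("1/1", "0/1")  # recessive_damaging
classify_pair_genotype <- function(gt_cald, gt_noncald) {
  valid <- c("0/0", "0/1", "1/1")
  allowed <- c(valid, "missing")
  bad <- (!is.na(gt_cald) & !gt_cald %in% allowed) |
         (!is.na(gt_noncald) & !gt_noncald %in% allowed)
  if (any(bad)) {
    stop("unrecognized genotype call(s)", call. = FALSE)
  }
  out <- rep(NA_character_, length(gt_cald))
  called <- !is.na(gt_cald) & !is.na(gt_noncald) &
    gt_cald %in% valid & gt_noncald %in% valid
  c_ <- gt_cald[called]
  n_ <- gt_noncald[called]
  res <- rep("none", length(c_))
  res[c_ == "1/1" & n_ %in% c("0/0", "0/1")] <- "recessive_damaging"
  res[n_ == "1/1" & c_ %in% c("0/0", "0/1")] <- "recessive_protective"
  res[c_ == "0/1" & n_ == "0/0"] <- "dominant_damaging"
  res[c_ == "0/0" & n_ == "0/1"] <- "dominant_protective"
  out[called] <- res
  out
}

#' Build per-family per-category discordant variant sets
#'
#' Classifies every (variant, family) pair with both brothers' genotypes
#' called; pairs with a missing genotype are skipped for that family only.
#'
#' @param geno Long variant tibble (see [read_vcf()]).
#' @param cohort A cohort tibble covering the genotyped samples.
#' @return Tibble with columns `family`, `category`, `variant_id`, one row
#'   per discordant (variant, family) pair.
#' @export
build_discordant_sets <- function(geno, cohort) {
  pairs <- cohort_pairs(cohort)
  g <- geno[c("variant_id", "sample", "gt")]
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    gc <- g[g$sample == pairs$cald[i], c("variant_id", "gt")]
    gn <- g[g$sample == pairs$noncald[i], c("variant_id", "gt")]
    m <- dplyr::inner_join(gc, gn, by = "variant_id",
                           suffix = c("_cald", "_noncald"))
    cat <- classify_pair_genotype(m$gt_cald, m$gt_noncald)
    keep <- !is.na(cat) & cat != "none"
    tibble::tibble(family = pairs$family[i],
                   category = cat[keep],
                   variant_id = m$variant_id[keep])
  })
  dplyr::bind_rows(out)
}

# exact disjoint partition of elements by the combination of sets holding them
exact_partition_tbl <- function(df, set_col, el_col) {
  stopifnot(all(c(set_col, el_col) %in% names(df)))
  df <- dplyr::distinct(df[c(set_col, el_col)])
  grouped <- dplyr::summarise(
    dplyr::group_by(df, .data[[el_col]]),
    sets = paste(sort(unique(.data[[set_col]])), collapse = "&"),
    degree = dplyr::n_distinct(.data[[set_col]]),
    .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(grouped, .data$sets, .data$degree),
    n = dplyr::n(),
    elements = list(sort(.data[[el_col]])),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$sets)
}

#' Exact cross-family (upset) intersection of discordant sets
#'
#' Computes, per category, the exact disjoint partition of discordant
#' variants by the precise subset of families in which they are
#' discordant with that category. A variant discordant in families 1, 2
#' and 3 is counted once, in the `fam1&fam2&fam3` cell only — not in any
#' sub-combination — matching upset-plot semantics. Depth-k marginals
#' (number of variants whose family set has size k) derive from the
#' partition.
#'
#' Intersection is within category: a variant dominant-damaging in one
#' family and recessive-damaging in another does not intersect.
#'
#' @param sets Tibble `family`, `category`, `variant_id` (from
#'   [build_discordant_sets()], or any set membership table).
#' @return List of class `upset_partition` with elements `partition`
#'   (tibble `category`, `families`, `degree`, `n`, `variant_ids`
#'   list-column) and `depth` (tibble `category`, `degree`, `n`).
#' @export
intersect_discordant_sets <- function(sets) {
  sets <- tibble::as_tibble(sets)
  if (nrow(sets) == 0) {
    empty <- tibble::tibble(category = character(), families = character(),
                            degree = integer(), n = integer(),
                            variant_ids = list())
    return(structure(
      list(partition = empty,
           depth = tibble::tibble(category = character(), degree = integer(),
                                  n = integer())),
      class = "upset_partition"))
  }
  parts <- dplyr::group_by(sets, .data$category)
  parts <- dplyr::group_modify(parts, function(d, key) {
    p <- exact_partition_tbl(d, "family", "variant_id")
    names(p)[names(p) == "sets"] <- "families"
    names(p)[names(p) == "elements"] <- "variant_ids"
    p
  })
  parts <- dplyr::ungroup(parts)
  depth <- dplyr::summarise(
    dplyr::group_by(parts, .data$category, .data$degree),
    n = sum(.data$n), .groups = "drop"
  )
  structure(list(partition = parts, depth = depth),
            class = "upset_partition")
}

#' @export
print.upset_partition <- function(x, ...) {
  cat("# upset_partition\n## depth marginals\n")
  print(x$depth)
  cat("## partition cells\n")
  print(x$partition)
  invisible(x)
}

#' Variants (or elements) intersecting at full depth
#'
#' @param x An `upset_partition`.
#' @param n_sets The number of sets defining full depth (e.g. number of
#'   families).
#' @return Tibble `category`, `variant_id` of the full-depth elements.
#' @export
full_depth_elements <- function(x, n_sets) {
  p <- x$partition[x$partition$degree == n_sets, ]
  if (nrow(p) == 0) {
    return(tibble::tibble(category = character(), variant_id = character()))
  }
  tidyr::unnest(p[c("category", "variant_ids")],
                cols = "variant_ids", names_repair = "minimal") |>
    stats::setNames(c("category", "variant_id"))
}

#' Scan for variants carried exclusively by one phenotype group
#'
#' Finds variants where every sample of the carrier group has exactly
#' `carrier_genotype` while no sample of the opposite group does (e.g.
#' heterozygous in all CALD patients with no non-CALD patient
#' heterozygous). Variants with any missing genotype among the sibling
#' samples are excluded.
#'
#' @param geno Long variant tibble.
#' @param cohort A cohort tibble.
#' @param carrier_genotype The shared genotype call, default `"0/1"`.
#' @param carrier_group `"CALD"` or `"non-CALD"`.
#' @return Character vector of variant ids.
#' @export
shared_carrier_scan <- function(geno, cohort, carrier_genotype = "0/1",
                                carrier_group = c("CALD", "non-CALD")) {
  carrier_group <- match.arg(carrier_group)
  carriers <- cohort$sample[cohort$phenotype == carrier_group]
  opposite <- cohort$sample[cohort$phenotype ==
                              setdiff(c("CALD", "non-CALD"), carrier_group)]
  stopifnot(length(carriers) > 0, length(opposite) > 0)
  g <- geno[geno$sample %in% c(carriers, opposite), ]
  res <- dplyr::summarise(
    dplyr::group_by(g, .data$variant_id),
    ok = all(.data$gt != "missing") &&
      all(.data$gt[.data$sample %in% carriers] == carrier_genotype) &&
      all(.data$gt[.data$sample %in% opposite] != carrier_genotype),
    .groups = "drop"
  )
  sort(res$variant_id[res$ok])
}

#' Group variants into haploblocks by genomic proximity
#'
#' Finds maximal runs of the listed variants on one chromosome whose
#' consecutive positions are at most `max_gap` bp apart, keeping runs with
#' at least `min_size` members. When every member of a block shares an
#' identical per-sample genotype vector the shared pattern is reported.
#'
#' @param variant_ids Variant ids to group (e.g. a [shared_carrier_scan()]
#'   result).
#' @param geno Long variant tibble holding these variants.
#' @param max_gap Maximum inter-variant gap in bp.
#' @param min_size Minimum number of member variants.
#' @return Tibble `chrom`, `start`, `end`, `span`, `n_variants`,
#'   `variant_ids` (list), `pattern` (shared genotype pattern or `NA`).
#' @export
detect_haploblocks <- function(variant_ids, geno, max_gap = 50000,
                               min_size = 3) {
  vars <- dplyr::distinct(geno[geno$variant_id %in% variant_ids,
                               c("variant_id", "chrom", "pos")])
  if (nrow(vars) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), span = integer(),
                          n_variants = integer(), variant_ids = list(),
                          pattern = character()))
  }
  vars <- vars[order(vars$chrom, vars$pos), ]
  blocks <- list()
  for (ch in unique(vars$chrom)) {
    v <- vars[vars$chrom == ch, ]
    run_id <- cumsum(c(1, diff(v$pos) > max_gap))
    for (r in unique(run_id)) {
      m <- v[run_id == r, ]
      if (nrow(m) < min_size) next
      gsub_ <- geno[geno$variant_id %in% m$variant_id, ]
      pat <- dplyr::summarise(
        dplyr::group_by(gsub_, .data$variant_id),
        p = paste(.data$gt[order(.data$sample)], collapse = ","),
        .groups = "drop"
      )
      pattern <- if (dplyr::n_distinct(pat$p) == 1L) pat$p[1] else NA_character_
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        chrom = ch, start = min(m$pos), end = max(m$pos),
        span = max(m$pos) - min(m$pos), n_variants = nrow(m),
        variant_ids = list(m$variant_id[order(m$pos)]), pattern = pattern
      )
    }
  }
  dplyr::bind_rows(blocks)
}

#' Classify a mitochondrial allele fraction into a heteroplasmy state
#'
#' @param af Alt-allele fraction(s) in \[0, 1\].
#' @param low,high Heteroplasmic band bounds (defaults 0.05 and 0.95):
#'   below `low` is `absent`, within \[`low`, `high`\] is `heteroplasmic`,
#'   above `high` is `homoplasmic`.
#' @return Character vector of states; `NA` input gives `NA`.
#' @export
classify_heteroplasmy <- function(af, low = 0.05, high = 0.95) {
  if (any(af < 0 | af > 1, na.rm = TRUE)) {
    stop("allele fraction outside [0, 1]", call. = FALSE)
  }
  out <- rep(NA_character_, length(af))
  ok <- !is.na(af)
  out[ok & af < low] <- "absent"
  out[ok & af >= low & af <= high] <- "heteroplasmic"
  out[ok & af > high] <- "homoplasmic"
  out
}

#' Mitochondrial heteroplasmy discordance between brothers
#'
#' A mitochondrial variant is family-discordant when the two brothers'
#' heteroplasmy states ([classify_heteroplasmy()]) differ. Per-family
#' discordant variant sets are aggregated to the gene level (union of
#' genes hit by discordant variants) and both levels are intersected
#' across families with the exact upset partition.
#'
#' @param geno Long variant tibble of mitochondrial records with `af`
#'   filled.
#' @param cohort A cohort tibble.
#' @param annotation Tibble `variant_id`, `gene`.
#' @param low,high Heteroplasmy band (see [classify_heteroplasmy()]).
#' @return List with `variant_sets` and `gene_sets` (tibbles `family`,
#'   `category`, `variant_id`) and their `variant_partition` and
#'   `gene_partition` ([intersect_discordant_sets()] results).
#' @export
mito_discordance <- function(geno, cohort, annotation,
                             low = 0.05, high = 0.95) {
  pairs <- cohort_pairs(cohort)
  g <- geno[c("variant_id", "sample", "af")]
  out <- purrr::map(seq_len(nrow(pairs)), function(i) {
    gc <- g[g$sample == pairs$cald[i], c("variant_id", "af")]
    gn <- g[g$sample == pairs$noncald[i], c("variant_id", "af")]
    m <- dplyr::inner_join(gc, gn, by = "variant_id",
                           suffix = c("_cald", "_noncald"))
    sc <- classify_heteroplasmy(m$af_cald, low, high)
    sn <- classify_heteroplasmy(m$af_noncald, low, high)
    keep <- !is.na(sc) & !is.na(sn) & sc != sn
    tibble::tibble(family = pairs$family[i], category = "mito_discordant",
                   variant_id = m$variant_id[keep])
  })
  variant_sets <- dplyr::bind_rows(out)
  gene_sets <- dplyr::inner_join(variant_sets, annotation, by = "variant_id")
  gene_sets <- dplyr::distinct(tibble::tibble(
    family = gene_sets$family, category = "mito_gene",
    variant_id = gene_sets$gene
  ))
  list(
    variant_sets = variant_sets,
    gene_sets = gene_sets,
    variant_partition = intersect_discordant_sets(variant_sets),
    gene_partition = intersect_discordant_sets(gene_sets)
  )
}
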