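#' Construct a platform-tagged feature matrix
#'
#' Feature matrices are wide tibbles: a `feature_id` column followed by one
#' numeric column per sample. The platform tag, the feature-to-gene
#' annotation and (for methylation) CpG coordinates travel as attributes so
#' the object still behaves as a plain tibble.
#'
#' Platform conventions: `lipid` and `protein` hold linear (positive)
#' abundances, `rna` holds raw non-negative integer counts, `dnam` holds
#' methylation beta values in \[0, 1\].
#'
#' @param values Data frame with a `feature_id` column and one column per
#'   sample.
#' @param platform One of `"lipid"`, `"rna"`, `"protein"`, `"dnam"`.
#' @param annotation Optional tibble `feature_id`, `gene` (one row per
#'   feature-gene link; features may map to several genes).
#' @param coords Optional tibble `feature_id`, `chrom`, `pos` (1-based CpG
#'   coordinates; dnam only).
#' @return A tibble of class `omic_matrix`.
#' @export
feature_matrix <- function(values, platform, annotation = NULL, coords = NULL) {
  platform <- match.arg(platform, c("lipid", "rna", "protein", "dnam"))
  x <- tibble::as_tibble(values)
  if (names(x)[1] != "feature_id") names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  if (anyDuplicated(x$feature_id)) {
    stop("duplicate feature id(s): ",
         paste(unique(x$feature_id[duplicated(x$feature_id)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) stop("feature values must be numeric", call. = FALSE)
  if (platform == "dnam") {
    if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
      stop("dnam beta values must lie in [0, 1]", call. = FALSE)
    }
  }
  if (platform == "rna") {
    if (any(vals < 0, na.rm = TRUE) ||
        any(abs(vals - round(vals)) > 1e-8, na.rm = TRUE)) {
      stop("rna values must be non-negative integer counts", call. = FALSE)
    }
  }
  if (!is.null(annotation)) {
    annotation <- tibble::as_tibble(annotation)
    stopifnot(all(c("feature_id", "gene") %in% names(annotation)))
  }
  if (!is.null(coords)) {
    coords <- tibble::as_tibble(coords)
    stopifnot(all(c("feature_id", "chrom", "pos") %in% names(coords)))
  }
  structure(x,
            platform = platform, annotation = annotation, coords = coords,
            class = c("omic_matrix", class(x)))
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("# omic_matrix: platform=%s, %d features x %d samples\n",
              omic_platform(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Platform tag of a feature matrix
#' @param x An `omic_matrix`.
#' @return Character scalar.
#' @export
omic_platform <- function(x) attr(x, "platform", exact = TRUE)

#' Feature-to-gene annotation of a feature matrix
#' @param x An `omic_matrix`.
#' @return Tibble `feature_id`, `gene`, or `NULL`.
#' @export
omic_annotation <- function(x) attr(x, "annotation", exact = TRUE)

#' CpG coordinates of a methylation matrix
#' @param x An `omic_matrix`.
#' @return Tibble `feature_id`, `chrom`, `pos`, or `NULL`.
#' @export
omic_coords <- function(x) attr(x, "coords", exact = TRUE)

#' Read a feature matrix from a delimited file
#'
#' Expects a tab-delimited file whose header row holds sample ids and whose
#' first column holds feature ids. Platform invariants (counts for rna,
#' \[0,1\] for dnam) are enforced on read.
#'
#' @param path Path to the matrix file.
#' @inheritParams feature_matrix
#' @param annotation Optional path to a two-column tab-delimited
#'   feature-to-gene table (header `feature_id`, `gene`), or a data frame.
#' @param coords Optional path to a tab-delimited CpG coordinate table
#'   (header `feature_id`, `chrom`, `pos`), or a data frame.
#' @return A tibble of class `omic_matrix`.
#' @export
read_feature_matrix <- function(path, platform, annotation = NULL, coords = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols())
  if (is.character(annotation)) {
    annotation <- readr::read_tsv(annotation, col_types = readr::cols())
  }
  if (is.character(coords)) {
    coords <- readr::read_tsv(coords, col_types = readr::cols())
  }
  feature_matrix(x, platform, annotation = annotation, coords = coords)
}

#' Write a feature matrix to a delimited file
#' @param x An `omic_matrix` (or plain wide data frame).
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path)
  invisible(path)
}

#' Write a results table deterministically
#'
#' Writes any per-feature or per-variant result tibble as tab-delimited
#' text, ordered by ascending p-value and then by id so output is
#' reproducible across runs.
#'
#' @param rows A data frame of results. The p-value column is taken as
#'   `p_value` (or `p`) when present; the id column is the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) > 0) {
    pcol <- intersect(c("p_value", "p"), names(rows))[1]
    idcol <- names(rows)[1]
    if (!is.na(pcol)) {
      rows <- rows[order(rows[[pcol]], rows[[idcol]]), ]
    } else {
      rows <- rows[order(rows[[idcol]]), ]
    }
  }
  readr::write_tsv(rows, path)
  invisible(path)
}

# ---- VCF ------------------------------------------------------------------

mito_chroms <- c("chrM", "chrMT", "MT", "M")

classify_variant_record <- function(chrom, ref, alt) {
  symbolic <- grepl("^<|\\[|\\]", alt)
  if (symbolic) {
    if (grepl("INS:ME|^<MEI", alt)) return("MEI")
    return("SV")
  }
  if (chrom %in% mito_chroms) return("mito")
  if (nchar(ref) == 1L && nchar(alt) == 1L) return("SNV")
  "indel"
}

normalize_gt <- function(gt, allele_index) {
  # gt: raw GT string; allele_index: which ALT allele this derived biallelic
  # record refers to (1-based within the site's ALT list)
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  gt <- gsub("\\|", "/", gt)
  parts <- strsplit(gt, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !all(grepl("^([0-9]+|\\.)$", parts))) {
    warning("malformed genotype '", gt, "' set to missing", call. = FALSE)
    return("missing")
  }
  if (any(parts == ".")) return("missing")
  n_alt <- sum(parts == as.character(allele_index))
  c("0/0", "0/1", "1/1")[n_alt + 1L]
}

#' Read a jointly genotyped multi-sample VCF into a long variant table
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), splits multiallelic sites into
#' biallelic records, normalizes genotypes to `0/0`, `0/1`, `1/1` or
#' `missing` with respect to each derived record's single ALT allele, and
#' extracts alt-allele fractions from allelic depths (`AD`, falling back to
#' a `FORMAT/AF` field) when present.
#'
#' Variant ids are `chrom:pos:ref:alt`; structural variants and mobile
#' element insertions (symbolic ALT alleles) keep the caller-assigned `ID`
#' verbatim. Records on the mitochondrial contig are classed `mito`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param cohort A cohort tibble; every non-control sample must appear in
#'   the VCF header. Only cohort samples are retained.
#' @return A long tibble with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `class`, `sample`, `gt`, `af`.
#' @export
read_vcf <- function(path, cohort) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]
  need <- cohort_ald_samples(cohort)
  absent <- setdiff(need, vcf_samples)
  if (length(absent) > 0) {
    stop("cohort sample(s) absent from VCF header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(cohort$sample, vcf_samples)

  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  ad_mat <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                     error = function(e) NULL)
  af_mat <- tryCatch(vcfR::extract.gt(vcf, element = "AF"),
                     error = function(e) NULL)
  fix <- vcf@fix

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    id <- fix[i, "ID"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    recs <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      alt <- alts[k]
      cls <- classify_variant_record(chrom, ref, alt)
      vid <- if (cls %in% c("SV", "MEI") && !is.na(id) && id != ".") {
        id
      } else {
        paste(chrom, pos, ref, alt, sep = ":")
      }
      gts <- vapply(keep, function(s) normalize_gt(gt_mat[i, s], k), character(1))
      afs <- rep(NA_real_, length(keep))
      if (!is.null(ad_mat)) {
        for (j in seq_along(keep)) {
          ad <- ad_mat[i, keep[j]]
          if (!is.na(ad)) {
            d <- suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
            if (length(d) >= k + 1L && sum(d, na.rm = TRUE) > 0) {
              afs[j] <- d[k + 1L] / sum(d, na.rm = TRUE)
            }
          }
        }
      }
      if (all(is.na(afs)) && !is.null(af_mat)) {
        for (j in seq_along(keep)) {
          a <- af_mat[i, keep[j]]
          if (!is.na(a)) {
            v <- suppressWarnings(as.numeric(strsplit(a, ",", fixed = TRUE)[[1]]))
            if (length(v) >= k) afs[j] <- v[k]
          }
        }
      }
      recs[[k]] <- tibble::tibble(
        variant_id = vid, chrom = chrom, pos = pos, ref = ref, alt = alt,
        class = cls, sample = keep, gt = unname(gts), af = afs
      )
    }
    out[[i]] <- dplyr::bind_rows(recs)
  }
  dplyr::bind_rows(out)
}

#' Write a long variant table as a minimal VCF 4.2 file
#'
#' Emits one biallelic VCF record per variant with `GT` (and `AD` derived
#' from the stored alt-allele fraction at a nominal depth of 100 when
#' fractions are present). The inverse of [read_vcf()] on tables the
#' simulator produces.
#'
#' @param geno Long variant tibble (see [read_vcf()] for columns).
#' @param path Output path.
#' @param depth Nominal total depth used to encode allele fractions as `AD`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, depth = 100L) {
  samples <- unique(geno$sample)
  vars <- dplyr::distinct(geno, .data$variant_id, .data$chrom, .data$pos,
                          .data$ref, .data$alt, .data$class)
  vars <- vars[order(vars$chrom, vars$pos, vars$variant_id), ]
  has_af <- any(!is.na(geno$af))
  fmt <- if (has_af) "GT:AD" else "GT"

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=discomod",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_af) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  gt_wide <- tidyr::pivot_wider(
    geno[c("variant_id", "sample", "gt", "af")],
    names_from = "sample", values_from = c("gt", "af")
  )
  gt_wide <- gt_wide[match(vars$variant_id, gt_wide$variant_id), ]

  lines <- character(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    cells <- character(length(samples))
    for (j in seq_along(samples)) {
      g <- gt_wide[[paste0("gt_", samples[j])]][i]
      g <- if (is.na(g) || g == "missing") "./." else g
      if (has_af) {
        a <- gt_wide[[paste0("af_", samples[j])]][i]
        ad <- if (is.na(a)) "." else {
          alt_d <- round(a * depth)
          paste(depth - alt_d, alt_d, sep = ",")
        }
        cells[j] <- paste(g, ad, sep = ":")
      } else {
        cells[j] <- g
      }
    }
    id_field <- if (vars$class[i] %in% c("SV", "MEI")) vars$variant_id[i] else "."
    lines[i] <- paste(c(vars$chrom[i], vars$pos[i], id_field, vars$ref[i],
                        vars$alt[i], ".", "PASS", ".", fmt, cells),
                      collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
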