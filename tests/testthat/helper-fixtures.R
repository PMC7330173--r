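# shared fixtures built in code

# a minimal 2-family cohort with fixed ages
toy_cohort <- function(n_families = 2) {
  cohort_design(tibble::tibble(
    sample = as.vector(rbind(paste0("F", 1:n_families, "_C"),
                             paste0("F", 1:n_families, "_N"))),
    family = rep(paste0("fam", 1:n_families), each = 2),
    phenotype = rep(c("CALD", "non-CALD"), n_families),
    age = rep(c(10, 12), n_families)
  ))
}

# long genotype tibble from a variants x samples genotype matrix
geno_from_matrix <- function(gt, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- 1000L * seq_len(nrow(gt))
  vid <- if (is.null(rownames(gt))) {
    paste(chrom, pos, "A", "G", sep = ":")
  } else rownames(gt)
  samples <- colnames(gt)
  tibble::tibble(
    variant_id = rep(vid, each = length(samples)),
    chrom = chrom,
    pos = rep(pos, each = length(samples)),
    ref = "A", alt = "G", class = "SNV",
    sample = rep(samples, nrow(gt)),
    gt = as.vector(t(gt)),
    af = NA_real_
  )
}

# independent re-statement of the category rule, used as an oracle
oracle_classify <- function(gc, gn) {
  if (gc == "missing" || gn == "missing") return(NA_character_)
  if (gc == "0/1" && gn == "0/0") return("dominant_damaging")
  if (gc == "0/0" && gn == "0/1") return("dominant_protective")
  if (gc == "1/1" && gn %in% c("0/0", "0/1")) return("recessive_damaging")
  if (gn == "1/1" && gc %in% c("0/0", "0/1")) return("recessive_protective")
  "none"
}

# brute-force exact upset partition: counts per (family subset, category)
# by enumerating every nonempty subset of families
oracle_partition <- function(sets_tbl, families) {
  out <- list()
  for (cat in unique(sets_tbl$category)) {
    d <- sets_tbl[sets_tbl$category == cat, ]
    fam_of <- split(d$family, d$variant_id)
    for (k in seq_along(families)) {
      for (combo in utils::combn(families, k, simplify = FALSE)) {
        n <- sum(vapply(fam_of, function(f) setequal(f, combo), logical(1)))
        if (n > 0) {
          out[[length(out) + 1L]] <- tibble::tibble(
            category = cat,
            families = paste(sort(combo), collapse = "&"),
            n = n)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

# Table 1 of the source cohort: APOE SNP genotypes and published epsilon calls
apoe_table1 <- function() {
  tibble::tribble(
    ~rs429358, ~rs7412, ~expected,
    "T/T", "C/C", "ε3/ε3",
    "T/T", "C/C", "ε3/ε3",
    "T/T", "C/C", "ε3/ε3",
    "T/T", "C/C", "ε3/ε3",
    "T/T", "C/C", "ε3/ε3",
    "T/T", "C/C", "ε3/ε3",
    "T/T", "T/T", "ε2/ε2",
    "T/T", "T/T", "ε2/ε2",
    "T/C", "C/C", "ε3/ε4",
    "T/C", "C/C", "ε3/ε4",
    "T/C", "C/C", "ε3/ε4",
    "T/C", "C/C", "ε3/ε4"
  )
}
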