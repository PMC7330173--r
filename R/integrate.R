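#' Collapse feature-level hits to gene-level hits
#'
#' Joins a hit table to its feature-to-gene annotation and keeps, per
#' (gene, platform), the single feature with the smallest p-value (ties
#' broken by feature id); the hit's direction (CALD relative to non-CALD)
#' comes from that feature's effect sign. Features mapping to several
#' genes contribute to each; unannotated features are dropped with a
#' count reported.
#'
#' @param hits A tibble of nominal hits with columns `feature_id`,
#'   `platform`, `p_value` and `log2fc` (e.g. a filtered
#'   [run_platform_scan()] result).
#' @param annotation Tibble `feature_id`, `gene` (multi-mapping allowed),
#'   e.g. [omic_annotation()].
#' @return Tibble `gene`, `platform`, `direction` (`"up"`/`"down"`),
#'   `p_value`, `feature_id`.
#' @export
map_features_to_genes <- function(hits, annotation) {
  hits <- tibble::as_tibble(hits)
  annotation <- tibble::as_tibble(annotation)
  n_unannotated <- sum(!hits$feature_id %in% annotation$feature_id)
  if (n_unannotated > 0) {
    message(n_unannotated, " hit feature(s) without gene annotation dropped")
  }
  m <- dplyr::inner_join(hits, annotation[c("feature_id", "gene")],
                         by = "feature_id", relationship = "many-to-many")
  if (nrow(m) == 0) {
    return(tibble::tibble(gene = character(), platform = character(),
                          direction = character(), p_value = numeric(),
                          feature_id = character()))
  }
  m <- m[order(m$p_value, m$feature_id), ]
  best <- dplyr::slice_head(dplyr::group_by(m, .data$gene, .data$platform),
                            n = 1)
  best <- dplyr::ungroup(best)
  out <- tibble::tibble(
    gene = best$gene,
    platform = best$platform,
    direction = ifelse(best$log2fc >= 0, "up", "down"),
    p_value = best$p_value,
    feature_id = best$feature_id
  )
  dplyr::arrange(out, .data$gene, .data$platform)
}

platform_order <- c("dnam", "rna", "protein")
arrow_of <- c(up = "↑", down = "↓")

#' Intersect gene-level hits across omics platforms
#'
#' Computes the four platform intersections of gene hit sets — DNAm-RNA,
#' DNAm-Protein, RNA-Protein and DNAm-RNA-Protein — and renders each
#' gene's per-platform directions as arrows in fixed platform order
#' (dnam, rna, protein), e.g. `"GENE(↑ – ↓)"` for a gene
#' hyper-methylated and down-regulated in CALD. Lipids, lacking a gene
#' mapping, do not participate.
#'
#' @param gene_hits A [map_features_to_genes()] result covering one or
#'   more of the platforms dnam, rna, protein (other platforms ignored).
#' @return Tibble `comparison` (e.g. `"DNAm and RNA"`), `gene`,
#'   `directions` (arrow string), `label` (`gene(arrows)`), one row per
#'   gene per intersection it belongs to.
#' @export
intersect_platform_hits <- function(gene_hits) {
  gene_hits <- tibble::as_tibble(gene_hits)
  gene_hits <- gene_hits[gene_hits$platform %in% platform_order, ]
  combos <- list(
    "DNAm and RNA" = c("dnam", "rna"),
    "DNAm and Protein" = c("dnam", "protein"),
    "RNA and Protein" = c("rna", "protein"),
    "DNAm and RNA and Protein" = c("dnam", "rna", "protein")
  )
  present <- unique(gene_hits$platform)
  out <- purrr::imap(combos, function(members, comp) {
    if (!all(members %in% present)) {
      return(tibble::tibble(comparison = character(), gene = character(),
                            directions = character(), label = character()))
    }
    sets <- lapply(members, function(p) {
      unique(gene_hits$gene[gene_hits$platform == p])
    })
    shared <- Reduce(intersect, sets)
    if (length(shared) == 0) {
      return(tibble::tibble(comparison = character(), gene = character(),
                            directions = character(), label = character()))
    }
    rows <- purrr::map(sort(shared), function(g) {
      dirs <- vapply(members, function(p) {
        gene_hits$direction[gene_hits$gene == g & gene_hits$platform == p][1]
      }, character(1))
      arr <- paste(arrow_of[dirs], collapse = " – ")
      tibble::tibble(comparison = comp, gene = g, directions = arr,
                     label = paste0(g, "(", arr, ")"))
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Select top hits of a scan for downstream fold-change analysis
#'
#' The union of the `n_top` smallest-p features and all features with
#' `p_value < p_threshold`.
#'
#' @param scan A [run_platform_scan()] result.
#' @param n_top Number of top features by p-value (default 10).
#' @param p_threshold Nominal cutoff (default 0.05).
#' @return Tibble `feature_id`, `platform`.
#' @export
select_top_hits <- function(scan, n_top = 10, p_threshold = 0.05) {
  scan <- tibble::as_tibble(scan)
  scan <- scan[!is.na(scan$p_value), ]
  scan <- scan[order(scan$p_value, scan$feature_id), ]
  keep <- union(utils::head(scan$feature_id, n_top),
                scan$feature_id[scan$p_value < p_threshold])
  tibble::tibble(feature_id = keep,
                 platform = scan$platform[match(keep, scan$feature_id)])
}

#' Per-family log2 fold-change matrix of selected features
#'
#' For each selected feature and each family, the log2 ratio of the CALD
#' brother's value over the non-CALD brother's. RNA counts are converted
#' to counts-per-million (library sizes from the sibling samples) with a
#' pseudocount of 0.5; lipid and protein abundances are used as-is
#' (features with non-positive abundances are dropped with a warning).
#' Working on within-family ratios removes between-family differences in
#' absolute level.
#'
#' @param matrices Named list of [feature_matrix()] objects keyed by
#'   platform (e.g. `list(rna = ..., protein = ..., lipid = ...)`).
#' @param cohort A cohort tibble.
#' @param selected Tibble `feature_id`, `platform` (e.g. from
#'   [select_top_hits()]).
#' @return Tibble of class `family_lfc`: `feature_id`, `platform`, one
#'   numeric column per family.
#' @export
build_family_lfc_matrix <- function(matrices, cohort, selected) {
  pairs <- cohort_pairs(cohort)
  selected <- tibble::as_tibble(selected)
  rows <- purrr::map(unique(selected$platform), function(p) {
    x <- matrices[[p]]
    if (is.null(x)) stop("no matrix supplied for platform '", p, "'",
                         call. = FALSE)
    x_tbl <- tibble::as_tibble(as.data.frame(x))
    sib <- intersect(cohort_ald_samples(cohort), names(x_tbl))
    values <- as.matrix(x_tbl[sib])
    rownames(values) <- x_tbl$feature_id
    feats <- selected$feature_id[selected$platform == p]
    feats <- intersect(feats, rownames(values))
    if (p == "rna") {
      lib <- colSums(values)
      values <- t(t(values) / lib * 1e6) + 0.5
    } else if (p %in% c("lipid", "protein")) {
      bad <- rowSums(values[feats, , drop = FALSE] <= 0) > 0
      if (any(bad)) {
        warning(sum(bad), " ", p,
                " feature(s) with non-positive abundance dropped",
                call. = FALSE)
        feats <- feats[!bad]
      }
    } else {
      stop("per-family fold changes are defined for rna, lipid and protein",
           call. = FALSE)
    }
    if (length(feats) == 0) return(NULL)
    lfc <- sapply(seq_len(nrow(pairs)), function(i) {
      log2(values[feats, pairs$cald[i]] / values[feats, pairs$noncald[i]])
    })
    lfc <- matrix(lfc, nrow = length(feats),
                  dimnames = list(feats, pairs$family))
    dplyr::bind_cols(
      tibble::tibble(feature_id = feats, platform = p),
      tibble::as_tibble(lfc)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("family_lfc", class(out)))
}

#' PCA and clustering of families on fold-change profiles
#'
#' Feature-centered singular value decomposition of the family-by-feature
#' log2-fold-change matrix, keeping the leading `n_components` family
#' scores, followed by agglomerative clustering (Euclidean distance,
#' average linkage) of the score vectors into `n_clusters` groups.
#' Families with identical profiles always share a cluster. Explained
#' variance fractions are reported in non-increasing order.
#'
#' @param lfc A [build_family_lfc_matrix()] result (rows with missing
#'   values are dropped).
#' @param n_components Number of principal components to keep (reduced
#'   with a warning if larger than the matrix rank allows).
#' @param n_clusters Number of family clusters (default 2).
#' @return List of class `family_pca`: `scores` (tibble `family`, `PC1`,
#'   ...), `clusters` (tibble `family`, `cluster`), `explained_variance`
#'   (all components), `n_components`.
#' @export
pca_cluster <- function(lfc, n_components = 3, n_clusters = 2) {
  lfc <- tibble::as_tibble(lfc)
  fam_cols <- setdiff(names(lfc), c("feature_id", "platform"))
  stopifnot(length(fam_cols) >= 2)
  V <- as.matrix(lfc[fam_cols])
  V <- V[rowSums(!is.finite(V)) == 0, , drop = FALSE]
  stopifnot(nrow(V) >= 2)
  M <- t(V)                               # families x features
  M <- sweep(M, 2, colMeans(M))           # feature-centered
  k_max <- min(dim(M)) - 0L
  if (n_components > k_max) {
    warning("n_components reduced to ", k_max, call. = FALSE)
    n_components <- k_max
  }
  sv <- svd(M)
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  scores_k <- scores[, seq_len(n_components), drop = FALSE]
  colnames(scores_k) <- paste0("PC", seq_len(n_components))
  score_tbl <- dplyr::bind_cols(tibble::tibble(family = fam_cols),
                                tibble::as_tibble(scores_k))

  k_eff <- min(n_clusters, nrow(unique(round(scores_k, 12))))
  hc <- stats::hclust(stats::dist(scores_k), method = "average")
  cl <- stats::cutree(hc, k = k_eff)
  structure(list(
    scores = score_tbl,
    clusters = tibble::tibble(family = fam_cols, cluster = unname(cl)),
    explained_variance = ev,
    n_components = n_components
  ), class = "family_pca")
}

#' @export
print.family_pca <- function(x, ...) {
  cat(sprintf("# family_pca: %d components, explained variance %s\n",
              x$n_components,
              paste(sprintf("%.2f", utils::head(x$explained_variance, 3)),
                    collapse = ", ")))
  print(dplyr::left_join(x$scores, x$clusters, by = "family"))
  invisible(x)
}
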