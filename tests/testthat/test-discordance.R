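test_that("the category map covers all nine called genotype pairs", {
  gts <- c("0/0", "0/1", "1/1")
  grid <- expand.grid(cald = gts, noncald = gts,
                      stringsAsFactors = FALSE)
  got <- classify_pair_genotype(grid$cald, grid$noncald)
  expected <- mapply(oracle_classify, grid$cald, grid$noncald)
  expect_equal(got, unname(expected))
  # exactly four discordant patterns... plus the homozygote-vs-het pairs
  expect_setequal(unique(got), c(discordance_categories(), "none"))
  # the (1/1, 0/0) pair is recessive (carrier homozygous), not dominant
  expect_equal(classify_pair_genotype("1/1", "0/0"), "recessive_damaging")
  # missing genotypes are not classifiable
  expect_true(is.na(classify_pair_genotype("missing", "0/0")))
  expect_error(classify_pair_genotype("0/3", "0/0"), "unrecognized")
})

test_that("swapping brothers swaps damaging and protective", {
  gts <- c("0/0", "0/1", "1/1")
  swap <- c(dominant_damaging = "dominant_protective",
            dominant_protective = "dominant_damaging",
            recessive_damaging = "recessive_protective",
            recessive_protective = "recessive_damaging",
            none = "none")
  for (a in gts) for (b in gts) {
    expect_equal(unname(swap[classify_pair_genotype(a, b)]),
                 classify_pair_genotype(b, a))
  }
})

test_that("discordant sets match hand classification on a toy table", {
  co <- toy_cohort(2)
  gt <- rbind(
    v1 = c("0/1", "0/0", "0/0", "0/0"),  # dom_dam fam1 only
    v2 = c("1/1", "0/1", "0/0", "1/1"),  # rec_dam fam1, rec_prot fam2
    v3 = c("0/1", "0/1", "0/0", "0/1"),  # none fam1, dom_prot fam2
    v4 = c("missing", "0/0", "0/0", "0/0")  # skipped fam1, none fam2
  )
  colnames(gt) <- c("F1_C", "F1_N", "F2_C", "F2_N")
  sets <- build_discordant_sets(geno_from_matrix(gt), co)
  expect_equal(nrow(sets), 4)
  expect_setequal(
    paste(sets$family, sets$category, sets$variant_id),
    c("fam1 dominant_damaging v1",
      "fam1 recessive_damaging v2",
      "fam2 recessive_protective v2",
      "fam2 dominant_protective v3"))

  concordant <- matrix("0/1", 2, 4,
                       dimnames = list(c("w1", "w2"), colnames(gt)))
  expect_equal(nrow(build_discordant_sets(geno_from_matrix(concordant), co)),
               0)
})

test_that("exact partition matches the small worked example", {
  sets <- tibble::tibble(
    family = c("fam1", "fam1", "fam2"),
    category = "dominant_damaging",
    variant_id = c("a", "b", "b"))
  up <- intersect_discordant_sets(sets)
  p <- up$partition
  expect_equal(p$n[p$families == "fam1"], 1)
  expect_equal(p$n[p$families == "fam1&fam2"], 1)
  expect_equal(up$depth$n[up$depth$degree == 2], 1)
  # a variant discordant everywhere is counted at full depth only
  all6 <- tibble::tibble(family = paste0("fam", 1:6),
                         category = "x", variant_id = "v")
  d6 <- intersect_discordant_sets(all6)$depth
  expect_equal(d6$degree, 6L)
  expect_equal(d6$n, 1L)
})

test_that("exact partition equals brute-force subset enumeration", {
  fams <- paste0("fam", 1:4)
  for (s in 1:20) {
    set.seed(100 + s)
    sets <- dplyr::bind_rows(lapply(fams, function(f) {
      tibble::tibble(
        family = f,
        category = sample(c("dominant_damaging", "recessive_damaging"),
                          sample(0:20, 1), replace = TRUE),
        variant_id = as.character(sample(20, length(category),
                                         replace = FALSE)))
    }))
    if (nrow(sets) == 0) next
    sets <- dplyr::distinct(sets)
    got <- intersect_discordant_sets(sets)$partition
    want <- oracle_partition(sets, fams)
    merged <- dplyr::full_join(got[c("category", "families", "n")], want,
                               by = c("category", "families"))
    expect_true(all(!is.na(merged$n.x) & !is.na(merged$n.y)))
    expect_equal(merged$n.x, merged$n.y)
    # conservation: partition sizes sum to the union per category
    tot <- dplyr::count(dplyr::distinct(sets[c("category", "variant_id")]),
                        .data$category)
    got_tot <- dplyr::summarise(dplyr::group_by(got, .data$category),
                                n = sum(n), .groups = "drop")
    expect_equal(dplyr::arrange(got_tot, category)$n,
                 dplyr::arrange(tot, category)$n)
  }
})

test_that("adding a family can only keep or shrink the full-depth set", {
  set.seed(42)
  fams <- paste0("fam", 1:5)
  sets <- dplyr::bind_rows(lapply(fams, function(f) {
    tibble::tibble(family = f, category = "c",
                   variant_id = as.character(sample(12, 8)))
  }))
  for (k in 3:5) {
    sub_k <- sets[sets$family %in% fams[1:k], ]
    sub_k1 <- sets[sets$family %in% fams[1:(k - 1)], ]
    full_k <- full_depth_elements(intersect_discordant_sets(sub_k), k)
    full_k1 <- full_depth_elements(intersect_discordant_sets(sub_k1), k - 1)
    expect_true(all(full_k$variant_id %in% full_k1$variant_id))
  }
})

test_that("shared-carrier scan requires exclusivity and complete calls", {
  co <- toy_cohort(3)
  samples <- co$sample
  gt <- rbind(
    v1 = c("0/1", "0/0", "0/1", "0/0", "0/1", "0/0"),  # het all CALD only
    v2 = c("0/1", "0/0", "0/0", "0/0", "0/1", "0/0"),  # het 2 of 3 CALD
    v3 = c("0/1", "0/1", "0/1", "0/0", "0/1", "0/0"),  # het in a non-CALD
    v4 = c("0/1", "0/0", "0/1", "missing", "0/1", "0/0")  # missing call
  )
  colnames(gt) <- samples
  got <- shared_carrier_scan(geno_from_matrix(gt), co, "0/1", "CALD")
  expect_equal(got, "v1")
})

test_that("haploblock grouping matches a brute-force run scan", {
  co <- toy_cohort(1)
  gt <- matrix("0/1", 3, 2, dimnames = list(NULL, co$sample))
  g <- geno_from_matrix(gt, pos = c(1000L, 2000L, 3000L))
  blocks <- detect_haploblocks(unique(g$variant_id), g,
                               max_gap = 50000, min_size = 3)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_variants, 3)
  expect_equal(blocks$span, 2000)
  expect_false(is.na(blocks$pattern))  # members share one genotype vector

  g2 <- geno_from_matrix(gt, pos = c(1000L, 2000L, 62000L))
  expect_equal(nrow(detect_haploblocks(unique(g2$variant_id), g2,
                                       max_gap = 50000, min_size = 3)), 0)

  # random positions vs an independent run-length scan
  for (s in 1:10) {
    set.seed(200 + s)
    pos <- sort(sample.int(1e6, 30))
    gtm <- matrix(sample(c("0/0", "0/1"), 60, replace = TRUE), 30, 2,
                  dimnames = list(NULL, co$sample))
    gg <- geno_from_matrix(gtm, pos = pos)
    got <- detect_haploblocks(unique(gg$variant_id), gg,
                              max_gap = 30000, min_size = 3)
    runs <- split(pos, cumsum(c(1, diff(pos) > 30000)))
    want <- Filter(function(r) length(r) >= 3, runs)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$n_variants, unname(vapply(want, length, integer(1))))
      expect_equal(got$start, unname(vapply(want, min, numeric(1))))
    }
  }
})

test_that("heteroplasmy states follow the allele-fraction band", {
  expect_equal(classify_heteroplasmy(c(0.5, 0.99, 0.02)),
               c("heteroplasmic", "homoplasmic", "absent"))
  expect_equal(classify_heteroplasmy(c(0.05, 0.95)),
               c("heteroplasmic", "heteroplasmic"))
  expect_error(classify_heteroplasmy(1.2), "\\[0, 1\\]")
})

test_that("mitochondrial discordance compares heteroplasmy states", {
  co <- toy_cohort(2)
  af <- rbind(
    m1 = c(0.5, 1.0, 0.5, 0.6),   # discordant fam1 (het vs hom), concordant fam2
    m2 = c(0.5, 0.6, 0.02, 0.5),  # concordant fam1, discordant fam2
    m3 = c(0.5, 1.0, 0.0, 0.5)    # discordant in both
  )
  colnames(af) <- co$sample
  g <- geno_from_matrix(matrix("0/1", 3, 4,
                               dimnames = list(rownames(af), colnames(af))))
  g$af <- as.vector(t(af))
  g$class <- "mito"
  ann <- tibble::tibble(variant_id = c("m1", "m2", "m3"),
                        gene = c("MT-ND1", "MT-ND1", "MT-CYB"))
  md <- mito_discordance(g, co, ann)
  expect_setequal(
    paste(md$variant_sets$family, md$variant_sets$variant_id),
    c("fam1 m1", "fam2 m2", "fam1 m3", "fam2 m3"))
  # m3's gene is discordant in both families: full depth in gene partition
  fd <- full_depth_elements(md$gene_partition, 2)
  expect_true("MT-CYB" %in% fd$variant_id)
  # MT-ND1 is hit in both families too (via m1 and m2)
  expect_true("MT-ND1" %in% fd$variant_id)
})
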