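#' Simulate a discordant sibling-pair cohort
#'
#' Generates `n_families` brother pairs, one CALD and one non-CALD member
#' each, with within-family age differences of at most two years, plus
#' optional unrelated adult controls (used by the lipid platform).
#'
#' @param n_families Number of sibling pairs (>= 1).
#' @param n_controls Number of unrelated control samples.
#' @param age_range Integer vector `c(min, max)` of sibling ages in years.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated cohort tibble (see [cohort_design()]).
#' @export
#' @examples
#' simulate_cohort(6, 8, c(6, 38), seed = 1)
simulate_cohort <- function(n_families, n_controls = 0, age_range = c(6, 38),
                            seed = 1) {
  stopifnot(n_families >= 1, age_range[1] >= 0, age_range[2] >= age_range[1])
  set.seed(seed)
  rows <- vector("list", n_families)
  ages <- seq(age_range[1], age_range[2])
  for (i in seq_len(n_families)) {
    a1 <- ages[sample.int(length(ages), 1)]
    a2 <- min(max(a1 + sample(-2:2, 1), age_range[1]), age_range[2])
    fam <- paste0("fam", i)
    rows[[i]] <- tibble::tibble(
      sample = c(paste0("F", i, "_C"), paste0("F", i, "_N")),
      family = fam,
      phenotype = c("CALD", "non-CALD"),
      age = c(a1, a2)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (n_controls > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample = paste0("CTRL", seq_len(n_controls)),
      family = NA_character_,
      phenotype = "control",
      age = sample(18:60, n_controls, replace = TRUE)
    ))
  }
  cohort_design(out)
}

planted_pattern <- function(category) {
  switch(category,
    dominant_damaging    = c(cald = "0/1", noncald = "0/0"),
    dominant_protective  = c(cald = "0/0", noncald = "0/1"),
    recessive_damaging   = c(cald = "1/1", noncald = "0/0"),
    recessive_protective = c(cald = "0/0", noncald = "1/1"),
    stop("unknown discordance category: ", category, call. = FALSE)
  )
}

#' Simulate a jointly genotyped variant table with planted discordant alleles
#'
#' Background variants draw each sibling's genotype independently under
#' Hardy-Weinberg equilibrium at `background_af` (so incidental discordance
#' arises by chance); planted variants realize exactly their category's
#' genotype pattern in every target family and are concordant homozygous
#' reference elsewhere.
#'
#' @param cohort A cohort tibble.
#' @param n_variants Total variant count (planted included).
#' @param planted `NULL`, or a data frame with columns `category` (one of
#'   the four discordance categories) and `families` (list-column of family
#'   ids; `NULL` entries mean all families).
#' @param background_af Background alternate-allele frequency in (0, 1),
#'   or 0 for no background alternate alleles.
#' @param seed Integer seed.
#' @param chrom Chromosome label for the simulated records.
#' @return List with `genotypes` (long variant tibble, see [read_vcf()])
#'   and `planted` (manifest tibble `variant_id`, `category`, `families`).
#' @export
simulate_genotypes <- function(cohort, n_variants = 1000, planted = NULL,
                               background_af = 0.1, seed = 1, chrom = "chr1") {
  stopifnot(background_af >= 0, background_af < 1)
  set.seed(seed)
  pairs <- cohort_pairs(cohort)
  samples <- cohort_ald_samples(cohort)
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  if (n_planted > n_variants) {
    stop("more planted variants than n_variants", call. = FALSE)
  }

  pos <- 10000L * seq_len(n_variants)
  vid <- paste(chrom, pos, "A", "G", sep = ":")

  # genotype matrix: variants x samples
  gt <- matrix("0/0", n_variants, length(samples),
               dimnames = list(vid, samples))
  if (background_af > 0 && n_variants > n_planted) {
    p <- background_af
    bg <- seq.int(n_planted + 1L, n_variants)
    draws <- sample(c("0/0", "0/1", "1/1"), length(bg) * length(samples),
                    replace = TRUE,
                    prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    gt[bg, ] <- draws
  }

  manifest <- NULL
  if (n_planted > 0) {
    planted <- tibble::as_tibble(planted)
    fams <- lapply(seq_len(n_planted), function(j) {
      f <- planted$families[[j]]
      if (is.null(f) || all(is.na(f))) pairs$family else as.character(f)
    })
    for (j in seq_len(n_planted)) {
      pat <- planted_pattern(planted$category[j])
      target <- pairs[pairs$family %in% fams[[j]], ]
      gt[j, ] <- "0/0"
      gt[j, target$cald] <- pat[["cald"]]
      gt[j, target$noncald] <- pat[["noncald"]]
    }
    manifest <- tibble::tibble(
      variant_id = vid[seq_len(n_planted)],
      category = planted$category,
      families = fams
    )
  }

  geno <- tibble::tibble(
    variant_id = rep(vid, each = length(samples)),
    chrom = chrom,
    pos = rep(pos, each = length(samples)),
    ref = "A", alt = "G", class = "SNV",
    sample = rep(samples, n_variants),
    gt = as.vector(t(gt)),
    af = NA_real_
  )
  list(genotypes = geno, planted = manifest)
}

platform_baseline <- function(platform) {
  switch(platform,
    rna = log2(500),       # mean library-scale expression, log2 counts
    dnam = qlogis(0.3) / log(2),  # ~30% methylated, log2-odds (M) scale
    lipid = 10,            # log2 abundance
    protein = 10
  )
}

#' Simulate a platform feature matrix with planted phenotype effects
#'
#' Each feature's latent value follows the family-cofactor model
#' `mu + fam + rho * beta (+ age * slope) + eps` on a log2 scale (log2
#' abundance for lipid/protein, log2 count mean for rna, log2
#' methylated/unmethylated odds — the M-value scale — for dnam). Family
#' effects are drawn once per feature per family and shared by both
#' brothers; unrelated controls carry no family effect. Emission per
#' platform: lipid/protein as linear positive abundances (`2^latent`), rna
#' as negative-binomial counts with mean `2^latent` and the stated
#' dispersion, dnam as beta values in (0, 1).
#'
#' The first `n_signal` features carry the phenotype effect `beta`
#' (CALD minus non-CALD, log2 units). For dnam, `age_effect` (log2-odds
#' per year) applies to every feature, mimicking global methylation drift
#' with age. `control_shift` (log2 units) offsets all affected (ALD)
#' samples relative to controls at signal features, for the ALD-vs-control
#' lipid comparison.
#'
#' @param cohort A cohort tibble (controls included are simulated too).
#' @param platform One of `"lipid"`, `"rna"`, `"protein"`, `"dnam"`.
#' @param n_features Number of features.
#' @param n_signal Number of leading features carrying `beta`.
#' @param beta Phenotype effect size (scalar, or length `n_signal`).
#' @param sigma_fam Family-effect standard deviation (log2 units).
#' @param sigma_eps Residual standard deviation (log2 units).
#' @param age_effect Per-year age slope (dnam only, log2-odds per year).
#' @param rna_dispersion Negative-binomial dispersion (rna only);
#'   `size = 1/rna_dispersion`.
#' @param control_shift ALD-vs-control offset at signal features.
#' @param cluster `NULL`, or `list(size =, gap =)`: place signal CpGs in
#'   runs of `size` consecutive sites `gap` bp apart sharing one signal
#'   (dnam only, for exercising the DMR caller).
#' @param seed Integer seed.
#' @return List with `data` (an [feature_matrix()] with gene annotation,
#'   plus CpG coordinates for dnam) and `signal` (manifest tibble
#'   `feature_id`, `beta`).
#' @export
simulate_omics <- function(cohort, platform, n_features = 2000, n_signal = 0,
                           beta = 0, sigma_fam = 0.5, sigma_eps = 0.5,
                           age_effect = 0.02, rna_dispersion = 0.1,
                           control_shift = 0, cluster = NULL, seed = 1) {
  platform <- match.arg(platform, c("lipid", "rna", "protein", "dnam"))
  stopifnot(sigma_fam >= 0, sigma_eps >= 0, n_signal <= n_features)
  set.seed(seed)

  samples <- cohort$sample
  n <- length(samples)
  is_ald <- cohort$phenotype != "control"
  rho <- as.numeric(cohort$phenotype == "CALD")
  fam_ids <- unique(cohort$family[!is.na(cohort$family)])
  fam_index <- match(cohort$family, fam_ids)  # NA for controls

  prefix <- c(lipid = "lip", rna = "rna", protein = "prt", dnam = "cpg")[platform]
  fid <- sprintf("%s%05d", prefix, seq_len(n_features))

  beta_f <- numeric(n_features)
  if (n_signal > 0) beta_f[seq_len(n_signal)] <- rep_len(beta, n_signal)

  coords <- NULL
  if (platform == "dnam") {
    pos <- 10000L * seq_len(n_features)
    if (!is.null(cluster) && n_signal > 0) {
      size <- cluster$size
      gap <- if (is.null(cluster$gap)) 200L else cluster$gap
      n_clusters <- ceiling(n_signal / size)
      for (c_i in seq_len(n_clusters)) {
        members <- seq.int((c_i - 1L) * size + 1L, min(c_i * size, n_signal))
        base <- 10000L * n_features + 10000L * 50L * c_i
        pos[members] <- base + gap * (seq_along(members) - 1L)
        # cluster members share one signal level
        beta_f[members] <- beta_f[members[1]]
      }
    }
    coords <- tibble::tibble(feature_id = fid, chrom = "chr1", pos = pos)
  }

  mu <- stats::rnorm(n_features, platform_baseline(platform), 1)
  fam_eff <- matrix(stats::rnorm(n_features * length(fam_ids), 0, sigma_fam),
                    n_features, length(fam_ids))
  eps <- matrix(stats::rnorm(n_features * n, 0, sigma_eps), n_features, n)

  latent <- matrix(mu, n_features, n) + eps
  for (s in seq_len(n)) {
    if (!is.na(fam_index[s])) latent[, s] <- latent[, s] + fam_eff[, fam_index[s]]
    latent[, s] <- latent[, s] + rho[s] * beta_f
    if (is_ald[s] && control_shift != 0 && n_signal > 0) {
      latent[seq_len(n_signal), s] <- latent[seq_len(n_signal), s] + control_shift
    }
    if (platform == "dnam") {
      latent[, s] <- latent[, s] + cohort$age[s] * age_effect
    }
  }

  values <- switch(platform,
    lipid = ,
    protein = 2^latent,
    rna = {
      counts <- matrix(
        stats::rnbinom(n_features * n, mu = 2^latent, size = 1 / rna_dispersion),
        n_features, n)
      counts
    },
    dnam = {
      b <- plogis(latent * log(2))
      # keep strictly inside (0,1)
      pmin(pmax(b, 1e-6), 1 - 1e-6)
    }
  )
  colnames(values) <- samples

  annotation <- tibble::tibble(feature_id = fid,
                               gene = sprintf("GENE%05d", seq_len(n_features)))
  if (platform == "lipid") annotation <- NULL

  dat <- feature_matrix(
    tibble::as_tibble(cbind(tibble::tibble(feature_id = fid),
                            tibble::as_tibble(values))),
    platform, annotation = annotation, coords = coords
  )
  signal <- tibble::tibble(feature_id = fid[seq_len(n_signal)],
                           beta = beta_f[seq_len(n_signal)])
  list(data = dat, signal = signal)
}

mito_genes <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
                "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
                "MT-CYB")

#' Simulate mitochondrial variants with per-sample allele fractions
#'
#' Each variant-sample cell is heteroplasmic with probability
#' `heteroplasmy_fraction` (alt-allele fraction drawn uniformly inside the
#' heteroplasmic band), otherwise homoplasmic absent (0) or present (1)
#' with equal probability. Variants are annotated to mitochondrial genes.
#'
#' @param cohort A cohort tibble.
#' @param n_variants Number of mitochondrial variants.
#' @param heteroplasmy_fraction Probability a cell is heteroplasmic, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param band Heteroplasmic allele-fraction band, default `c(0.05, 0.95)`.
#' @return List with `genotypes` (long variant tibble, class `mito`, `af`
#'   filled) and `annotation` (tibble `variant_id`, `gene`).
#' @export
simulate_mito <- function(cohort, n_variants = 300, heteroplasmy_fraction = 0.5,
                          seed = 1, band = c(0.05, 0.95)) {
  stopifnot(heteroplasmy_fraction >= 0, heteroplasmy_fraction <= 1)
  set.seed(seed)
  samples <- cohort_ald_samples(cohort)
  pos <- sort(sample.int(16569L, n_variants))
  vid <- paste("chrM", pos, "A", "G", sep = ":")

  n_cells <- n_variants * length(samples)
  het <- stats::runif(n_cells) < heteroplasmy_fraction
  af <- ifelse(het,
               stats::runif(n_cells, band[1], band[2]),
               as.numeric(stats::runif(n_cells) < 0.5))
  state_gt <- ifelse(af < band[1], "0/0", ifelse(af > band[2], "1/1", "0/1"))

  geno <- tibble::tibble(
    variant_id = rep(vid, each = length(samples)),
    chrom = "chrM",
    pos = rep(pos, each = length(samples)),
    ref = "A", alt = "G", class = "mito",
    sample = rep(samples, n_variants),
    gt = state_gt,
    af = af
  )
  annotation <- tibble::tibble(
    variant_id = vid,
    gene = mito_genes[1L + (pos %/% 1300L) %% length(mito_genes)]
  )
  list(genotypes = geno, annotation = annotation)
}
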