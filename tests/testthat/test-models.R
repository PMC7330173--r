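test_that("noise-free pairs give the exact closed-form estimate", {
  co <- cohort_design(tibble::tibble(
    sample = c("a1", "a2", "b1", "b2", "c1", "c2"),
    family = rep(c("f1", "f2", "f3"), each = 2),
    phenotype = rep(c("non-CALD", "CALD"), 3),
    age = rep(10, 6)))
  y <- c(a1 = 10, a2 = 12, b1 = 20, b2 = 22, c1 = 30, c2 = 32)
  fit <- fit_feature_model(y, co)
  expect_equal(fit$estimate, 2.0, tolerance = 1e-12)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p_value))
})

test_that("the fit equals an explicit normal-equation and t-CDF oracle", {
  co <- simulate_cohort(6, 0, c(6, 38), seed = 30)
  ald <- co[co$phenotype != "control", ]
  set.seed(31)
  y <- stats::setNames(rnorm(12, 10, 2), ald$sample)
  fit <- fit_feature_model(y, co)

  X <- cbind(model.matrix(~ factor(ald$family)),
             rho = as.numeric(ald$phenotype == "CALD"))
  beta_hat <- solve(crossprod(X), crossprod(X, y[ald$sample]))
  res <- y[ald$sample] - X %*% beta_hat
  df <- 12 - ncol(X)
  expect_equal(df, 5)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(crossprod(X))["rho", "rho"])
  expect_equal(fit$estimate, unname(beta_hat["rho", 1]), tolerance = 1e-12)
  expect_equal(fit$std_error, unname(se), tolerance = 1e-12)
  expect_equal(fit$p_value,
               unname(2 * pt(-abs(beta_hat["rho", 1] / se), df)),
               tolerance = 1e-12)
  expect_equal(fit$df, 5)

  # lm agrees too
  lmfit <- lm(y[ald$sample] ~ factor(ald$family) + ald$phenotype)
  expect_equal(abs(fit$statistic),
               abs(summary(lmfit)$coefficients[7, "t value"]),
               tolerance = 1e-10)
})

test_that("sample order does not change the fit", {
  co <- simulate_cohort(4, 0, c(6, 38), seed = 32)
  ald <- co[co$phenotype != "control", ]
  set.seed(33)
  y <- stats::setNames(rnorm(8), ald$sample)
  f1 <- fit_feature_model(y, co)
  perm <- sample(names(y))
  f2 <- fit_feature_model(y[perm], co)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
})

test_that("the family-cofactor fit reduces to the paired t-test", {
  for (s in 1:50) {
    set.seed(400 + s)
    n_fam <- sample(3:8, 1)
    co <- simulate_cohort(n_fam, 0, c(6, 38), seed = 500 + s)
    ald <- co[co$phenotype != "control", ]
    y <- stats::setNames(rnorm(2 * n_fam, 5, 3), ald$sample)
    fit <- fit_feature_model(y, co)
    pairs <- cohort_pairs(co)
    diffs <- y[pairs$cald] - y[pairs$noncald]
    tt <- t.test(diffs)
    expect_equal(fit$estimate, mean(diffs), tolerance = 1e-10)
    expect_equal(fit$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("age enters the methylation model and drops when collinear", {
  co <- simulate_cohort(6, 0, c(6, 38), seed = 34)
  ald <- co[co$phenotype != "control", ]
  set.seed(35)
  y <- stats::setNames(rnorm(12) + 0.1 * ald$age, ald$sample)
  fit <- fit_feature_model(y, co, include_age = TRUE)
  expect_equal(fit$df, 12 - 6 - 2)
  expect_false(is.na(fit$age_estimate))

  same_age <- ald
  same_age$age <- rep(c(10, 10, 20, 20, 30, 30, 12, 12, 14, 14, 16, 16))
  co2 <- cohort_design(same_age)
  expect_warning(fit2 <- fit_feature_model(y, co2, include_age = TRUE),
                 "collinear")
  expect_equal(fit2$df, 12 - 6 - 1)
})

test_that("multiple-testing adjustment matches the textbook formulas", {
  expect_equal(adjust_pvalues(rep(0.001, 17), "bonferroni")[1], 0.017)
  expect_equal(adjust_pvalues(c(0.9, 0.4), "bonferroni"), c(1, 0.8))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_identical(adjust_pvalues(numeric(0), "bh"), numeric(0))
  # step-up oracle on random vectors
  for (s in 1:10) {
    set.seed(600 + s)
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    stepup <- numeric(m)
    running <- 1
    for (i in m:1) {
      running <- min(running, m / i * p[o[i]])
      stepup[o[i]] <- running
    }
    expect_equal(adjust_pvalues(p, "bh"), stepup, tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "bonferroni"), pmin(1, m * p),
                 tolerance = 1e-12)
    expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
  }
})

test_that("platform scans rank planted signal above null features", {
  co <- simulate_cohort(6, 0, c(6, 38), seed = 36)
  om <- simulate_omics(co, "rna", n_features = 200, n_signal = 10, beta = 2,
                       seed = 37)
  sc <- run_platform_scan(om$data, co)
  signal <- tibble::as_tibble(sc)[sc$feature_id %in% om$signal$feature_id, ]
  null <- tibble::as_tibble(sc)[!sc$feature_id %in% om$signal$feature_id, ]
  expect_gt(mean(abs(signal$statistic)), mean(abs(null$statistic)))
  expect_equal(sc$p_adjusted, pmin(1, nrow(sc) * sc$p_value),
               tolerance = 1e-12)
})

test_that("unusable features are dropped from scans", {
  co <- toy_cohort(3)
  counts <- tibble::tibble(
    feature_id = c("z", "ok"),
    !!!stats::setNames(as.list(rep(0L, 6)), co$sample))
  counts[2, -1] <- as.list(c(5L, 9L, 3L, 7L, 2L, 8L))
  m <- feature_matrix(counts, "rna")
  expect_message(sc <- run_platform_scan(m, co), "dropped")
  expect_equal(sc$feature_id, "ok")
})

test_that("CpG filtering applies both thresholds", {
  fits <- tibble::tibble(
    feature_id = c("c1", "c2", "c3"),
    p_value = c(1e-4, 1e-4, 1e-3),
    delta_beta = c(0.08, 0.02, 0.08))
  kept <- filter_cpgs(fits)
  expect_equal(kept$feature_id, "c1")
})

test_that("DMR calls follow the run, direction and Stouffer rules", {
  coords <- tibble::tibble(feature_id = paste0("c", 1:3), chrom = "chr1",
                           pos = c(1000L, 1200L, 1400L))
  fits <- tibble::tibble(feature_id = paste0("c", 1:3),
                         p_value = 1e-4, delta_beta = 0.12)
  dmr <- call_dmrs(fits, coords)
  expect_equal(nrow(dmr), 1)
  expect_equal(dmr$n_cpgs, 3)
  z <- qnorm(1e-4 / 2, lower.tail = FALSE)
  expect_equal(dmr$combined_z, sqrt(3) * z, tolerance = 1e-12)
  expect_equal(dmr$direction, "up")
  expect_equal(dmr$delta_beta, 0.12)

  # sign change splits the run
  mixed <- fits
  mixed$delta_beta <- c(0.12, -0.12, 0.12)
  expect_equal(nrow(call_dmrs(mixed, coords)), 0)

  # below the member-count floor
  expect_equal(nrow(call_dmrs(fits[1:2, ], coords[1:2, ])), 0)

  # gap above the ceiling splits
  far <- coords
  far$pos[3] <- 5000L
  expect_equal(nrow(call_dmrs(fits, far)), 0)
})

test_that("every emitted DMR re-satisfies its structural thresholds", {
  set.seed(700)
  n <- 400
  coords <- tibble::tibble(
    feature_id = paste0("c", 1:n), chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample.int(2e6, n))
  fits <- tibble::tibble(
    feature_id = coords$feature_id,
    p_value = 10^runif(n, -8, 0),
    delta_beta = runif(n, -0.3, 0.3))
  dmr <- call_dmrs(fits, coords, max_gap = 5000, min_cpgs = 3)
  for (i in seq_len(nrow(dmr))) {
    members <- dplyr::inner_join(
      fits[fits$feature_id %in% dmr$cpg_ids[[i]], ], coords,
      by = "feature_id")
    members <- members[order(members$pos), ]
    expect_gte(nrow(members), 3)
    expect_true(all(diff(members$pos) <= 5000))
    expect_true(all(members$p_value < 5e-4))
    expect_equal(length(unique(sign(members$delta_beta))), 1)
    expect_lt(dmr$fdr[i], 0.05)
    expect_gt(abs(dmr$delta_beta[i]), 0.10)
    expect_equal(dmr$delta_beta[i], mean(members$delta_beta))
  }
})

test_that("the control comparison is the pooled two-sample test", {
  co <- simulate_cohort(6, 8, c(6, 38), seed = 40)
  set.seed(41)
  vals <- matrix(2^rnorm(3 * 20, 10, 1), 3, 20,
                 dimnames = list(NULL, co$sample))
  m <- feature_matrix(
    tibble::as_tibble(cbind(tibble::tibble(feature_id = paste0("l", 1:3)),
                            tibble::as_tibble(vals))), "lipid")
  sc <- ald_vs_control_scan(m, co)
  is_ald <- co$phenotype != "control"
  for (i in 1:3) {
    y <- log2(vals[i, ])
    tt <- t.test(y[is_ald[match(colnames(vals), co$sample)]],
                 y[!is_ald[match(colnames(vals), co$sample)]],
                 var.equal = TRUE)
    row <- sc[sc$feature_id == paste0("l", i), ]
    expect_equal(abs(row$statistic), unname(abs(tt$statistic)),
                 tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$df, 18)
  }
  expect_error(ald_vs_control_scan(m, simulate_cohort(6, 0, c(6, 38), 1)),
               "controls")
})

test_that("a planted abundance shift is recovered against controls", {
  co <- simulate_cohort(6, 8, c(6, 38), seed = 42)
  om <- simulate_omics(co, "lipid", n_features = 50, n_signal = 5, beta = 0,
                       control_shift = 2, sigma_fam = 0.2, sigma_eps = 0.2,
                       seed = 43)
  sc <- ald_vs_control_scan(om$data, co)
  planted <- tibble::as_tibble(sc)[sc$feature_id %in% om$signal$feature_id, ]
  expect_true(all(planted$p_value < 0.05))
  expect_equal(mean(planted$log2fc), 2, tolerance = 0.4)
})

test_that("feature_fit tidiers are broom-shaped", {
  co <- simulate_cohort(6, 0, c(6, 38), seed = 44)
  ald <- co[co$phenotype != "control", ]
  set.seed(45)
  y <- stats::setNames(rnorm(12), ald$sample)
  fit <- fit_feature_model(y, co, include_age = TRUE)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("phenotype", "age"))
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, 12)
  expect_equal(gl$df.residual, 4)
})
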