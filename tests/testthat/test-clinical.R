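test_that("hallmark membership is a pure lookup", {
  sets <- list(angiogenesis = c("FGFR1", "FLT1"),
               resisting_death = c("FGFR1", "FADD"))
  hm <- map_to_hallmarks(c("FGFR1", "ZZZ9"), sets)
  expect_setequal(hm$FGFR1, c("angiogenesis", "resisting_death"))
  expect_length(hm$ZZZ9, 0L)
})

test_that("hallmark counts over random sets match a flat recount", {
  set.seed(51)
  genes <- sprintf("G%03d", 1:100)
  sets <- lapply(1:10, function(i) sample(genes, 20))
  names(sets) <- sprintf("H%02d", 1:10)
  hm <- map_to_hallmarks(genes, sets)
  flat <- table(unlist(sets))
  for (g in genes) {
    expect_equal(length(hm[[g]]),
                 if (g %in% names(flat)) unname(as.integer(flat[g])) else 0L)
  }
})

test_that("GMT parsing yields upper-cased, non-empty sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tfgfr1\tFLT1", "setB\tdesc\tFADD"), path)
  sets <- read_gmt(path)
  expect_equal(sets$setA, c("FGFR1", "FLT1"))
  expect_equal(sets$setB, "FADD")
})

test_that("coverage-to-CPM follows the library-size formula", {
  expect_equal(coverage_to_cpm(50, 1e7), 5)
  expect_equal(coverage_to_cpm(0, 1e7), 0)
  expect_error(coverage_to_cpm(1, 0), "library_size")
  set.seed(52)
  m <- matrix(runif(12, 0, 100), nrow = 3,
              dimnames = list(letters[1:3], LETTERS[1:4]))
  lib <- c(1e7, 2e7, 5e6, 8e6)
  got <- coverage_to_cpm(m, lib)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(got[i, j], m[i, j] / lib[j] * 1e6)
  }
})

test_that("mean stratification sends ties to LOW and errors on constants", {
  expect_equal(stratify_by_mean(c(1, 2, 3, 6)),
               c("LOW", "LOW", "LOW", "HIGH"))
  expect_equal(stratify_by_mean(c(0, 10)), c("LOW", "HIGH"))
  expect_error(stratify_by_mean(c(5, 5, 5)), "constant")
  expect_error(stratify_by_mean(3), "2 samples")
  set.seed(53)
  for (rep in 1:20) {
    x <- rnorm(sample(5:50, 1))
    g <- stratify_by_mean(x)
    expect_length(g, length(x))
    expect_gt(mean(x[g == "HIGH"]), mean(x[g == "LOW"]))
  }
})

test_that("KM equals the empirical survival function with no censoring", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_equal(km2$surv_fn(0), 1)
  expect_equal(km2$surv_fn(2.5), 2 / 3)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("KM is a valid non-increasing survival curve", {
  set.seed(54)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    t <- rexp(n, 0.01)
    e <- rbinom(n, 1, 0.7)
    if (sum(e) == 0) next
    km <- km_estimate(t, e)
    expect_true(all(diff(c(1, km$surv)) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("KM matches the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(55)
  for (rep in 1:10) {
    n <- 60
    t <- round(rexp(n, 0.01), 1)
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) next
    km <- km_estimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    at_events <- summary(sf, times = km$time)
    expect_equal(km$surv, at_events$surv, tolerance = 1e-10)
    expect_equal(km$n_risk, at_events$n.risk, tolerance = 1e-10)
  }
})

test_that("log-rank is symmetric, null on identical groups, matches survdiff", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- rep(1, 8)
  g <- rep(c("HIGH", "LOW"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  # separation gives a positive statistic
  lr2 <- logrank_test(c(1, 1, 1, 9, 9, 9), c(1, 1, 1, 0, 0, 0),
                      rep(c("HIGH", "LOW"), each = 3))
  expect_gt(lr2$chi2, 0)
  # label symmetry
  set.seed(56)
  t <- rexp(40, 0.01); e <- rbinom(40, 1, 0.8)
  g <- sample(rep(c("HIGH", "LOW"), 20))
  a <- logrank_test(t, e, g)
  b <- logrank_test(t, e, ifelse(g == "HIGH", "LOW", "HIGH"))
  expect_equal(a$chi2, b$chi2)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(a$chi2, sd$chisq, tolerance = 1e-10)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("HIGH", "LOW")), "no events")
})

test_that("the survival screen flags a planted effect and spares the null", {
  spec <- fixture_spec(seed = 7, n_samples = 200, hazard_ratio = 3,
                       censoring_rate = 0.2)
  coh <- generate_clinical_cohort(spec)
  scr <- survival_screen(coh$cpm, coh$parent_cpm, coh$clinical,
                         coh$peptide_gene, subtype = "all")
  eff <- scr[scr$peptide == coh$truth$effect_peptide, ]
  expect_true(eff$significant)
  expect_equal(eff$direction, "HIGH_EXPR_POOR")
  expect_lte(eff$p_novel, 0.05)
})

test_that("a survival-associated parent gene disqualifies its peptide", {
  spec <- fixture_spec(seed = 8, n_samples = 200, hazard_ratio = 3,
                       censoring_rate = 0.2, parent_effect = TRUE)
  coh <- generate_clinical_cohort(spec)
  scr <- survival_screen(coh$cpm, coh$parent_cpm, coh$clinical,
                         coh$peptide_gene, subtype = "all")
  eff <- scr[scr$peptide == coh$truth$effect_peptide, ]
  expect_lte(eff$p_novel, 0.05)          # the peptide itself separates
  expect_lte(eff$p_parent_gene, 0.1)     # but so does its parent gene
  expect_false(eff$significant)
})

test_that("small subtypes are skipped with a warning", {
  spec <- fixture_spec(seed = 9, n_samples = 24)
  coh <- generate_clinical_cohort(spec)
  expect_warning(
    out <- survival_screen(coh$cpm, coh$parent_cpm, coh$clinical,
                           coh$peptide_gene, subtype = "basal",
                           min_samples = 10L),
    "skipped")
  expect_equal(nrow(out), 0L)
})
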