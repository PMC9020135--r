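test_that("reference index answers substring membership with I/L folding", {
  ref <- list(protein_entry("p", "REFERENCE", "XXPEPTLDEKYY"))
  idx <- build_reference_index(ref, il_equivalent = TRUE)
  expect_true(is_known(idx, "PEPTLDEK"))
  expect_true(is_known(idx, "PEPTIDEK"))   # I folds onto reference L
  idx_exact <- build_reference_index(ref, il_equivalent = FALSE)
  expect_true(is_known(idx_exact, "PEPTLDEK"))
  expect_false(is_known(idx_exact, "PEPTIDEK"))
  expect_error(build_reference_index(list()), "empty")
})

test_that("index never matches across protein boundaries", {
  idx <- build_reference_index(c("AAAA", "CCCC"), il_equivalent = FALSE)
  expect_false(is_known(idx, "AACC"))
})

test_that("filter_novel collapses PSMs and partitions known/novel", {
  idx <- build_reference_index(c("MAAAPEPTLDEKGGG"))
  psms <- data.frame(
    peptide = c(rep("PEPTIDEK", 3), "QQQQWWWK", "QQQQWWWK", "LOWCONF"),
    experiment_id = c("e1", "e1", "e2", "e1", "e2", "e1"),
    spectrum_id = paste0("s", 1:6),
    confidence = c(1, 0.995, 0.999, 1, 1, 0.5),
    stringsAsFactors = FALSE)
  out <- filter_novel(psms, idx, fdr_threshold = 0.01)
  expect_equal(nrow(out), 2L)
  known <- out[out$peptide == "PEPTIDEK", ]
  expect_equal(known$status, "KNOWN")   # I/L-folded substring of reference
  expect_equal(known$psm_count, 3L)
  expect_equal(known$n_experiments, 2L)
  expect_equal(out$status[out$peptide == "QQQQWWWK"], "NOVEL")
  expect_error(filter_novel(psms, idx, 0), "fdr_threshold")
})

test_that("fixture PSM tables recover the planted known/novel partition", {
  u <- shared_fixture()
  tabs <- generate_psm_tables(u$spec, u$db, u$fix$ground_truth$peptide)
  idx <- build_reference_index(u$ref)
  ids <- filter_novel(read_psm_table_roundtrip(tabs$psms), idx, 0.01)
  expect_setequal(ids$peptide[ids$status == "NOVEL"], tabs$truth$novel)
  expect_setequal(ids$peptide[ids$status == "KNOWN"], tabs$truth$known)
})

test_that("PepQuery filtering applies the p-value and modification rules", {
  novel <- data.frame(peptide = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK",
                                  "EEEEEEEK"),
                      psm_count = 1L, n_experiments = 1L, experiments = "e1",
                      status = "NOVEL", stringsAsFactors = FALSE)
  pq <- data.frame(
    peptide = c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"),
    spectrum = paste0("s", 1:3),
    hyperscore = c(30, 30, 30),
    p_value = c(0.005, 0.02, 0.005),
    n_ptm = c(0L, 0L, 1L), stringsAsFactors = FALSE)
  expect_message(out <- apply_pepquery_filter(novel, pq), "no PepQuery")
  expect_equal(out$peptide, "AAAAAAAK")  # 0.02 fails p, n_ptm 1 fails mods
  expect_error(apply_pepquery_filter(novel, pq, p_max = 0), "p_max")
})

test_that("PepQuery filtering is monotone in the p-value threshold", {
  set.seed(31)
  novel <- data.frame(peptide = sprintf("PEP%02dAAK", 1:30),
                      psm_count = 1L, n_experiments = 1L, experiments = "e1",
                      status = "NOVEL", stringsAsFactors = FALSE)
  pq <- data.frame(peptide = novel$peptide, spectrum = "s",
                   hyperscore = 30, p_value = runif(30), n_ptm = 0L,
                   stringsAsFactors = FALSE)
  kept <- lapply(c(0.01, 0.05, 0.2, 1), function(p)
    apply_pepquery_filter(novel, pq, p_max = p)$peptide)
  for (i in 1:3) expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  expect_true(all(unlist(kept) %in% novel$peptide))
})

test_that("aggregation sums PSM counts and unions experiments", {
  a <- data.frame(peptide = "AAAK", psm_count = 2L, n_experiments = 1L,
                  experiments = "e1", status = "NOVEL",
                  stringsAsFactors = FALSE)
  b <- data.frame(peptide = c("AAAK", "CCCK"), psm_count = c(3L, 1L),
                  n_experiments = 1L, experiments = "e2", status = "NOVEL",
                  stringsAsFactors = FALSE)
  m <- aggregate_psm_counts(list(a, b))
  expect_equal(m$psm_count[m$peptide == "AAAK"], 5L)
  expect_equal(m$experiments[m$peptide == "AAAK"], "e1,e2")
  expect_equal(m$n_experiments[m$peptide == "AAAK"], 2L)
  expect_equal(nrow(m), 2L)
})

test_that("aggregation over many experiments equals a flat recount", {
  set.seed(32)
  idx <- build_reference_index("MMMM")
  per_exp <- list()
  all_psms <- list()
  for (e in 1:36) {
    peps <- sprintf("PEPTIDE%02dK", sample(1:20, sample(3:8, 1)))
    psms <- do.call(rbind, lapply(peps, function(p) data.frame(
      peptide = p, experiment_id = sprintf("e%02d", e),
      spectrum_id = paste0("s", seq_len(sample(1:3, 1))),
      confidence = 1, stringsAsFactors = FALSE)))
    all_psms[[e]] <- psms
    per_exp[[e]] <- filter_novel(psms, idx, 0.01)
  }
  merged <- aggregate_psm_counts(per_exp)
  flat <- table(do.call(rbind, all_psms)$peptide)
  expect_equal(sum(merged$psm_count), sum(flat))
  expect_equal(merged$psm_count[match(names(flat), merged$peptide)],
               unname(as.integer(flat)))
})

test_that("malformed PSM rows are rejected at row level", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\texperiment_id\tspectrum_id\tconfidence",
               "AAAK\te1\ts1\t0.999",
               "\te1\ts2\t0.999",
               "CCCK\te1\ts3\t1.7",
               "ccxk\te1\ts4\t0.999"), path)
  expect_message(d <- read_psm_table(path), "malformed")
  expect_equal(d$peptide, "AAAK")
})
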