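test_that("fixture specs validate their parameters", {
  expect_error(fixture_spec(n_samples = 10), "n_samples")
  expect_error(fixture_spec(censoring_rate = 1), "censoring_rate")
  s <- fixture_spec(events_per_category = c(UTR5 = 3L))
  expect_equal(unname(s$events["UTR5"]), 3L)
  expect_equal(unname(s$events["LNCRNA"]), 0L)
})

test_that("generated coding genes have clean reading frames", {
  u <- shared_fixture()
  ann <- u$ann
  for (tid in unique(ann$cds$tx_id)) {
    cc <- ann$cds[ann$cds$tx_id == tid, ]
    chrom <- ann$transcripts$chrom[match(tid, ann$transcripts$tx_id)]
    cds_seq <- paste(vapply(seq_len(nrow(cc)), function(k)
      substr(u$fix$genome[[chrom]], cc$start[k] + 1, cc$end[k]),
      character(1)), collapse = "")
    expect_equal(nchar(cds_seq) %% 3, 0)
    aa <- translate_six_frames(cds_seq)[[1]]
    # single terminal stop, none internal
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("event transcripts realise their engineered structures", {
  u <- shared_fixture()
  gt <- u$fix$ground_truth
  ann <- u$ann
  # a skipped-exon transcript omits the middle exon's sequence
  skip_row <- gt[gt$category == "EXON_SKIPPING", ][1, ]
  tx <- u$txs[[skip_row$tx_id]]
  g_exons <- ann$exons[ann$exons$tx_id ==
    ann$transcripts$tx_id[ann$transcripts$gene_id == skip_row$gene_id], ]
  e2 <- g_exons[2, ]
  e2_seq <- substr(u$fix$genome[[skip_row$chrom]], e2$start + 1, e2$end)
  expect_false(grepl(e2_seq, tx$sequence, fixed = TRUE))
  expect_equal(nrow(tx$alignment$blocks), 2L)
  # a retained-intron transcript carries the full intron between its exons
  ri_row <- gt[gt$category == "EXON_EXTENSION_INTRONIC", ][1, ]
  tx_ri <- u$txs[[ri_row$tx_id]]
  txs_of_gene <- ann$transcripts$tx_id[
    ann$transcripts$gene_id == ri_row$gene_id]
  intr <- ann$introns[ann$introns$tx_id %in% txs_of_gene, ][1, ]
  intron_seq <- substr(u$fix$genome[[ri_row$chrom]], intr$start + 1,
                       intr$end)
  expect_true(grepl(intron_seq, tx_ri$sequence, fixed = TRUE))
})

test_that("planted peptides are tryptic, novel and in the longest ORF", {
  u <- shared_fixture()
  gt <- u$fix$ground_truth
  idx <- build_reference_index(u$ref)
  expect_false(any(is_known(idx, gt$peptide)))
  for (i in seq_len(nrow(gt))) {
    tx <- u$txs[[gt$tx_id[i]]]
    orf <- extract_longest_orf(translate_six_frames(tx$sequence), tx$id)
    expect_true(gt$peptide[i] %in% digest_tryptic(orf$aa_sequence))
  }
})

test_that("identical seeds produce byte-identical fixture sets", {
  spec <- fixture_spec(seed = 17, n_samples = 24, n_null_peptides = 3L)
  d1 <- file.path(tempdir(), "fixset1")
  d2 <- file.path(tempdir(), "fixset2")
  simulate_fixtures(spec, d1)
  simulate_fixtures(spec, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # a different seed changes the genome
  d3 <- file.path(tempdir(), "fixset3")
  simulate_fixtures(fixture_spec(seed = 18, n_samples = 24,
                                 n_null_peptides = 3L), d3)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d3, "genome.fa"))))
})

test_that("PepQuery pass fractions are planted exactly", {
  u <- shared_fixture()
  spec <- fixture_spec(seed = u$spec$seed, fraction_pass = 0.5)
  tabs <- generate_psm_tables(spec, u$db, u$fix$ground_truth$peptide)
  n_novel <- nrow(u$fix$ground_truth)
  novel <- data.frame(peptide = u$fix$ground_truth$peptide,
                      psm_count = 1L, n_experiments = 1L,
                      experiments = "e1", status = "NOVEL",
                      stringsAsFactors = FALSE)
  kept <- apply_pepquery_filter(novel, tabs$pepquery)
  expect_equal(nrow(kept), round(0.5 * n_novel))
  expect_setequal(kept$peptide, tabs$truth$pepquery_pass)
})

test_that("zero censoring yields purely empirical survival groups", {
  spec <- fixture_spec(seed = 19, n_samples = 40, censoring_rate = 0)
  coh <- generate_clinical_cohort(spec)
  expect_true(all(coh$clinical$event == 1L))
  grp <- ifelse(coh$clinical$sample_id %in% coh$truth$high_group,
                "HIGH", "LOW")
  for (g in c("HIGH", "LOW")) {
    t <- coh$clinical$time_days[grp == g]
    km <- km_estimate(t, rep(1L, length(t)))
    emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
    expect_equal(km$surv, emp)
  }
})
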