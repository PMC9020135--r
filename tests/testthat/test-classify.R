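mini_ann <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t600\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chr1\tsrc\tmRNA\t101\t600\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t501\t600\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tCDS\t301\t400\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tCDS\t501\t600\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tgene\t2001\t2200\t.\t+\t.\tID=g2;gene_biotype=pseudogene",
    "chr1\tsrc\ttranscript\t2001\t2200\t.\t+\t.\tID=t2;Parent=g2",
    "chr1\tsrc\texon\t2001\t2200\t.\t+\t.\tParent=t2",
    "chr1\tsrc\tgene\t3001\t3200\t.\t+\t.\tID=g3;gene_biotype=lncRNA",
    "chr1\tsrc\ttranscript\t3001\t3200\t.\t+\t.\tID=t3;Parent=g3",
    "chr1\tsrc\texon\t3001\t3200\t.\t+\t.\tParent=t3"), path)
  load_annotation(path)
}

mk_align <- function(blocks, peptide = "SAMPLEPK", strand = "+") {
  structure(list(peptide = peptide, chrom = "chr1", strand = strand,
                 blocks = blocks, source_transcript_id = "novel",
                 orf_frame = 1L),
            class = "peptide_alignment")
}

test_that("a junction joining non-consecutive exons is exon skipping", {
  ann <- mini_ann()
  # exon1 ends at 200, exon3 starts at 500: skips exon2
  al <- mk_align(rbind(c(188L, 200L), c(500L, 512L)))
  out <- classify_peptide(al, ann)
  expect_equal(out$category, "EXON_SKIPPING")
  expect_equal(out$top_level, "PROTEIN_CODING_GENE")
  expect_equal(out$gene_id, "g1")
})

test_that("an unannotated junction with exonic flanks is junctional variation", {
  ann <- mini_ann()
  al <- mk_align(rbind(c(176L, 188L), c(300L, 312L)))  # donor shifted by 12
  expect_equal(classify_peptide(al, ann)$category, "JUNCTIONAL_VARIATION")
})

test_that("a block crossing an exon boundary is an exon-extension overlap", {
  ann <- mini_ann()
  al <- mk_align(rbind(c(190L, 211L)))
  expect_equal(classify_peptide(al, ann)$category, "EXON_EXTENSION_OVERLAP")
})

test_that("intronic peptides demote to nORF without a linked in-frame source", {
  ann <- mini_ann()
  al <- mk_align(rbind(c(230L, 260L)))   # wholly inside intron 1
  out <- classify_peptide(al, ann)       # no source transcript supplied
  expect_equal(out$category, "NORF_INTRONIC")
  expect_equal(out$top_level, "NORF")
  expect_equal(out$gene_id, "g1")
})

test_that("noncoding-gene biotypes map directly to their categories", {
  ann <- mini_ann()
  expect_equal(classify_peptide(mk_align(rbind(c(2050L, 2080L))), ann)$category,
               "PSEUDOGENE")
  expect_equal(classify_peptide(mk_align(rbind(c(3050L, 3080L))), ann)$category,
               "LNCRNA")
})

test_that("peptides far from any gene are intergenic novel ORFs", {
  ann <- mini_ann()
  out <- classify_peptide(mk_align(rbind(c(9000L, 9030L))), ann)
  expect_equal(out$category, "NORF_INTERGENIC")
  expect_true(is.na(out$gene_id))
})

test_that("every planted fixture event is recovered with its true category", {
  u <- shared_fixture()
  cl <- classify_fixture(u)
  gt <- u$fix$ground_truth
  expect_equal(nrow(cl), nrow(gt))
  m <- match(cl$peptide, gt$peptide)
  expect_false(anyNA(m))
  expect_equal(cl$category, gt$category[m])
  expect_equal(cl$top_level, gt$top_level[m])
  expect_equal(cl$blocks, gt$blocks[m])
  same_gene <- !is.na(gt$gene_id[m])
  expect_equal(cl$gene_id[same_gene], gt$gene_id[m][same_gene])
})

test_that("classification is a total function partitioning the input", {
  u <- shared_fixture()
  cl <- classify_fixture(u)
  expect_true(all(cl$category %in% peptide_categories()))
  tab <- summarize_by_chromosome(cl)
  expect_equal(sum(tab), nrow(cl))
  # top-level arithmetic: the three classes partition the classified set
  expect_equal(sum(cl$top_level == "PROTEIN_CODING_GENE") +
                 sum(cl$top_level == "NONCODING_GENE") +
                 sum(cl$top_level == "NORF"),
               nrow(cl))
})

test_that("chromosome summary equals a flat group-by recount", {
  u <- shared_fixture()
  cl <- classify_fixture(u)
  tab <- summarize_by_chromosome(cl)
  for (ch in unique(cl$chrom)) {
    expect_equal(sum(tab[ch, ]), sum(cl$chrom == ch))
    for (cat in unique(cl$category)) {
      expect_equal(unname(tab[ch, cat]),
                   sum(cl$chrom == ch & cl$category == cat))
    }
  }
  empty <- summarize_by_chromosome(cl[0, , drop = FALSE])
  expect_equal(sum(empty), 0L)
})

test_that("classification is invariant under genome reverse-complement", {
  u <- shared_fixture()
  flipped <- flip_fixture(u$fix)
  txs2 <- generate_event_transcripts(flipped)
  # sequences are unchanged: the transcripts live on the flipped strand
  expect_equal(vapply(txs2, `[[`, character(1), "sequence"),
               vapply(u$txs, `[[`, character(1), "sequence"))
  db2 <- build_custom_database(unname(txs2), u$ref)
  gff2 <- tempfile(fileext = ".gff3")
  write_fixture_gff3(flipped, gff2)
  ann2 <- load_annotation(gff2)
  orfs2 <- list()
  for (e in db2) {
    if (e$source == "NOVEL_ORF") orfs2[[e$origin$transcript_id]] <- e$origin
  }
  aligns2 <- locate_peptides(flipped$ground_truth$peptide, db2, txs2)
  mm2 <- remove_multimapped(aligns2)
  cl2 <- classify_peptides(mm2$kept, ann2, txs2, orfs2)
  gt <- flipped$ground_truth
  m <- match(cl2$peptide, gt$peptide)
  expect_equal(cl2$category, gt$category[m])
  expect_equal(cl2$blocks, gt$blocks[m])
  expect_true(all(cl2$strand == "-"))
})

test_that("classified peptides round-trip through BED12", {
  u <- shared_fixture()
  cl <- classify_fixture(u)
  path <- tempfile(fileext = ".bed")
  write_bed(cl, path)
  back <- read_bed12(path)
  expect_length(back, nrow(cl))
  for (i in seq_len(nrow(cl))) {
    rec <- back[[paste0(cl$peptide[i], "|", cl$category[i])]]
    expect_equal(paste(rec$blocks[, 1], rec$blocks[, 2], sep = "-",
                       collapse = ","),
                 cl$blocks[i])
  }
  # independent parser: rtracklayer reproduces the same blocks
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(path, format = "bed")
  expect_equal(length(gr), nrow(cl))
  bl <- rtracklayer::blocks(gr)
  for (i in seq_len(nrow(cl))) {
    b <- bl[[i]]
    expect_equal(paste(GenomicRanges::start(b) - 1, GenomicRanges::end(b),
                       sep = "-", collapse = ","),
                 cl$blocks[i])
  }
})
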