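# One shared fixture universe per test run, built lazily and cached.
.fixture_cache <- new.env(parent = emptyenv())

shared_fixture <- function(seed = 42) {
  key <- paste0("fix", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- fixture_spec(seed = seed)
  fix <- generate_genome_and_annotation(spec)
  txs <- generate_event_transcripts(fix)
  ref <- fixture_reference_proteome(fix)
  db <- build_custom_database(unname(txs), ref)
  gff <- tempfile(fileext = ".gff3")
  write_fixture_gff3(fix, gff)
  ann <- load_annotation(gff)
  orfs <- list()
  for (e in db) {
    if (e$source == "NOVEL_ORF") orfs[[e$origin$transcript_id]] <- e$origin
  }
  out <- list(spec = spec, fix = fix, txs = txs, ref = ref, db = db,
              gff = gff, ann = ann, orfs = orfs)
  .fixture_cache[[key]] <- out
  out
}

classify_fixture <- function(u) {
  aligns <- locate_peptides(u$fix$ground_truth$peptide, u$db, u$txs)
  mm <- remove_multimapped(aligns)
  classify_peptides(mm$kept, u$ann, u$txs, u$orfs)
}

# Serialize a PSM data.frame through the TSV reader (exercises the parser).
read_psm_table_roundtrip <- function(psms) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(psms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  read_psm_table(path)
}

# Mirror a fixture genome end-for-end: reverse-complement every chromosome,
# flip all coordinates and strands. Planted biology is unchanged, so
# classification must be invariant under this transformation.
flip_fixture <- function(fix) {
  L <- nchar(fix$genome)
  out <- fix
  out$genome <- vapply(fix$genome, revcomp, character(1))
  flip <- function(chrom, s, e) {
    n <- L[[chrom]]
    c(n - e, n - s)
  }
  g <- fix$gff
  for (i in seq_len(nrow(g))) {
    se <- flip(g$seqid[i], g$start[i], g$end[i])
    g$start[i] <- se[1]; g$end[i] <- se[2]
  }
  g$strand <- "-"
  out$gff <- g
  for (tid in names(fix$tx_design)) {
    d <- fix$tx_design[[tid]]
    b <- d$blocks
    nb <- cbind(L[[d$chrom]] - b[, 2], L[[d$chrom]] - b[, 1])
    nb <- nb[order(nb[, 1]), , drop = FALSE]
    colnames(nb) <- c("start", "end")
    out$tx_design[[tid]] <- list(chrom = d$chrom, strand = "-", blocks = nb)
  }
  gt <- fix$ground_truth
  gt$strand <- "-"
  gt$blocks <- vapply(seq_len(nrow(gt)), function(i) {
    parts <- strsplit(gt$blocks[i], ",")[[1]]
    b <- do.call(rbind, lapply(parts, function(p)
      as.integer(strsplit(p, "-")[[1]])))
    n <- L[[gt$chrom[i]]]
    nb <- cbind(n - b[, 2], n - b[, 1])
    nb <- nb[order(nb[, 1]), , drop = FALSE]
    paste(nb[, 1], nb[, 2], sep = "-", collapse = ",")
  }, character(1))
  out$ground_truth <- gt
  out
}
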