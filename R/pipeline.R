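#' Derived identities of the novel-peptide discovery funnel
#'
#' The discovery funnel partitions validated novel peptides into three
#' top-level classes (protein-coding genes, noncoding genes, novel ORFs) and
#' the noncoding class into biotypes. Given the atomic counts actually
#' tallied at each stage, this computes every derived total, so internal
#' bookkeeping (e.g. that the three classes sum to the validated total, and
#' that the noncoding class decomposes identically by biotype and by
#' subtraction) can be checked as arithmetic.
#'
#' @param counts Named numeric vector or list of atomic counts:
#'   \code{peptides_initial} (novel peptides before the secondary
#'   known-protein screen), \code{ensembl_mapped} (removed by that screen),
#'   \code{pepquery_validated}, \code{coding_peptides},
#'   \code{pseudogene_peptides}, \code{lncrna_peptides},
#'   \code{tec_peptides}, \code{norf_peptides}, and optionally
#'   \code{comparison_total}/\code{comparison_known} for an external
#'   comparison dataset.
#' @return Named list of derived counts: \code{novel_peptides}
#'   (initial minus secondary-screen removals), \code{noncoding_by_biotype}
#'   (pseudogene + lncRNA + TEC), \code{noncoding_by_subtraction}
#'   (validated - coding - novel-ORF), \code{annotated_gene_peptides}
#'   (coding + noncoding), \code{partition_total} (three-class sum), and
#'   \code{comparison_novel} when the comparison atoms are present.
#' @export
funnel_identities <- function(counts) {
  counts <- as.list(counts)
  need <- function(k) {
    v <- counts[[k]]
    if (is.null(v)) stop("missing count: ", k, call. = FALSE)
    as.numeric(v)
  }
  out <- list(
    novel_peptides = need("peptides_initial") - need("ensembl_mapped"),
    noncoding_by_biotype = need("pseudogene_peptides") +
      need("lncrna_peptides") + need("tec_peptides"),
    noncoding_by_subtraction = need("pepquery_validated") -
      need("coding_peptides") - need("norf_peptides"),
    partition_total = need("coding_peptides") +
      need("pseudogene_peptides") + need("lncrna_peptides") +
      need("tec_peptides") + need("norf_peptides")
  )
  out$annotated_gene_peptides <- need("coding_peptides") +
    out$noncoding_by_biotype
  if (!is.null(counts$comparison_total) &&
      !is.null(counts$comparison_known)) {
    out$comparison_novel <- need("comparison_total") -
      need("comparison_known")
  }
  out
}

#' Read a name/value count table
#'
#' @param path TSV with columns \code{name}, \code{value} (such as the
#'   published study counts shipped under \code{inst/extdata}).
#' @return Named numeric vector.
#' @export
read_count_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$value), d$name)
}

#' Locate novel peptides in the database and project them to the genome
#'
#' Finds every occurrence of each peptide in the novel-ORF entries of the
#' custom database and projects each occurrence through the source
#' transcript's alignment (occurrences, not peptides, feed the
#' multi-mapping filter).
#'
#' @param peptides Character vector of peptide sequences.
#' @param database Entries from \code{\link{build_custom_database}}.
#' @param transcripts Named list of \code{assembled_transcript} (names =
#'   transcript ids); only aligned transcripts can be projected.
#' @return List of \code{peptide_alignment} objects.
#' @export
locate_peptides <- function(peptides, database, transcripts) {
  novel_entries <- Filter(function(e)
    e$source == "NOVEL_ORF" && !is.null(e$origin), database)
  out <- list()
  for (pep in peptides) {
    for (e in novel_entries) {
      hits <- gregexpr(pep, e$aa_sequence, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      tx <- transcripts[[e$origin$transcript_id]]
      if (is.null(tx) || is.null(tx$alignment)) next
      for (h in hits) {
        out[[length(out) + 1L]] <-
          project_peptide(h - 1L, pep, e$origin, tx)
      }
    }
  }
  out
}

#' Run the full novel-peptide pipeline on file inputs
#'
#' Chains database construction, FDR + reference novelty filtering,
#' PepQuery validation filtering, genomic projection, multi-locus removal,
#' event classification, optional hallmark mapping and optional survival
#' screening; writes stage outputs under \code{out_dir} and returns a run
#' manifest recording the peptide count at every stage of the funnel.
#'
#' @param config Named list: \code{transcripts} (FASTA), \code{alignments}
#'   (BED12), \code{reference} (character vector of protein FASTAs),
#'   \code{psms} (TSV), \code{pepquery} (TSV), \code{annotation}
#'   (GTF/GFF3), optional \code{hallmarks} (GMT), optional \code{coverage},
#'   \code{library_sizes}, \code{clinical} (TSVs), \code{peptide_gene}
#'   (optional 2-column TSV peptide/gene), \code{out_dir}, and parameter
#'   overrides \code{digestion} (list), \code{fdr}, \code{pepquery_p_max},
#'   \code{pepquery_n_ptm_max}, \code{subtype}, \code{alpha},
#'   \code{parent_threshold}.
#' @return The manifest (named list), invisibly written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  out_dir <- cfg$out_dir %||% "novelpep_out"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  txs <- stage("read-transcripts",
               read_transcripts(cfg$transcripts, cfg$alignments))
  names(txs) <- vapply(txs, `[[`, character(1), "id")
  reference <- stage("read-reference", do.call(c, lapply(
    cfg$reference, read_protein_fasta)))
  dig <- do.call(digestion_config, cfg$digestion %||% list())
  db <- stage("build-db", build_custom_database(txs, reference))
  write_database_fasta(db, file.path(out_dir, "custom_db.fa"))
  if (isTRUE(cfg$write_digest)) {
    utils::write.table(digest_database(db, dig),
                       file.path(out_dir, "digest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  index <- build_reference_index(reference)
  psms <- stage("read-psms", read_psm_table(cfg$psms))
  idents <- stage("filter-novel",
                  filter_novel(psms, index, cfg$fdr %||% 0.01))
  novel <- idents[idents$status == "NOVEL", , drop = FALSE]
  utils::write.table(novel, file.path(out_dir, "novel_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pq <- stage("read-pepquery", utils::read.delim(cfg$pepquery,
                                                 stringsAsFactors = FALSE))
  validated <- stage("pepquery-filter", apply_pepquery_filter(
    novel, pq, cfg$pepquery_p_max %||% 0.01,
    cfg$pepquery_n_ptm_max %||% 0L))
  utils::write.table(validated, file.path(out_dir, "validated_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- stage("load-annotation", load_annotation(cfg$annotation))
  aligns <- stage("project", locate_peptides(validated$peptide, db, txs))
  mm <- remove_multimapped(aligns)
  orfs <- list()
  for (e in db) {
    if (e$source == "NOVEL_ORF" && !is.null(e$origin)) {
      orfs[[e$origin$transcript_id]] <- e$origin
    }
  }
  classified <- stage("classify",
                      classify_peptides(mm$kept, ann, txs, orfs))
  m <- match(classified$peptide, validated$peptide)
  classified$psm_count <- validated$psm_count[m]
  utils::write.table(classified, file.path(out_dir, "classified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(classified, file.path(out_dir, "classified.bed"))
  chrom_tab <- summarize_by_chromosome(classified)
  utils::write.table(as.data.frame.matrix(chrom_tab),
                     file.path(out_dir, "chromosome_summary.tsv"),
                     sep = "\t", quote = FALSE)

  n_hallmark <- NA_integer_
  if (!is.null(cfg$hallmarks)) {
    sets <- stage("hallmarks", read_gmt(cfg$hallmarks))
    genes <- unique(stats::na.omit(classified$gene_id[
      classified$top_level == "PROTEIN_CODING_GENE"]))
    hm <- map_to_hallmarks(genes, sets)
    n_hallmark <- sum(lengths(hm) > 0L)
  }

  n_significant <- NA_integer_
  if (!is.null(cfg$coverage) && !is.null(cfg$clinical)) {
    surv <- stage("survival", {
      cov <- utils::read.delim(cfg$coverage, check.names = FALSE,
                               stringsAsFactors = FALSE)
      covm <- as.matrix(cov[, -1, drop = FALSE])
      rownames(covm) <- cov[[1]]
      lib <- utils::read.delim(cfg$library_sizes, stringsAsFactors = FALSE)
      libv <- stats::setNames(lib$library_size, lib$sample_id)
      cpm <- coverage_to_cpm(covm[, names(libv), drop = FALSE], libv)
      clin <- utils::read.delim(cfg$clinical, stringsAsFactors = FALSE)
      pg <- if (!is.null(cfg$peptide_gene)) {
        d <- utils::read.delim(cfg$peptide_gene, stringsAsFactors = FALSE)
        stats::setNames(d[[2]], d[[1]])
      } else {
        stats::setNames(classified$gene_id, classified$peptide)
      }
      survival_screen(cpm, cpm, clin, pg,
                      subtype = cfg$subtype %||% "all",
                      alpha = cfg$alpha %||% 0.05,
                      parent_threshold = cfg$parent_threshold %||% 0.1)
    })
    utils::write.table(surv, file.path(out_dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_significant <- sum(surv$significant)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("novelpep")),
    config = cfg[setdiff(names(cfg), "out_dir")],
    counts = list(
      transcripts = length(txs),
      database_entries = length(db),
      psms_read = nrow(psms),
      peptides_identified = nrow(idents),
      peptides_novel = nrow(novel),
      peptides_validated = nrow(validated),
      alignments = length(aligns),
      peptides_multimapped = length(mm$removed),
      peptides_classified = nrow(classified),
      genes_hallmark_mapped = n_hallmark,
      peptides_survival_significant = n_significant
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
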