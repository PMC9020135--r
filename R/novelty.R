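# Fold isoleucine to leucine: the two are isobaric and indistinguishable by
# standard MS/MS fragmentation, so novelty matching treats them as one.
.il_fold <- function(x) gsub("I", "L", x, fixed = TRUE)

#' Build a substring index over reference proteomes
#'
#' Concatenates all reference protein sequences (separator-delimited) into a
#' text searched by fixed-string matching. With \code{il_equivalent} the index
#' and every query are I-to-L folded, so peptides differing from a reference
#' only at isobaric I/L positions are still treated as known.
#'
#' @param proteomes A list of \code{\link{protein_entry}} objects (or a
#'   character vector of sequences). Decoy entries are ignored.
#' @param il_equivalent Fold I to L in both index and queries (default TRUE).
#' @return An object of class \code{reference_index}.
#' @export
build_reference_index <- function(proteomes, il_equivalent = TRUE) {
  if (is.character(proteomes)) {
    seqs <- proteomes
  } else {
    keep <- vapply(proteomes, function(e) e$source != "DECOY", logical(1))
    seqs <- vapply(proteomes[keep], `[[`, character(1), "aa_sequence")
  }
  if (length(seqs) == 0L) stop("empty reference proteome", call. = FALSE)
  if (il_equivalent) seqs <- .il_fold(seqs)
  structure(list(text = paste0("#", paste(seqs, collapse = "#"), "#"),
                 il_equivalent = isTRUE(il_equivalent),
                 n_proteins = length(seqs)),
            class = "reference_index")
}

#' Query a reference index for peptide membership
#'
#' @param index A \code{\link{build_reference_index}} result.
#' @param peptides Character vector of peptide sequences.
#' @return Logical vector: is each peptide a substring of any reference
#'   protein (after I/L folding if the index was built that way)?
#' @export
is_known <- function(index, peptides) {
  stopifnot(inherits(index, "reference_index"))
  q <- if (index$il_equivalent) .il_fold(peptides) else peptides
  vapply(q, function(p) grepl(p, index$text, fixed = TRUE), logical(1),
         USE.NAMES = FALSE)
}

#' Read a peptide-spectrum-match table
#'
#' Expects tab-separated columns \code{peptide}, \code{experiment_id},
#' \code{spectrum_id}, \code{confidence}, \code{protein_ids}
#' (semicolon-separated). Malformed rows (missing peptide, confidence outside
#' \code{[0,1]}) are dropped with a message rather than aborting the run.
#'
#' @param path TSV path.
#' @return A data.frame of PSM records.
#' @export
read_psm_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("peptide", "experiment_id", "spectrum_id", "confidence")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("PSM table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d$confidence <- suppressWarnings(as.numeric(d$confidence))
  bad <- is.na(d$peptide) | d$peptide == "" | is.na(d$confidence) |
    d$confidence < 0 | d$confidence > 1 |
    grepl("[^A-Z]", d$peptide)
  if (any(bad)) {
    message("dropping ", sum(bad), " malformed PSM row(s)")
    d <- d[!bad, , drop = FALSE]
  }
  if (is.null(d$protein_ids)) d$protein_ids <- ""
  d
}

#' Collapse FDR-passing PSMs into known/novel peptide identifications
#'
#' PSMs below the confidence implied by the FDR threshold are dropped (the
#' upstream search pipeline computed the FDR; here \code{confidence >= 1 -
#' fdr_threshold} passes). Surviving PSMs are collapsed to one record per
#' peptide; peptides found as substrings of the reference index are KNOWN,
#' the rest NOVEL.
#'
#' @param psms A PSM data.frame (see \code{\link{read_psm_table}}).
#' @param index A \code{\link{build_reference_index}} result.
#' @param fdr_threshold False-discovery-rate threshold in \code{(0, 1]}.
#' @return A data.frame with columns \code{peptide}, \code{psm_count},
#'   \code{n_experiments}, \code{experiments} (comma-separated),
#'   \code{status} (\code{KNOWN}/\code{NOVEL}), ordered by peptide.
#' @export
filter_novel <- function(psms, index, fdr_threshold = 0.01) {
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    stop("fdr_threshold must be in (0, 1]", call. = FALSE)
  }
  keep <- psms$confidence >= 1 - fdr_threshold
  psms <- psms[keep, , drop = FALSE]
  if (nrow(psms) == 0L) {
    return(data.frame(peptide = character(0), psm_count = integer(0),
                      n_experiments = integer(0), experiments = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(psms, psms$peptide)
  out <- data.frame(
    peptide = names(sp),
    psm_count = vapply(sp, nrow, integer(1)),
    n_experiments = vapply(sp, function(d)
      length(unique(d$experiment_id)), integer(1)),
    experiments = vapply(sp, function(d)
      paste(sort(unique(d$experiment_id)), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$status <- ifelse(is_known(index, out$peptide), "KNOWN", "NOVEL")
  out[order(out$peptide), , drop = FALSE]
}

#' Filter novel peptides by PepQuery validation results
#'
#' Retains a peptide when at least one of its PepQuery PSMs has
#' \code{p_value <= p_max} and \code{n_ptm <= n_ptm_max} (defaults: p-value
#' at most 0.01 with zero unrestricted modifications). Peptides with no
#' PepQuery result at all are dropped and reported.
#'
#' @param novel Identification data.frame from \code{\link{filter_novel}}
#'   (typically only NOVEL rows).
#' @param results PepQuery results: data.frame with columns \code{peptide},
#'   \code{p_value}, \code{n_ptm} (and optionally \code{hyperscore},
#'   \code{spectrum}).
#' @param p_max Maximum permutation p-value.
#' @param n_ptm_max Maximum number of post-translational modifications.
#' @return The retained subset of \code{novel}, with appended columns
#'   \code{pq_p_value} and \code{pq_n_ptm} (best passing or best available).
#' @export
apply_pepquery_filter <- function(novel, results, p_max = 0.01,
                                  n_ptm_max = 0L) {
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) {
    stop("p_max must be in (0, 1]", call. = FALSE)
  }
  results$p_value <- as.numeric(results$p_value)
  results$n_ptm <- as.integer(results$n_ptm)
  pass <- results[results$p_value <= p_max & results$n_ptm <= n_ptm_max, ,
                  drop = FALSE]
  no_result <- setdiff(novel$peptide, results$peptide)
  if (length(no_result)) {
    message(length(no_result),
            " peptide(s) had no PepQuery result and were dropped")
  }
  keep <- novel$peptide %in% pass$peptide
  out <- novel[keep, , drop = FALSE]
  if (nrow(out)) {
    best <- do.call(rbind, lapply(split(pass, pass$peptide), function(d) {
      d[which.min(d$p_value), c("peptide", "p_value", "n_ptm"), drop = FALSE]
    }))
    m <- match(out$peptide, best$peptide)
    out$pq_p_value <- best$p_value[m]
    out$pq_n_ptm <- best$n_ptm[m]
  } else {
    out$pq_p_value <- numeric(0)
    out$pq_n_ptm <- integer(0)
  }
  row.names(out) <- NULL
  out
}

#' Merge peptide identifications across experiments
#'
#' @param per_experiment A list of identification data.frames (as returned by
#'   \code{\link{filter_novel}}), one per experiment or batch.
#' @return One data.frame with a single row per distinct peptide:
#'   \code{psm_count} summed, \code{experiments} unioned. Conflicting status
#'   labels resolve to KNOWN (a peptide known anywhere is known).
#' @export
aggregate_psm_counts <- function(per_experiment) {
  all <- do.call(rbind, per_experiment)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(peptide = character(0), psm_count = integer(0),
                      n_experiments = integer(0), experiments = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(all, all$peptide)
  out <- data.frame(
    peptide = names(sp),
    psm_count = vapply(sp, function(d) sum(d$psm_count), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  exps <- vapply(sp, function(d) {
    paste(sort(unique(unlist(strsplit(d$experiments, ",", fixed = TRUE)))),
          collapse = ",")
  }, character(1))
  out$n_experiments <- vapply(strsplit(exps, ",", fixed = TRUE), length,
                              integer(1))
  out$experiments <- exps
  out$status <- vapply(sp, function(d) {
    if (any(d$status == "KNOWN")) "KNOWN" else d$status[1]
  }, character(1))
  out[order(out$peptide), , drop = FALSE]
}
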