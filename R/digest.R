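#' Digestion configuration
#'
#' Parameters for in-silico tryptic digestion, defaulting to the common
#' database-search settings: up to 2 missed cleavages and peptide lengths
#' between 7 and 30 residues, with cleavage after K/R suppressed before
#' proline (the Keil rule).
#'
#' @param max_missed_cleavages Maximum number of uncut internal K/R sites.
#' @param min_len,max_len Retained peptide length bounds (residues).
#' @param keil_rule Suppress cleavage when K/R is followed by P.
#' @return An object of class \code{digestion_config}.
#' @export
digestion_config <- function(max_missed_cleavages = 2L, min_len = 7L,
                             max_len = 30L, keil_rule = TRUE) {
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (max_missed_cleavages < 0L) {
    stop("max_missed_cleavages must be >= 0", call. = FALSE)
  }
  if (min_len < 1L || min_len > max_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  structure(list(max_missed_cleavages = max_missed_cleavages,
                 min_len = min_len, max_len = max_len,
                 keil_rule = isTRUE(keil_rule)),
            class = "digestion_config")
}

# 0-based positions after which trypsin cuts: after K or R, not before P
# (when keil_rule). Returns integer vector of cut points in 1..nchar-1
# (position i means a cut between residue i and i+1, 1-based).
.cleavage_sites <- function(protein, keil_rule = TRUE) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  kr <- which(chars[-n] %in% c("K", "R"))
  if (keil_rule && length(kr)) kr <- kr[chars[kr + 1L] != "P"]
  kr
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein after K or R (suppressed before P when the Keil rule is
#' on), generates all peptides spanning at most
#' \code{config$max_missed_cleavages} internal cleavage sites, and keeps those
#' within the configured length bounds.
#'
#' @param protein A single uppercase amino-acid string.
#' @param config A \code{\link{digestion_config}}.
#' @param positions If \code{TRUE}, return a data.frame with columns
#'   \code{peptide}, \code{start} (0-based residue offset in the protein) and
#'   \code{missed_cleavages}; otherwise a deduplicated character vector of
#'   peptides.
#' @return Character vector of unique peptides, or a data.frame when
#'   \code{positions = TRUE} (one row per occurrence).
#' @examples
#' digest_tryptic("AAAAAAAKCCCCCCCR", digestion_config(0, 7, 30))
#' @export
digest_tryptic <- function(protein, config = digestion_config(),
                           positions = FALSE) {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein) ||
      nchar(protein) == 0L) {
    stop("protein must be a single non-empty string", call. = FALSE)
  }
  stopifnot(inherits(config, "digestion_config"))
  n <- nchar(protein)
  cuts <- .cleavage_sites(protein, config$keil_rule)
  # fragment boundaries in 0-based half-open coordinates
  bounds <- c(0L, cuts, n)
  n_frag <- length(bounds) - 1L
  pep <- character(0)
  start <- integer(0)
  mc <- integer(0)
  for (i in seq_len(n_frag)) {
    for (j in i:min(n_frag, i + config$max_missed_cleavages)) {
      len <- bounds[j + 1L] - bounds[i]
      if (len < config$min_len || len > config$max_len) next
      pep <- c(pep, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
      start <- c(start, bounds[i])
      mc <- c(mc, j - i)
    }
  }
  if (positions) {
    return(data.frame(peptide = pep, start = start, missed_cleavages = mc,
                      stringsAsFactors = FALSE))
  }
  unique(pep)
}

#' Digest every target entry of a database to a peptide table
#'
#' @param entries A protein database as returned by
#'   \code{\link{build_custom_database}} (decoys are skipped).
#' @param config A \code{\link{digestion_config}}.
#' @return A data.frame with columns \code{protein_id}, \code{peptide},
#'   \code{start}, \code{missed_cleavages}.
#' @export
digest_database <- function(entries, config = digestion_config()) {
  out <- lapply(entries, function(e) {
    if (e$source == "DECOY") return(NULL)
    d <- digest_tryptic(e$aa_sequence, config, positions = TRUE)
    if (nrow(d) == 0L) return(NULL)
    cbind(data.frame(protein_id = e$id, stringsAsFactors = FALSE), d)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), peptide = character(0),
                      start = integer(0), missed_cleavages = integer(0),
                      stringsAsFactors = FALSE)
  }
  out
}
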