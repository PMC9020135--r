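#' Write classified peptides as a BED12 track
#'
#' One line per peptide; \code{blockSizes}/\code{blockStarts} encode the
#' genomic blocks, and the name field carries \code{peptide|category}.
#'
#' @param classified Data.frame from \code{\link{classify_peptides}} (needs
#'   \code{peptide}, \code{chrom}, \code{strand}, \code{blocks}, and
#'   optionally \code{category}).
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(classified, path) {
  lines <- character(nrow(classified))
  for (i in seq_len(nrow(classified))) {
    bl <- do.call(rbind, lapply(
      strsplit(classified$blocks[i], ",", fixed = TRUE)[[1]],
      function(p) as.integer(strsplit(p, "-", fixed = TRUE)[[1]])))
    cs <- bl[1L, 1L]
    ce <- bl[nrow(bl), 2L]
    name <- if (!is.null(classified$category)) {
      paste0(classified$peptide[i], "|", classified$category[i])
    } else classified$peptide[i]
    lines[i] <- paste(
      classified$chrom[i], cs, ce, name, 0L, classified$strand[i], cs, ce,
      "0,0,0", nrow(bl),
      paste0(paste(bl[, 2L] - bl[, 1L], collapse = ","), ","),
      paste0(paste(bl[, 1L] - cs, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 file as per-name genomic block lists
#'
#' @param path BED12 path.
#' @return A named list (by the BED name field): each element a list with
#'   \code{chrom}, \code{strand}, and a \code{blocks} matrix of 0-based
#'   half-open genomic blocks.
#' @export
read_bed12 <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12L) stop("expected 12 BED columns", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(d))) {
    cs <- as.integer(d[i, 2L])
    sizes <- as.integer(strsplit(sub(",$", "", d[i, 11L]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", d[i, 12L]), ",")[[1]])
    blocks <- cbind(start = cs + starts, end = cs + starts + sizes)
    out[[as.character(d[i, 4L])]] <- list(chrom = as.character(d[i, 1L]),
                                          strand = as.character(d[i, 6L]),
                                          blocks = blocks)
  }
  out
}
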