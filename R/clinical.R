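#' Read hallmark gene sets from a GMT file
#'
#' GMT format: one set per line, tab-separated: name, description, then gene
#' symbols. Symbols are upper-cased.
#'
#' @param path GMT path.
#' @return Named list of character vectors (set name -> gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) next
    out[[f[1]]] <- unique(toupper(f[-(1:2)]))
  }
  if (length(out) == 0L) stop("no gene sets parsed from ", path, call. = FALSE)
  out
}

#' Map genes to cancer-hallmark set membership
#'
#' @param gene_ids Character vector of gene symbols.
#' @param sets Named list of gene-symbol vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @return Named list: for each gene, the character vector of hallmark set
#'   names containing it (empty when in none).
#' @export
map_to_hallmarks <- function(gene_ids, sets) {
  gene_ids <- unique(as.character(gene_ids))
  res <- lapply(toupper(gene_ids), function(g) {
    names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
  })
  names(res) <- gene_ids
  res
}

#' Convert mean per-base coverage to counts per million
#'
#' @param mean_coverage Numeric scalar, vector or matrix of mean per-base
#'   read coverage over a peptide's genomic blocks.
#' @param library_size Total mapped reads per sample (scalar, or one per
#'   column when \code{mean_coverage} is a matrix).
#' @return \code{mean_coverage / library_size * 1e6}, same shape as the
#'   input.
#' @export
coverage_to_cpm <- function(mean_coverage, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  if (is.matrix(mean_coverage)) {
    if (length(library_size) == 1L) {
      library_size <- rep(library_size, ncol(mean_coverage))
    }
    stopifnot(length(library_size) == ncol(mean_coverage))
    return(sweep(mean_coverage, 2L, library_size, "/") * 1e6)
  }
  mean_coverage / library_size * 1e6
}

#' Stratify samples by the mean expression value
#'
#' @param expression Numeric vector over samples.
#' @return Character vector of \code{"HIGH"}/\code{"LOW"} labels:
#'   \code{HIGH} strictly above the mean, ties at the mean go to \code{LOW}.
#'   Errors on fewer than 2 samples or a constant vector (degenerate
#'   stratification).
#' @export
stratify_by_mean <- function(expression) {
  if (length(expression) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(expression)) == 1L) {
    stop("constant expression vector: degenerate stratification",
         call. = FALSE)
  }
  ifelse(expression > mean(expression), "HIGH", "LOW")
}

#' Kaplan-Meier product-limit estimate
#'
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over distinct event times
#' \eqn{t_i}, with \eqn{d_i} deaths and \eqn{n_i} subjects at risk;
#' right-continuous, \eqn{S(0) = 1}. With no censoring this equals the
#' empirical survival function.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = death, 0 = censored).
#' @return An object of class \code{km_fit}: data.frame-backed list with
#'   \code{time} (distinct event times), \code{n_risk}, \code{n_event},
#'   \code{surv}, and \code{surv_fn}, a right-continuous step function.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  fn <- if (length(et)) {
    stats::stepfun(et, c(1, surv), right = FALSE)
  } else {
    function(t) rep(1, length(t))
  }
  structure(list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
                 surv_fn = fn),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d event time(s); final S = %.4f\n", length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Accumulates observed and hypergeometric-expected events (and variance)
#' over the distinct event times of the pooled sample;
#' \eqn{\chi^2 = (O - E)^2 / V} referred to a chi-square distribution with
#' one degree of freedom.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1/0).
#' @param groups Two-level group labels (e.g. \code{"HIGH"}/\code{"LOW"}).
#' @return List with \code{chi2}, \code{p}, \code{observed} and
#'   \code{expected} (named by group). The sign of \code{observed - expected}
#'   tells which group died more than expected.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L) stop("need exactly two non-empty groups",
                             call. = FALSE)
  if (sum(events) == 0) stop("no events: log-rank test undefined",
                             call. = FALSE)
  g1 <- groups == lv[1]
  et <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  O <- c(O1, sum(events) - O1)
  E <- c(E1, sum(events) - E1)
  names(O) <- names(E) <- lv
  list(chi2 = chi2, p = p, observed = O, expected = E)
}

#' Peptide-level survival screen with parent-gene control
#'
#' For each peptide region: restrict to the requested tumour subtype, split
#' samples into high/low groups at the mean expression
#' (\code{\link{stratify_by_mean}}), and test survival separation with the
#' log-rank test. The same is done for the peptide's parent gene; a peptide
#' is flagged significant only when its own p-value passes \code{alpha}
#' while the parent gene shows no survival association (parent p above
#' \code{parent_threshold}), so the association is attributable to the novel
#' peptide region rather than overall gene expression.
#'
#' @param expression Peptide CPM matrix (rows = peptides, columns = sample
#'   ids).
#' @param parent_gene_expression Gene CPM matrix (rows = gene ids, columns =
#'   sample ids).
#' @param clinical Data.frame with columns \code{sample_id}, \code{subtype},
#'   \code{time_days}, \code{event}.
#' @param peptide_gene Named character vector mapping peptide (rownames of
#'   \code{expression}) to parent gene id.
#' @param subtype Subtype to analyse, or \code{"all"}.
#' @param alpha Peptide significance threshold.
#' @param parent_threshold Parent gene is considered survival-associated when
#'   its p-value is at or below this (default 0.1, treating near-significant
#'   parent association as disqualifying).
#' @param min_samples Minimum subtype size; smaller subtypes are skipped with
#'   a warning.
#' @param expression_filter Optional function taking the per-sample
#'   expression vector of a peptide and returning \code{TRUE} to keep it —
#'   a pluggable pre-screen (default \code{NULL}: no pre-filtering).
#' @param p_adjust_method Optional multiple-testing correction applied to
#'   the peptide p-values (\code{"none"} by default, matching raw reporting;
#'   e.g. \code{"BH"}).
#' @return Data.frame with one row per testable peptide: \code{peptide},
#'   \code{gene_id}, \code{subtype}, \code{n_high}, \code{n_low},
#'   \code{logrank_chi2}, \code{p_novel}, \code{p_parent_gene},
#'   \code{direction} (\code{HIGH_EXPR_POOR}/\code{LOW_EXPR_POOR}),
#'   \code{significant}.
#' @export
survival_screen <- function(expression, parent_gene_expression, clinical,
                            peptide_gene, subtype = "all", alpha = 0.05,
                            parent_threshold = 0.1, min_samples = 10L,
                            expression_filter = NULL,
                            p_adjust_method = "none") {
  cl <- clinical
  if (!identical(subtype, "all")) cl <- cl[cl$subtype == subtype, , drop = FALSE]
  samples <- intersect(cl$sample_id, colnames(expression))
  if (length(samples) < min_samples) {
    warning("subtype '", subtype, "' has ", length(samples),
            " samples (< ", min_samples, "); skipped", call. = FALSE)
    return(data.frame())
  }
  cl <- cl[match(samples, cl$sample_id), , drop = FALSE]
  rows <- list()
  for (pep in rownames(expression)) {
    expr <- expression[pep, samples]
    if (!is.null(expression_filter) && !isTRUE(expression_filter(expr))) next
    grp <- tryCatch(stratify_by_mean(expr), error = function(e) NULL)
    if (is.null(grp) || length(unique(grp)) < 2L) {
      message("peptide ", pep, ": degenerate stratification; skipped")
      next
    }
    lr <- tryCatch(logrank_test(cl$time_days, cl$event, grp),
                   error = function(e) NULL)
    if (is.null(lr)) next
    gene <- if (pep %in% names(peptide_gene)) peptide_gene[[pep]] else
      NA_character_
    p_parent <- NA_real_
    if (!is.null(gene) && !is.na(gene) &&
        gene %in% rownames(parent_gene_expression)) {
      gexpr <- parent_gene_expression[gene, samples]
      ggrp <- tryCatch(stratify_by_mean(gexpr), error = function(e) NULL)
      if (!is.null(ggrp) && length(unique(ggrp)) == 2L) {
        glr <- tryCatch(logrank_test(cl$time_days, cl$event, ggrp),
                        error = function(e) NULL)
        if (!is.null(glr)) p_parent <- glr$p
      }
    }
    dir <- if (lr$observed["HIGH"] > lr$expected["HIGH"]) {
      "HIGH_EXPR_POOR"
    } else {
      "LOW_EXPR_POOR"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = pep,
      gene_id = if (is.null(gene)) NA_character_ else gene,
      subtype = subtype,
      n_high = sum(grp == "HIGH"), n_low = sum(grp == "LOW"),
      logrank_chi2 = lr$chi2, p_novel = lr$p, p_parent_gene = p_parent,
      direction = dir, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  if (!identical(p_adjust_method, "none")) {
    out$p_novel_adj <- stats::p.adjust(out$p_novel, method = p_adjust_method)
  }
  p_use <- if (!identical(p_adjust_method, "none")) out$p_novel_adj else
    out$p_novel
  out$significant <- p_use <= alpha &
    (is.na(out$p_parent_gene) | out$p_parent_gene > parent_threshold)
  row.names(out) <- NULL
  out
}

#' Per-peptide Kaplan-Meier table for the two expression groups
#'
#' @param times,events Survival data.
#' @param groups HIGH/LOW labels from \code{\link{stratify_by_mean}}.
#' @return Data.frame with columns \code{time}, \code{group}, \code{surv},
#'   \code{n_risk}, \code{n_event} stacked over the two groups.
#' @export
km_table <- function(times, events, groups) {
  out <- lapply(c("HIGH", "LOW"), function(g) {
    sel <- groups == g
    if (!any(sel)) return(NULL)
    km <- km_estimate(times[sel], events[sel])
    if (length(km$time) == 0L) return(NULL)
    data.frame(time = km$time, group = g, surv = km$surv,
               n_risk = km$n_risk, n_event = km$n_event,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
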