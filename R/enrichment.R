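# Class-enrichment statistics: 2x2 contingency tables, exact conditional
# (hypergeometric) tests, odds ratios, and the cross-class report.
#
# The exact test is written out here rather than delegated, because its
# tie handling and log-space evaluation are part of the package's contract
# and are verified against an independent enumeration oracle in the tests.

#' Construct a 2x2 contingency table of motif presence
#'
#' @param a Promoters with the motif in set A.
#' @param b Promoters without the motif in set A.
#' @param c Promoters with the motif in set B.
#' @param d Promoters without the motif in set B.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(11, 39, 0, 20)
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("contingency counts must be non-negative integers")
  counts <- stats::setNames(as.list(as.integer(counts)), names(counts))
  structure(counts, class = "contingency_table")
}

.as_table <- function(t) {
  if (inherits(t, "contingency_table")) return(t)
  if (is.matrix(t) && all(dim(t) == 2L))
    return(contingency_table(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  if (is.numeric(t) && length(t) == 4L)
    return(contingency_table(t[1], t[2], t[3], t[4]))
  stop("expected a contingency_table, a 2x2 matrix, or 4 counts (a,b,c,d)")
}

#' Exact conditional test on a 2x2 table
#'
#' Conditions on the margins and evaluates the hypergeometric distribution
#' of the top-left cell. Two-sided p-values use the point-probability
#' criterion: the sum of the probabilities of all tables with the same
#' margins whose point probability does not exceed that of the observed
#' table (with a relative tie tolerance of 1e-7, so floating-point-equal
#' probabilities are included). One-sided alternatives refer to enrichment
#' of the motif in set A (`greater`) or depletion (`less`). Probabilities
#' are accumulated in log space, so large background tables (hundreds of
#' promoters) lose no accuracy. A margin that is zero on both sides of
#' either classification returns p = 1.
#'
#' @param t A `contingency_table`, 2x2 matrix, or numeric vector (a,b,c,d).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return The p-value, a number in (0, 1].
#' @examples
#' fisher_exact(contingency_table(11, 39, 0, 20))             # ~0.027
#' fisher_exact(contingency_table(11, 39, 0, 20), "greater")  # ~0.017
#' @export
fisher_exact <- function(t, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  t <- .as_table(t)
  nA <- t$a + t$b; nB <- t$c + t$d; m <- t$a + t$c
  if (nA == 0L || nB == 0L || m == 0L || m == nA + nB) return(1)
  support <- max(0L, m - nB):min(m, nA)
  logp <- stats::dhyper(support, nA, nB, m, log = TRUE)
  keep <- switch(alternative,
    greater = support >= t$a,
    less = support <= t$a,
    two.sided = logp <= logp[support == t$a] + log1p(1e-7)
  )
  # log-sum-exp over the selected tables
  mx <- max(logp[keep])
  min(1, exp(mx + log(sum(exp(logp[keep] - mx)))))
}

#' Two-sided exact test (point-probability criterion)
#'
#' Convenience wrapper around [fisher_exact()] with
#' `alternative = "two.sided"`.
#'
#' @inheritParams fisher_exact
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(t) fisher_exact(t, "two.sided")

#' Sample odds ratio of a 2x2 table
#'
#' (a d)/(b c); infinite when the denominator is zero but the numerator is
#' not, and 1 by convention when both products are zero.
#'
#' @inheritParams fisher_exact
#' @return A non-negative number, possibly `Inf`.
#' @export
odds_ratio <- function(t) {
  t <- .as_table(t)
  num <- as.numeric(t$a) * t$d; den <- as.numeric(t$b) * t$c
  if (den == 0) { if (num == 0) 1 else Inf } else num / den
}

.class_of <- function(classes) {
  if (is.data.frame(classes)) {
    stopifnot(all(c("gene_id", "class") %in% names(classes)))
    stats::setNames(as.character(classes$class), classes$gene_id)
  } else if (inherits(classes, "promoter_set")) {
    stats::setNames(classes$records$class_label, classes$records$gene_id)
  } else {
    stopifnot(is.character(classes), !is.null(names(classes)))
    classes
  }
}

#' Test one motif's enrichment between two promoter classes
#'
#' Builds the 2x2 presence table restricted to the two classes and applies
#' the exact test and odds ratio. `p_greater` is the one-sided p-value for
#' over-representation in set A.
#'
#' @param presence Logical presence matrix (genes x motifs) or `motif_scan`.
#' @param classes Gene classes: a data.frame (gene_id, class), a named
#'   character vector, or the scanned `promoter_set` itself.
#' @param motif_name Column of the presence matrix to test.
#' @param set_A,set_B The two class labels to compare.
#' @return One-row data.frame: motif, comparison, n_A, hits_A, frac_A,
#'   n_B, hits_B, frac_B, odds_ratio, p_two_sided, p_greater.
#' @export
enrich <- function(presence, classes, motif_name, set_A, set_B) {
  if (inherits(presence, "motif_scan")) presence <- presence$presence
  if (!motif_name %in% colnames(presence))
    stop("motif '", motif_name, "' not in presence matrix")
  cls <- .class_of(classes)[rownames(presence)]
  in_A <- !is.na(cls) & cls == set_A
  in_B <- !is.na(cls) & cls == set_B
  if (!any(in_A)) stop("class '", set_A, "' is empty among labeled genes")
  if (!any(in_B)) stop("class '", set_B, "' is empty among labeled genes")
  col <- presence[, motif_name]
  tab <- contingency_table(sum(col[in_A]), sum(!col[in_A]),
                           sum(col[in_B]), sum(!col[in_B]))
  data.frame(
    motif = motif_name,
    comparison = paste(set_A, "vs", set_B),
    n_A = tab$a + tab$b, hits_A = tab$a, frac_A = tab$a / (tab$a + tab$b),
    n_B = tab$c + tab$d, hits_B = tab$c, frac_B = tab$c / (tab$c + tab$d),
    odds_ratio = odds_ratio(tab),
    p_two_sided = fisher_exact(tab, "two.sided"),
    p_greater = fisher_exact(tab, "greater"),
    stringsAsFactors = FALSE)
}

#' The default class comparisons
#'
#' Class I vs Class II, Class I vs background, Class II vs background.
#'
#' @return List of length-2 character vectors.
#' @export
default_comparisons <- function() {
  list(c("class_I", "class_II"),
       c("class_I", "background"),
       c("class_II", "background"))
}

#' Full motif-by-comparison enrichment report
#'
#' One row per (motif, comparison) in catalog order then comparison order.
#' Raw p-values are reported (no multiple-testing correction); the number
#' of tests is recorded in the `n_tests` column so downstream correction
#' is straightforward.
#'
#' @inheritParams enrich
#' @param catalog A `motif_catalog` naming the columns to test
#'   (default [builtin_catalog()]).
#' @param comparisons List of c(set_A, set_B) pairs
#'   (default [default_comparisons()]).
#' @return data.frame with one row per motif x comparison.
#' @export
enrichment_report <- function(presence, classes, catalog = builtin_catalog(),
                              comparisons = default_comparisons()) {
  rows <- list()
  for (m in names(catalog))
    for (cmp in comparisons)
      rows[[length(rows) + 1L]] <- enrich(presence, classes, m, cmp[1], cmp[2])
  out <- do.call(rbind, rows)
  out$n_tests <- nrow(out)
  rownames(out) <- NULL
  out
}

#' Write / read an enrichment report
#'
#' TSV or JSON, chosen by the file extension (.json for JSON, anything
#' else TSV). Values round-trip exactly (full double precision).
#'
#' @param report data.frame from [enrichment_report()].
#' @param path Output path.
#' @return `path` invisibly for the writer; the data.frame for the reader.
#' @export
write_enrichment_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         na = "string", pretty = TRUE)
  } else {
    fmt <- report
    for (col in c("frac_A", "frac_B", "odds_ratio", "p_two_sided", "p_greater"))
      fmt[[col]] <- ifelse(is.finite(fmt[[col]]),
                           sprintf("%.17g", fmt[[col]]),
                           as.character(fmt[[col]]))
    utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_enrichment_report
#' @export
read_enrichment_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  for (col in c("frac_A", "frac_B", "odds_ratio", "p_two_sided", "p_greater"))
    df[[col]] <- as.numeric(df[[col]])
  df
}
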