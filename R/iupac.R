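# IUPAC nucleotide ambiguity alphabet: expansion, complement, regex translation.

.IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_CODES <- names(.IUPAC_EXPAND)

# complement is defined on the whole ambiguity alphabet (M <-> K etc.)
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Expand an IUPAC ambiguity code to the bases it admits
#'
#' @param code A single IUPAC nucleotide character (case-insensitive).
#' @return Character vector of unambiguous bases (subset of A, C, G, T).
#' @examples
#' expand_iupac("N")
#' expand_iupac("M")
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("`code` must be a single character")
  code <- toupper(code)
  if (!code %in% .IUPAC_CODES)
    stop("not an IUPAC nucleotide code: '", code, "'")
  .IUPAC_EXPAND[[code]]
}

.check_iupac_string <- function(x, what = "sequence") {
  bad <- regmatches(x, regexpr(sprintf("[^%s]", .IUPAC_FROM), toupper(x)))
  if (length(bad) && nzchar(bad))
    stop("non-IUPAC character '", bad, "' in ", what)
  invisible(TRUE)
}

#' Reverse complement of IUPAC strings
#'
#' Complements ambiguity codes too (e.g. M to K), so degenerate motif
#' patterns can be reverse-complemented, not just plain sequence.
#'
#' @param x Character vector of DNA strings over the IUPAC alphabet.
#' @return Character vector of the same lengths; an involution.
#' @examples
#' reverse_complement("TGTC")    # "GACA"
#' reverse_complement("CACGTG")  # palindrome
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    .check_iupac_string(s)
    comp <- chartr(.IUPAC_FROM, .IUPAC_TO, toupper(s))
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate an IUPAC pattern into a PCRE character-class regex. N becomes
# [ACGT], so an N (or any non-ACGT letter) in the scanned sequence never
# matches any pattern position.
iupac_to_regex <- function(pattern) {
  .check_iupac_string(pattern, "pattern")
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    bases <- .IUPAC_EXPAND[[ch]]
    if (length(bases) == 1L) bases else paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}
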