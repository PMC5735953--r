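# Motif grammars: single IUPAC consensus patterns and spaced dyads
# (everted repeats), their strand algebra, and the built-in catalog.

#' Create a degenerate consensus motif
#'
#' @param name Short unique identifier.
#' @param pattern IUPAC string (length >= 4) over A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @param strand_mode `"both_strands"` (default) or `"forward_only"`.
#'   Palindromic patterns are scanned on the forward strand only and each
#'   site is reported once, regardless of mode.
#' @return An object of class `consensus_motif`.
#' @examples
#' consensus_motif("BZR1_Gbox", "CACGTG")
#' consensus_motif("ClassI_PIF5like", "CANNNNCATGTG")
#' @export
consensus_motif <- function(name, pattern,
                            strand_mode = c("both_strands", "forward_only")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4L)
    stop("consensus pattern must be at least 4 nt, got '", pattern, "'")
  .check_iupac_string(pattern, "pattern")
  structure(list(name = name, pattern = pattern, strand_mode = strand_mode),
            class = c("consensus_motif", "motif"))
}

#' Create a spaced-dyad motif (two cores with a variable-length spacer)
#'
#' Describes elements like the combined auxin response element
#' TGTC\[N11-13\]GACA: two IUPAC cores separated by `spacer_min` to
#' `spacer_max` unconstrained nucleotides. The spacer counts bases strictly
#' between the cores, so TGTC + 11 nt + GACA spans a 19-nt window.
#'
#' @param name Short unique identifier.
#' @param core5,core3 IUPAC strings for the upstream and downstream cores.
#' @param spacer_min,spacer_max Spacer length bounds in nt, 0 <= min <= max <= 50.
#' @return An object of class `dyad_motif`.
#' @examples
#' dyad_motif("AuxRE_combined", "TGTC", "GACA", 11, 13)
#' @export
dyad_motif <- function(name, core5, core3, spacer_min, spacer_max) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  core5 <- toupper(core5); core3 <- toupper(core3)
  .check_iupac_string(core5, "core5")
  .check_iupac_string(core3, "core3")
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  if (is.na(spacer_min) || is.na(spacer_max) ||
      spacer_min < 0L || spacer_min > spacer_max || spacer_max > 50L)
    stop("spacer range must satisfy 0 <= spacer_min <= spacer_max <= 50")
  structure(list(name = name, core5 = core5, core3 = core3,
                 spacer_min = spacer_min, spacer_max = spacer_max),
            class = c("dyad_motif", "motif"))
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus motif> %s: %s (%s)\n", x$name, x$pattern, x$strand_mode))
  invisible(x)
}

#' @export
print.dyad_motif <- function(x, ...) {
  cat(sprintf("<dyad motif> %s: %s[N%d-%d]%s%s\n", x$name, x$core5,
              x$spacer_min, x$spacer_max, x$core3,
              if (is_self_reverse_complementary(x)) " (everted repeat)" else ""))
  invisible(x)
}

#' Is a motif its own reverse complement?
#'
#' A palindromic consensus (e.g. CACGTG), or a dyad whose pattern family is
#' closed under reverse complementation (an everted repeat such as
#' TGTC\[N11-13\]GACA), matches identically on both strands; the scanner
#' then scans the forward strand only and reports each site once.
#'
#' @param motif A `consensus_motif` or `dyad_motif`.
#' @return Logical scalar.
#' @export
is_self_reverse_complementary <- function(motif) {
  UseMethod("is_self_reverse_complementary")
}

#' @export
is_self_reverse_complementary.consensus_motif <- function(motif) {
  identical(reverse_complement(motif$pattern), motif$pattern)
}

#' @export
is_self_reverse_complementary.dyad_motif <- function(motif) {
  # revcomp of core5 [N_s] core3 is revcomp(core3) [N_s] revcomp(core5);
  # the spacer range maps onto itself, so only the cores decide.
  identical(reverse_complement(motif$core3), motif$core5) &&
    identical(reverse_complement(motif$core5), motif$core3)
}

# match width(s): scalar for consensus, one per spacer for dyads
motif_widths <- function(motif) {
  if (inherits(motif, "consensus_motif")) return(nchar(motif$pattern))
  nchar(motif$core5) + (motif$spacer_min:motif$spacer_max) + nchar(motif$core3)
}

#' Build a motif catalog
#'
#' @param ... `consensus_motif` / `dyad_motif` objects, or a single list of them.
#' @return An ordered, uniquely named list of class `motif_catalog`.
#' @export
motif_catalog <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && !inherits(entries[[1L]], "motif"))
    entries <- entries[[1L]]
  if (!length(entries)) stop("catalog must contain at least one motif")
  ok <- vapply(entries, inherits, logical(1), what = "motif")
  if (!all(ok)) stop("all catalog entries must be motifs")
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate motif names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(entries) <- nms
  structure(entries, class = "motif_catalog")
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif catalog> %d motifs\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

#' The built-in cis-element catalog
#'
#' The motifs analysed in auxin-responsive promoter studies: single AuxRE
#' cores TGTCTC and TGTCGG (scanned on both strands), the combined AuxRE
#' everted repeat TGTC\[N11-13\]GACA and two relaxed GGTC-core variants, the
#' BZR1-bound G-box CACGTG, the PIF core box CATGTG, and two extended
#' PIF5-like consensus patterns (CANNNNCATGTG and CAMNNANGTG).
#'
#' @return A `motif_catalog` of 9 motifs.
#' @export
builtin_catalog <- function() {
  motif_catalog(
    consensus_motif("AuxRE_TGTCTC", "TGTCTC", "both_strands"),
    consensus_motif("AuxRE_TGTCGG", "TGTCGG", "both_strands"),
    dyad_motif("AuxRE_combined", "TGTC", "GACA", 11, 13),
    dyad_motif("AuxRE_relaxed_GGTC11", "GGTC", "GACA", 11, 11),
    dyad_motif("AuxRE_relaxed_GGTC9", "GGTC", "GACA", 9, 9),
    consensus_motif("BZR1_Gbox", "CACGTG", "both_strands"),
    consensus_motif("PIF_core", "CATGTG", "both_strands"),
    consensus_motif("ClassI_PIF5like", "CANNNNCATGTG", "both_strands"),
    consensus_motif("ClassII_PIF5like", "CAMNNANGTG", "both_strands")
  )
}

#' Read a motif catalog from a TSV definition file
#'
#' Expected columns: name, kind (`consensus` or `dyad`), pattern (consensus
#' rows), core5/core3/spacer_min/spacer_max (dyad rows), strand_mode.
#' Header row required; fields not applicable to a row's kind may be empty.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A `motif_catalog`.
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("name", "kind")
  if (!all(required %in% names(df)))
    stop("motif table must have columns: ", paste(required, collapse = ", "))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    switch(as.character(row$kind),
      consensus = consensus_motif(row$name, row$pattern,
                                  strand_mode = row$strand_mode),
      dyad = dyad_motif(row$name, row$core5, row$core3,
                        row$spacer_min, row$spacer_max),
      stop("line ", i + 1L, ": unknown motif kind '", row$kind, "'")
    )
  })
  motif_catalog(entries)
}

#' Write a motif catalog to a TSV definition file
#'
#' @param catalog A `motif_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "motif_catalog"))
  rows <- lapply(catalog, function(m) {
    if (inherits(m, "consensus_motif")) {
      data.frame(name = m$name, kind = "consensus", pattern = m$pattern,
                 core5 = NA, core3 = NA, spacer_min = NA, spacer_max = NA,
                 strand_mode = m$strand_mode, stringsAsFactors = FALSE)
    } else {
      data.frame(name = m$name, kind = "dyad", pattern = NA,
                 core5 = m$core5, core3 = m$core3,
                 spacer_min = m$spacer_min, spacer_max = m$spacer_max,
                 strand_mode = "both_strands", stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
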