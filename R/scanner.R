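# Motif scanning: all occurrences of consensus and dyad motifs in promoter
# sequences, reduced to per-gene presence/absence.

# all 0-based start positions of a regex, overlapping matches included;
# vectorized over sequences, returns a list of integer vectors
.regex_starts_vec <- function(seqs, regex) {
  lapply(gregexpr(paste0("(?=", regex, ")"), seqs, perl = TRUE),
         function(m) if (m[1L] == -1L) integer(0) else as.integer(m) - 1L)
}

.regex_starts <- function(seq, regex) .regex_starts_vec(seq, regex)[[1L]]

# every (regex, strand, spacer, width) a motif expands to, honouring the
# strand algebra: self-reverse-complementary patterns scan forward only
.motif_regexes <- function(motif) {
  if (inherits(motif, "consensus_motif")) {
    rows <- data.frame(regex = iupac_to_regex(motif$pattern), strand = "+",
                       spacer_len = NA_integer_, width = nchar(motif$pattern),
                       stringsAsFactors = FALSE)
    if (motif$strand_mode == "both_strands" &&
        !is_self_reverse_complementary(motif))
      rows <- rbind(rows, data.frame(
        regex = iupac_to_regex(reverse_complement(motif$pattern)),
        strand = "-", spacer_len = NA_integer_,
        width = nchar(motif$pattern), stringsAsFactors = FALSE))
    return(rows)
  }
  orientations <- list(list(core5 = motif$core5, core3 = motif$core3,
                            strand = "+"))
  if (!is_self_reverse_complementary(motif))
    orientations <- c(orientations,
                      list(list(core5 = reverse_complement(motif$core3),
                                core3 = reverse_complement(motif$core5),
                                strand = "-")))
  do.call(rbind, lapply(orientations, function(o) {
    s <- motif$spacer_min:motif$spacer_max
    data.frame(regex = paste0(iupac_to_regex(o$core5),
                              sprintf("[ACGT]{%d}", s),
                              iupac_to_regex(o$core3)),
               strand = o$strand, spacer_len = s,
               width = nchar(o$core5) + s + nchar(o$core3),
               stringsAsFactors = FALSE)
  }))
}

.empty_hits <- function() {
  data.frame(motif = character(0), start = integer(0), end = integer(0),
             strand = character(0), spacer_len = integer(0),
             stringsAsFactors = FALSE)
}

.sort_hits <- function(hits) {
  hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
}

#' Scan a sequence for a consensus motif
#'
#' Reports every window matching the IUPAC pattern, overlaps included.
#' In `both_strands` mode the reverse orientation is scanned by matching
#' the reverse-complemented pattern on the forward sequence; a window that
#' matches in both orientations is reported once per orientation, except
#' for palindromic patterns, which are reported once on strand `+`.
#' Sequence characters outside A,C,G,T (assembly N's and the like) match
#' no pattern position.
#'
#' @param seq A DNA string (case-insensitive).
#' @param motif A `consensus_motif`.
#' @return data.frame of hits: motif, start (0-based), end (exclusive),
#'   strand (`+`/`-` relative to the stored sequence), spacer_len (NA).
#' @examples
#' scan_consensus("ATCACGTGAT", consensus_motif("Gbox", "CACGTG"))
#' @export
scan_consensus <- function(seq, motif) {
  stopifnot(inherits(motif, "consensus_motif"))
  .scan_one(seq, motif)
}

#' Scan a sequence for a spaced-dyad motif
#'
#' For every spacer length s in the motif's range, matches core5, then s
#' unambiguous A/C/G/T bases, then core3 (an N inside the spacer voids the
#' match). Self-reverse-complementary dyads (everted repeats) are scanned
#' on the forward strand only and each site reported once; other dyads are
#' scanned in both orientations.
#'
#' @param seq A DNA string.
#' @param motif A `dyad_motif`.
#' @return data.frame of hits with spacer_len filled per hit;
#'   end - start = nchar(core5) + spacer_len + nchar(core3).
#' @examples
#' scan_dyad(paste0("TGTC", strrep("A", 11), "GACA"),
#'           dyad_motif("AuxRE_combined", "TGTC", "GACA", 11, 13))
#' @export
scan_dyad <- function(seq, motif) {
  stopifnot(inherits(motif, "dyad_motif"))
  .scan_one(seq, motif)
}

.scan_one <- function(seq, motif) {
  seq <- toupper(seq)
  rx <- .motif_regexes(motif)
  out <- list()
  for (r in seq_len(nrow(rx))) {
    starts <- .regex_starts(seq, rx$regex[r])
    if (length(starts))
      out[[length(out) + 1L]] <- data.frame(
        motif = motif$name, start = starts, end = starts + rx$width[r],
        strand = rx$strand[r], spacer_len = rx$spacer_len[r],
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_hits())
  .sort_hits(do.call(rbind, out))
}

#' Scan a sequence for any motif
#'
#' Dispatches to [scan_consensus()] or [scan_dyad()].
#'
#' @param seq A DNA string.
#' @param motif A `consensus_motif` or `dyad_motif`.
#' @return data.frame of hits.
#' @export
scan_motif <- function(seq, motif) {
  if (inherits(motif, "consensus_motif")) scan_consensus(seq, motif)
  else if (inherits(motif, "dyad_motif")) scan_dyad(seq, motif)
  else stop("not a motif object")
}

#' Scan a promoter set against a catalog and build the presence matrix
#'
#' @param pset A `promoter_set`.
#' @param catalog A `motif_catalog` (default [builtin_catalog()]).
#' @return A list of class `motif_scan` with
#'   \describe{
#'     \item{presence}{logical matrix, genes x motifs: gene has >= 1 hit}
#'     \item{hits}{data.frame of all hits with a gene_id column}
#'   }
#' @export
build_presence <- function(pset, catalog = builtin_catalog()) {
  stopifnot(inherits(pset, "promoter_set"), inherits(catalog, "motif_catalog"))
  genes <- pset$records$gene_id
  seqs <- toupper(pset$records$sequence)
  presence <- matrix(FALSE, nrow = length(genes), ncol = length(catalog),
                     dimnames = list(genes, names(catalog)))
  out <- list()
  for (m in names(catalog)) {
    rx <- .motif_regexes(catalog[[m]])
    for (r in seq_len(nrow(rx))) {
      starts <- .regex_starts_vec(seqs, rx$regex[r])
      n_hit <- lengths(starts)
      presence[, m] <- presence[, m] | n_hit > 0L
      if (any(n_hit > 0L))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = rep(genes, n_hit),
          motif = m, start = unlist(starts),
          end = unlist(starts) + rx$width[r],
          strand = rx$strand[r], spacer_len = rx$spacer_len[r],
          stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    cbind(gene_id = character(0), .empty_hits())
  # stable ordering: promoter order in the set, then position
  hits <- hits[order(match(hits$gene_id, genes), hits$start, hits$end,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(presence = presence, hits = hits), class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat(sprintf("<motif scan> %d promoters x %d motifs, %d hits\n",
              nrow(x$presence), ncol(x$presence), nrow(x$hits)))
  print(colSums(x$presence))
  invisible(x)
}

#' Write a hit table as TSV in promoter-local coordinates
#'
#' Columns: gene_id, motif, start, end, strand, spacer_len, plus
#' tss_offset — the negative distance of the hit start from the 3' end of
#' the stored promoter (the transcription start), the coordinate flavour
#' used when sites are quoted as e.g. "-1538".
#'
#' @param scan A `motif_scan` or a hits data.frame.
#' @param pset The scanned `promoter_set` (for promoter lengths).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(scan, pset, path) {
  hits <- if (inherits(scan, "motif_scan")) scan$hits else scan
  plen <- nchar(pset$records$sequence)[match(hits$gene_id,
                                             pset$records$gene_id)]
  hits$tss_offset <- hits$start - plen
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert promoter-local hits to genomic coordinates
#'
#' Requires provenance on the promoter set. For promoters on the genomic
#' minus strand the local coordinates are mirrored and hit strands flipped.
#'
#' @param scan A `motif_scan` or hits data.frame.
#' @param pset The scanned `promoter_set`, with provenance columns.
#' @return A `GRanges` with mcols gene_id, motif, spacer_len; names are
#'   `gene_id:motif`.
#' @export
hits_to_granges <- function(scan, pset) {
  hits <- if (inherits(scan, "motif_scan")) scan$hits else scan
  rec <- pset$records
  if (!"chrom" %in% names(rec))
    stop("promoter set has no genomic provenance")
  idx <- match(hits$gene_id, rec$gene_id)
  gstart <- ifelse(rec$strand[idx] == "-",
                   rec$end[idx] - hits$end,
                   rec$start[idx] + hits$start)
  gstrand <- ifelse(rec$strand[idx] == "-",
                    chartr("+-", "-+", hits$strand), hits$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = rec$chrom[idx],
    ranges = IRanges::IRanges(start = gstart + 1L,
                              width = hits$end - hits$start),
    strand = gstrand)
  S4Vectors::mcols(gr)$gene_id <- hits$gene_id
  S4Vectors::mcols(gr)$motif <- hits$motif
  S4Vectors::mcols(gr)$spacer_len <- hits$spacer_len
  names(gr) <- paste(hits$gene_id, hits$motif, sep = ":")
  gr
}

#' Write hits as genomic BED6
#'
#' @inheritParams hits_to_granges
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(scan, pset, path) {
  gr <- hits_to_granges(scan, pset)
  S4Vectors::mcols(gr)$name <- names(gr)
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Write / read a presence matrix as TSV (genes as rows, 0/1 cells)
#'
#' @param presence Logical matrix (genes x motifs) or a `motif_scan`.
#' @param path TSV path.
#' @return `path` invisibly for the writer; a logical matrix for the reader.
#' @export
write_presence <- function(presence, path) {
  if (inherits(presence, "motif_scan")) presence <- presence$presence
  df <- data.frame(gene_id = rownames(presence),
                   presence + 0L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence
#' @export
read_presence <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE]) == 1L
  rownames(m) <- df$gene_id
  m
}
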