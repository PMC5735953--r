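# Promoter sets: FASTA/label I/O, strand-aware upstream extraction from a
# genome + GFF3 annotation, and background sampling.

.PROMOTER_CLASSES <- c("class_I", "class_II", "background", "unlabeled")

#' Construct a promoter set
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param sequence Character vector of DNA sequences (stored uppercased).
#' @param class_label Per-gene class, one of `class_I`, `class_II`,
#'   `background`, `unlabeled`. Recycled if scalar.
#' @param provenance Optional data.frame with columns chrom, start, end,
#'   strand (0-based half-open genomic coordinates of each promoter window);
#'   row order matches `gene_id`.
#' @param metadata List of free-form set metadata (upstream length, source,
#'   sampling seed, ...).
#' @return An object of class `promoter_set`: a list with a `records`
#'   data.frame and a `metadata` list.
#' @export
promoter_set <- function(gene_id, sequence, class_label = "unlabeled",
                         provenance = NULL, metadata = list()) {
  stopifnot(length(gene_id) == length(sequence))
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  class_label <- rep_len(as.character(class_label), length(gene_id))
  bad <- setdiff(unique(class_label), .PROMOTER_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  records <- data.frame(gene_id = as.character(gene_id),
                        class_label = class_label,
                        sequence = toupper(sequence),
                        stringsAsFactors = FALSE)
  if (!is.null(provenance)) {
    stopifnot(nrow(provenance) == nrow(records),
              all(c("chrom", "start", "end", "strand") %in% names(provenance)))
    width_ok <- is.na(provenance$start) |
      (provenance$end - provenance$start) == nchar(records$sequence)
    if (!all(width_ok))
      stop("provenance width disagrees with sequence length for: ",
           paste(records$gene_id[!width_ok], collapse = ", "))
    records <- cbind(records, provenance[, c("chrom", "start", "end", "strand")])
  }
  structure(list(records = records, metadata = metadata), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  tab <- table(factor(x$records$class_label, levels = .PROMOTER_CLASSES))
  cat(sprintf("<promoter set> %d promoters (%s)\n", nrow(x$records),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
length.promoter_set <- function(x) nrow(x$records)

#' Read a gene-to-class label table
#'
#' Two-column TSV (gene_id, class) with a header row.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns gene_id, class.
#' @export
read_class_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label table needs two columns: gene_id, class")
  names(df)[1:2] <- c("gene_id", "class")
  bad <- setdiff(unique(df$class), .PROMOTER_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  df[, c("gene_id", "class")]
}

#' Read promoters from FASTA, optionally attaching class labels
#'
#' FASTA ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased on read. Genes without a label get class
#' `unlabeled`; labels for genes absent from the FASTA raise a warning.
#'
#' @param fasta Path to a FASTA file.
#' @param labels Optional label source: a path to a two-column TSV or a
#'   data.frame with columns gene_id, class.
#' @param metadata Optional metadata list stored on the set.
#' @return A `promoter_set`.
#' @export
read_promoters <- function(fasta, labels = NULL, metadata = list()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) stop("empty FASTA: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cls <- rep("unlabeled", length(ids))
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- read_class_labels(labels)
    missing <- setdiff(labels$gene_id, ids)
    if (length(missing))
      warning("labels reference genes absent from FASTA: ",
              paste(missing, collapse = ", "))
    idx <- match(ids, labels$gene_id)
    cls[!is.na(idx)] <- labels$class[idx[!is.na(idx)]]
  }
  metadata$source <- if (is.character(fasta)) fasta else "FASTA"
  promoter_set(ids, as.character(seqs), cls, metadata = metadata)
}

#' Write a promoter set to FASTA (and its labels to TSV)
#'
#' @param pset A `promoter_set`.
#' @param fasta Output FASTA path.
#' @param labels Optional output path for the gene/class TSV.
#' @return `fasta`, invisibly.
#' @export
write_promoters <- function(pset, fasta, labels = NULL) {
  stopifnot(inherits(pset, "promoter_set"))
  seqs <- Biostrings::DNAStringSet(pset$records$sequence)
  names(seqs) <- pset$records$gene_id
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)
  if (!is.null(labels)) {
    utils::write.table(
      data.frame(gene_id = pset$records$gene_id,
                 class = pset$records$class_label),
      labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

# 5'-most annotated start for a gene on its strand, from gene/mRNA features
.gene_anchor <- function(ann, gene_id) {
  meta <- S4Vectors::mcols(ann)
  hit <- rep(FALSE, length(ann))
  for (col in intersect(c("ID", "Name", "gene_id", "locus_tag"), names(meta))) {
    v <- as.character(meta[[col]])
    hit <- hit | (!is.na(v) & v == gene_id)
  }
  if ("type" %in% names(meta))
    hit <- hit & as.character(meta$type) %in% c("gene", "mRNA", "transcript")
  feats <- ann[hit]
  if (!length(feats)) return(NULL)
  strand <- as.character(GenomicRanges::strand(feats))[1L]
  list(
    chrom = as.character(GenomicRanges::seqnames(feats))[1L],
    strand = strand,
    # 0-based TSS coordinate: for "+" the smallest start, for "-" the largest end
    tss = if (strand == "-") max(GenomicRanges::end(feats))
          else min(GenomicRanges::start(feats)) - 1L
  )
}

#' Extract fixed-length upstream promoter regions from a genome
#'
#' For a plus-strand gene whose annotated 5' end is at 0-based position s,
#' the promoter is \[max(0, s - length), s) on the forward strand; for a
#' minus-strand gene ending at e it is \[e, min(chrom_len, e + length))
#' reverse-complemented, so stored sequences always read 5' to 3' towards
#' the transcription start. Windows may overlap neighbouring genes; genes
#' closer than `length` to a chromosome edge yield clipped records (flagged
#' in the metadata). When a gene has several mRNAs the 5'-most start on the
#' gene's strand is used.
#'
#' @param genome A `DNAStringSet` or path to a genome FASTA.
#' @param annotation A `GRanges` (e.g. from [rtracklayer::import]) or path
#'   to a GFF3 file. GFF3's 1-based closed coordinates are converted to the
#'   0-based half-open convention used throughout.
#' @param gene_ids Character vector of genes to extract.
#' @param upstream_length Window length in nt (default 3000).
#' @return A `promoter_set` with provenance; genes not found are dropped
#'   with a warning, zero-length windows are an error.
#' @export
extract_upstream <- function(genome, annotation, gene_ids,
                             upstream_length = 3000L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  upstream_length <- as.integer(upstream_length)
  stopifnot(upstream_length > 0L)
  names(genome) <- sub("\\s.*$", "", names(genome))

  out <- list(); clipped <- character(0); missing <- character(0)
  for (g in gene_ids) {
    anc <- .gene_anchor(annotation, g)
    if (is.null(anc)) { missing <- c(missing, g); next }
    if (!anc$chrom %in% names(genome))
      stop("chromosome '", anc$chrom, "' of gene '", g, "' not in genome")
    clen <- Biostrings::width(genome[anc$chrom])
    if (anc$strand == "-") {
      start0 <- anc$tss
      end0 <- min(clen, anc$tss + upstream_length)
    } else {
      start0 <- max(0L, anc$tss - upstream_length)
      end0 <- anc$tss
    }
    if (end0 <= start0)
      stop("zero-length upstream region for gene '", g, "' at chromosome edge")
    seq <- as.character(Biostrings::subseq(genome[[anc$chrom]],
                                           start = start0 + 1L, end = end0))
    if (anc$strand == "-") seq <- reverse_complement(seq)
    if (end0 - start0 < upstream_length) clipped <- c(clipped, g)
    out[[g]] <- data.frame(gene_id = g, sequence = seq, chrom = anc$chrom,
                           start = start0, end = end0, strand = anc$strand,
                           stringsAsFactors = FALSE)
  }
  if (length(missing))
    warning("genes not found in annotation: ", paste(missing, collapse = ", "))
  if (!length(out)) stop("none of the requested genes were found")
  df <- do.call(rbind, out)
  promoter_set(df$gene_id, df$sequence,
               provenance = df[, c("chrom", "start", "end", "strand")],
               metadata = list(upstream_length = upstream_length,
                               clipped = clipped,
                               n_missing = length(missing)))
}

#' Sample a background promoter set
#'
#' Draws `n` distinct promoters from a universe, excluding the study genes,
#' and relabels them `background`. The same seed always yields the same
#' selection.
#'
#' @param universe A `promoter_set` to sample from.
#' @param n Number of background promoters (default 500).
#' @param exclude Character vector of gene ids to exclude.
#' @param seed Integer RNG seed, recorded in the result's metadata.
#' @return A `promoter_set` of `n` background records.
#' @export
sample_background <- function(universe, n = 500L, exclude = character(0),
                              seed = 1L) {
  stopifnot(inherits(universe, "promoter_set"))
  pool <- universe$records[!universe$records$gene_id %in% exclude, ,
                           drop = FALSE]
  if (nrow(pool) < n)
    stop("universe too small: need ", n, " promoters, only ", nrow(pool),
         " available after exclusions")
  rng <- .with_seed(seed, sample.int(nrow(pool), n))
  sel <- pool[rng, , drop = FALSE]
  prov <- if ("chrom" %in% names(sel))
    sel[, c("chrom", "start", "end", "strand")] else NULL
  promoter_set(sel$gene_id, sel$sequence, "background", provenance = prov,
               metadata = c(universe$metadata,
                            list(background_seed = seed, background_n = n)))
}

# Run code under a local RNG state; the caller's stream is untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
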