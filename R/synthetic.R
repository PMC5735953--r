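# Synthetic promoter studies: i.i.d. background sequence, motif planting
# with full ground truth, and a seeded study generator mirroring the
# 50 / 20 / 500 class design with 3000-nt promoters.

#' Default per-class motif planting rates
#'
#' Planting rates for the synthetic study: the combined AuxRE everted
#' repeat at 0.22 in Class I, absent from Class II and at 0.07 in the
#' background; the BZR1 G-box at 0.20 in Class I only (chance G-box
#' occurrences supply background presence, as in real promoters); and the
#' extended PIF5-like element at 0.56 / 0.10 / 0.112. Planting is the
#' rate of deliberate insertion — chance matches arising from the
#' background composition are additional and are counted as real presence.
#'
#' @return data.frame with columns motif, class, rate.
#' @export
default_plantings <- function() {
  data.frame(
    motif = c("AuxRE_combined", "AuxRE_combined", "AuxRE_combined",
              "BZR1_Gbox", "BZR1_Gbox",
              "ClassI_PIF5like", "ClassI_PIF5like", "ClassI_PIF5like"),
    class = c("class_I", "class_II", "background",
              "class_I", "class_II",
              "class_I", "class_II", "background"),
    rate = c(0.22, 0, 0.07,
             0.20, 0,
             0.56, 0.10, 0.112),
    stringsAsFactors = FALSE)
}

#' Describe a synthetic promoter study
#'
#' @param n_class_I,n_class_II,n_background Class sizes
#'   (defaults 50, 20, 500).
#' @param length Promoter length in nt (default 3000).
#' @param base_composition Named probabilities over A, C, G, T summing to 1.
#'   The default (A = T = 0.33, C = G = 0.17) reflects the AT-rich base
#'   composition of plant intergenic regions.
#' @param plantings data.frame (motif, class, rate): each promoter of the
#'   class independently receives one planted instance with that
#'   probability. Motif names must exist in the catalog used downstream.
#' @param seed Master integer seed; per-promoter streams are derived from
#'   it (see [generate_study()]).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_class_I = 50L, n_class_II = 20L,
                         n_background = 500L, length = 3000L,
                         base_composition = c(A = 0.33, C = 0.17,
                                              G = 0.17, T = 0.33),
                         plantings = default_plantings(), seed = 1L) {
  stopifnot(n_class_I >= 0, n_class_II >= 0, n_background >= 0, length >= 0)
  if (!setequal(names(base_composition), c("A", "C", "G", "T")))
    stop("base_composition must be named over A, C, G, T")
  base_composition <- base_composition[c("A", "C", "G", "T")]
  if (abs(sum(base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1 (got ", sum(base_composition), ")")
  stopifnot(all(c("motif", "class", "rate") %in% names(plantings)),
            all(plantings$rate >= 0 & plantings$rate <= 1))
  structure(list(n_class_I = as.integer(n_class_I),
                 n_class_II = as.integer(n_class_II),
                 n_background = as.integer(n_background),
                 length = as.integer(length),
                 base_composition = base_composition,
                 plantings = plantings,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study design> %d class_I + %d class_II + %d background, %d nt, seed %d\n",
    x$n_class_I, x$n_class_II, x$n_background, x$length, x$seed))
  invisible(x)
}

#' Generate an i.i.d. background sequence
#'
#' Bases are drawn independently from `base_composition` using the current
#' RNG stream (or a locally seeded one when `seed` is given).
#'
#' @param length Sequence length in nt.
#' @param base_composition Named probabilities over A, C, G, T.
#' @param seed Optional seed; when given, the caller's RNG state is
#'   untouched.
#' @return A DNA string of `length` characters.
#' @export
generate_background_sequence <- function(length,
                                         base_composition = c(A = 0.25,
                                                              C = 0.25,
                                                              G = 0.25,
                                                              T = 0.25),
                                         seed = NULL) {
  if (length == 0L) return("")
  draw <- function() intToUtf8(c(65L, 67L, 71L, 84L)[
    sample.int(4L, length, replace = TRUE,
               prob = base_composition[c("A", "C", "G", "T")])])
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

# sample one concrete instance of a motif; returns list(instance, spacer_len)
.sample_instance <- function(motif, base_composition) {
  inst_of <- function(pattern)
    paste(vapply(strsplit(pattern, "", fixed = TRUE)[[1L]], function(ch) {
      b <- .IUPAC_EXPAND[[ch]]
      b[sample.int(length(b), 1L)]
    }, character(1)), collapse = "")
  if (inherits(motif, "consensus_motif"))
    return(list(instance = inst_of(motif$pattern), spacer_len = NA_integer_))
  s <- motif$spacer_min +
    sample.int(motif$spacer_max - motif$spacer_min + 1L, 1L) - 1L
  spacer <- if (s > 0L)
    paste(sample(c("A", "C", "G", "T"), s, replace = TRUE,
                 prob = base_composition[c("A", "C", "G", "T")]),
          collapse = "") else ""
  list(instance = paste0(inst_of(motif$core5), spacer, inst_of(motif$core3)),
       spacer_len = s)
}

#' Plant one motif instance into a sequence
#'
#' Samples a concrete instance (each degenerate position uniform over its
#' admitted bases; dyad spacer length uniform over its range with spacer
#' bases from `base_composition`) and overwrites the sequence at the chosen
#' position, keeping the length fixed. The strand is uniform over +/- for
#' motifs that are not their own reverse complement; a minus-strand
#' planting writes the reverse complement of the instance. Uses the
#' current RNG stream.
#'
#' @param sequence DNA string to plant into.
#' @param motif A `consensus_motif` or `dyad_motif`.
#' @param position Optional 0-based start; uniform over legal starts when
#'   `NULL`.
#' @param strand Optional `"+"` or `"-"`.
#' @param base_composition Composition for dyad spacer bases.
#' @param avoid Optional data.frame of (start, end) 0-based half-open
#'   intervals the planted instance must not overlap (earlier plantings).
#' @return List with `sequence` (modified string) and `entry`, a one-row
#'   data.frame (motif, start, strand, spacer_len).
#' @export
plant_motif <- function(sequence, motif, position = NULL, strand = NULL,
                        base_composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                        avoid = NULL) {
  L <- nchar(sequence)
  smp <- .sample_instance(motif, base_composition)
  w <- nchar(smp$instance)
  if (w > L) stop("motif instance (", w, " nt) longer than sequence (", L, " nt)")
  if (is.null(strand)) {
    strand <- if (is_self_reverse_complementary(motif)) "+"
              else c("+", "-")[sample.int(2L, 1L)]
  }
  if (is.null(position)) {
    starts <- 0:(L - w)
    if (!is.null(avoid) && nrow(avoid)) {
      ok <- rep(TRUE, length(starts))
      for (j in seq_len(nrow(avoid)))
        ok <- ok & (starts + w <= avoid$start[j] | starts >= avoid$end[j])
      starts <- starts[ok]
      if (!length(starts))
        stop("no non-overlapping position left for motif '", motif$name, "'")
    }
    position <- starts[sample.int(length(starts), 1L)]
  }
  if (position < 0L || position + w > L) stop("planting position out of range")
  written <- if (strand == "-") reverse_complement(smp$instance) else smp$instance
  substr(sequence, position + 1L, position + w) <- written
  list(sequence = sequence,
       entry = data.frame(motif = motif$name, start = as.integer(position),
                          strand = strand, spacer_len = smp$spacer_len,
                          stringsAsFactors = FALSE))
}

# counter-based per-promoter stream: promoter i of master seed s
.promoter_stream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 9973) %% 2147483629) + 1L
}

#' Generate a complete synthetic promoter study
#'
#' Each promoter gets its own RNG stream, derived from the master seed by
#' a counter scheme (`(seed + 9973 * index) mod 2147483629 + 1`), so any
#' single promoter can be regenerated in isolation and the whole study is
#' reproducible byte-for-byte. Within a promoter's stream: the background
#' sequence is drawn first, then for each planting row of its class (in
#' row order) a Bernoulli draw at the planting rate decides insertion, and
#' planted instances never overlap one another. At most one instance of a
#' motif is planted per promoter; chance occurrences from the background
#' process are additional real hits.
#'
#' @param design A `study_design`.
#' @param catalog Catalog supplying the planted motifs' definitions
#'   (default [builtin_catalog()]).
#' @return List of class `synthetic_study`: `promoters` (a labeled
#'   `promoter_set`), `truth` (data.frame gene_id, motif, start, strand,
#'   spacer_len of every planted instance), and `design`.
#' @export
generate_study <- function(design, catalog = builtin_catalog()) {
  stopifnot(inherits(design, "study_design"))
  missing <- setdiff(design$plantings$motif, names(catalog))
  if (length(missing))
    stop("plantings reference motifs absent from catalog: ",
         paste(missing, collapse = ", "))
  classes <- rep(c("class_I", "class_II", "background"),
                 c(design$n_class_I, design$n_class_II, design$n_background))
  ids <- c(sprintf("classI_%03d", seq_len(design$n_class_I)),
           sprintf("classII_%03d", seq_len(design$n_class_II)),
           sprintf("bg_%03d", seq_len(design$n_background)))
  seqs <- character(length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- design$plantings[design$plantings$class == classes[i], ,
                             drop = FALSE]
    res <- .with_seed(.promoter_stream_seed(design$seed, i), {
      seq <- generate_background_sequence(design$length,
                                          design$base_composition)
      planted <- list()
      occupied <- data.frame(start = integer(0), end = integer(0))
      for (j in seq_len(nrow(rows))) {
        if (stats::runif(1) < rows$rate[j]) {
          p <- plant_motif(seq, catalog[[rows$motif[j]]],
                           base_composition = design$base_composition,
                           avoid = occupied)
          seq <- p$sequence
          w <- if (is.na(p$entry$spacer_len))
            nchar(catalog[[rows$motif[j]]]$pattern)
          else nchar(catalog[[rows$motif[j]]]$core5) + p$entry$spacer_len +
            nchar(catalog[[rows$motif[j]]]$core3)
          occupied <- rbind(occupied,
                            data.frame(start = p$entry$start,
                                       end = p$entry$start + w))
          planted[[length(planted) + 1L]] <- p$entry
        }
      }
      list(seq = seq, planted = planted)
    })
    seqs[i] <- res$seq
    if (length(res$planted))
      truth[[i]] <- cbind(gene_id = ids[i], do.call(rbind, res$planted))
  }
  truth <- if (any(!vapply(truth, is.null, logical(1))))
    do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  else data.frame(gene_id = character(0), motif = character(0),
                  start = integer(0), strand = character(0),
                  spacer_len = integer(0))
  rownames(truth) <- NULL
  pset <- promoter_set(ids, seqs, classes,
                       metadata = list(upstream_length = design$length,
                                       source = "synthetic",
                                       seed = design$seed))
  structure(list(promoters = pset, truth = truth, design = design),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  print(x$promoters)
  cat(sprintf("  %d planted motif instances (seed %d)\n",
              nrow(x$truth), x$design$seed))
  invisible(x)
}

#' Write a synthetic study bundle to a directory
#'
#' Writes promoters.fasta, labels.tsv, ground_truth.tsv and design.json.
#' Identical designs (including seed) produce byte-identical bundles.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_promoters(study$promoters, file.path(dir, "promoters.fasta"),
                  labels = file.path(dir, "labels.tsv"))
  utils::write.table(study$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  d <- study$design
  jsonlite::write_json(
    list(n_class_I = d$n_class_I, n_class_II = d$n_class_II,
         n_background = d$n_background, length = d$length,
         base_composition = as.list(d$base_composition),
         plantings = d$plantings, seed = d$seed),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic study bundle back
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return List with `promoters` (labeled `promoter_set`), `truth` and
#'   `design` (as a plain list).
#' @export
read_study_bundle <- function(dir) {
  promoters <- read_promoters(file.path(dir, "promoters.fasta"),
                              labels = file.path(dir, "labels.tsv"))
  truth <- utils::read.delim(file.path(dir, "ground_truth.tsv"),
                             stringsAsFactors = FALSE)
  design <- jsonlite::read_json(file.path(dir, "design.json"),
                                simplifyVector = TRUE)
  list(promoters = promoters, truth = truth, design = design)
}
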