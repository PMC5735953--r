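# Independent oracles used across the suite. They share nothing with the
# package's scanning/statistics internals: matching is naive per-position
# set membership, reverse-strand hits are obtained by mirroring matches on
# the reverse-complemented sequence, and hypergeometric probabilities come
# from choose().

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# forward-strand starts (0-based) of an IUPAC pattern, naive enumeration
brute_starts <- function(seq, pattern) {
  sc <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  L <- length(sc); w <- length(pc)
  if (L < w) return(integer(0))
  starts <- 0:(L - w)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(w))
    ok <- ok & sc[starts + j] %in% IUPAC_SETS[[pc[j]]]
  starts[ok]
}

mirror <- function(starts, w, L) sort(L - (starts + w))

# oracle for consensus scanning incl. strand algebra
brute_consensus <- function(seq, pattern, both_strands = TRUE) {
  L <- nchar(seq); w <- nchar(pattern)
  fwd <- brute_starts(seq, pattern)
  hits <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  palindrome <- identical(reverse_complement(pattern), pattern)
  if (both_strands && !palindrome) {
    rc <- mirror(brute_starts(reverse_complement(seq), pattern), w, L)
    hits <- rbind(hits, data.frame(start = rc, strand = rep("-", length(rc))))
  }
  hits$end <- hits$start + w
  hits[order(hits$start, hits$end, hits$strand), c("start", "end", "strand")]
}

# oracle for dyad scanning incl. strand algebra: forward enumeration plus,
# for non-everted dyads, mirrored enumeration on the reverse complement
brute_dyad <- function(seq, core5, core3, smin, smax) {
  L <- nchar(seq)
  fwd <- brute_dyad_fwd(seq, core5, core3, smin, smax)
  fwd$strand <- rep("+", nrow(fwd))
  self_rc <- identical(reverse_complement(core3), core5) &&
    identical(reverse_complement(core5), core3)
  if (!self_rc) {
    r <- brute_dyad_fwd(reverse_complement(seq), core5, core3, smin, smax)
    rev <- data.frame(start = L - r$end, end = L - r$start,
                      spacer_len = r$spacer_len,
                      strand = rep("-", nrow(r)))
    fwd <- rbind(fwd, rev)
  }
  fwd <- fwd[order(fwd$start, fwd$end, fwd$strand),
             c("start", "end", "strand", "spacer_len")]
  rownames(fwd) <- NULL
  fwd
}

# forward-only dyad enumeration (used for the minus strand via mirroring):
# every (start, spacer) pair where core5 matches, the spacer is clean
# A/C/G/T, and core3 matches right after it
brute_dyad_fwd <- function(seq, core5, core3, smin, smax) {
  L <- nchar(seq)
  starts5 <- brute_starts(seq, core5)
  starts3 <- brute_starts(seq, core3)
  out <- list()
  for (sp in smin:smax) {
    w <- nchar(core5) + sp + nchar(core3)
    if (L < w) next
    cand <- intersect(starts5, starts3 - nchar(core5) - sp)
    cand <- cand[cand + w <= L]
    if (sp > 0 && length(cand)) {
      clean <- !vapply(cand, function(st)
        grepl("[^ACGT]", substring(seq, st + nchar(core5) + 1,
                                   st + nchar(core5) + sp)), logical(1))
      cand <- cand[clean]
    }
    if (length(cand))
      out[[length(out) + 1L]] <- data.frame(start = sort(cand),
                                            end = sort(cand) + w,
                                            spacer_len = sp)
  }
  if (!length(out)) data.frame(start = integer(0), end = integer(0),
                               spacer_len = integer(0))
  else do.call(rbind, out)
}

# exact conditional p-value by direct enumeration over the support, with
# probabilities from choose(); independent of dhyper and of the package
enum_fisher <- function(a, b, c, d, alternative = "two.sided") {
  nA <- a + b; nB <- c + d; m <- a + c
  if (nA == 0 || nB == 0 || m == 0 || m == nA + nB) return(1)
  ks <- max(0, m - nB):min(m, nA)
  probs <- choose(nA, ks) * choose(nB, m - ks) / choose(nA + nB, m)
  pobs <- probs[ks == a]
  keep <- switch(alternative,
                 greater = ks >= a,
                 less = ks <= a,
                 two.sided = probs <= pobs * (1 + 1e-7))
  min(1, sum(probs[keep]))
}
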