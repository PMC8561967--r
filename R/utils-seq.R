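#' @import data.table
#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils head tail write.table read.table
#' @importFrom graphics hist
NULL

HINDIII <- "AAGCTT"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors, delegating to
#' [Biostrings::reverseComplement()] so IUPAC codes (including `N`) are
#' handled. Output is uppercase; soft-masking is tracked separately as
#' logical vectors where it matters (see [align_bes()]).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  ## S4 construction dominates for a handful of short strings; do those in
  ## plain R and leave bulk calls to Biostrings' C code
  if (length(x) <= 20L && all(nchar(x) < 1000L)) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
    return(vapply(comp, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
      "", USE.NAMES = FALSE))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Number of mismatching positions between two equal-length strings.
## N mismatches everything (including N), so assembly gaps never align.
seq_mismatches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

## Random DNA of length n with given GC content (vector of single strings).
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## All k-mer start positions' substrings of one sequence (character vector).
seq_kmers <- function(seq, k, stride = 1L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

#' Build an exact k-mer position index of a genome
#'
#' Indexes every k-mer of every sequence (forward strand) with its position,
#' keyed for fast lookup during seed-and-extend alignment and repeat masking.
#'
#' @param genome named character vector of DNA sequences.
#' @param k k-mer length (default 21).
#' @return an object of class `kmer_index`: a list with `positions` (a
#'   `data.table` of `kmer`, `chrom`, `pos` (1-based start), keyed by
#'   `kmer`), `counts` (strand-combined k-mer frequencies), `k` and
#'   `seqlengths`.
#' @export
kmer_index <- function(genome, k = 21L) {
  stopifnot(length(genome) > 0L, !is.null(names(genome)))
  pieces <- lapply(names(genome), function(nm) {
    km <- seq_kmers(genome[[nm]], k)
    if (length(km) == 0L) return(NULL)
    data.table(kmer = km, chrom = nm, pos = seq_along(km))
  })
  idx <- rbindlist(pieces)
  idx <- idx[!grepl("N", kmer, fixed = TRUE)]
  setkey(idx, kmer)
  cnt <- idx[, .(n = .N), by = kmer]
  ## strand-combined frequency, cached once at build time
  n_rc <- cnt[J(revcomp(cnt$kmer))]$n
  n_rc[is.na(n_rc)] <- 0L
  counts <- data.table(kmer = cnt$kmer, n_both = cnt$n + n_rc)
  setkey(counts, kmer)
  structure(list(positions = idx, counts = counts, k = as.integer(k),
                 seqlengths = vapply(genome, nchar, integer(1))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: k = ", x$k, ", ", nrow(x$positions), " positions over ",
      length(x$seqlengths), " sequence(s)\n", sep = "")
  invisible(x)
}

## Strand-combined genome frequency of each k-mer string (0 when absent),
## using the counts table cached on the index (keyed join).
kmer_freq <- function(genome_index, kmers) {
  n <- genome_index$counts[J(kmers)]$n_both
  n[is.na(n)] <- 0L
  n
}

## Find all HindIII (AAGCTT) site start positions in one sequence (1-based).
hindiii_sites <- function(seq) {
  m <- gregexpr(HINDIII, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

## Mean Phred quality per read from Sanger-encoded quality strings.
## Fast path for constant-width sets (one charToRaw over the paste).
mean_phred <- function(qual) {
  if (length(qual) == 0L) return(numeric(0))
  w <- nchar(qual)
  if (length(unique(w)) == 1L) {
    m <- matrix(as.integer(charToRaw(paste(qual, collapse = ""))) - 33L,
                nrow = w[1])
    colMeans(m)
  } else {
    vapply(qual, function(q) mean(as.integer(charToRaw(q)) - 33L), 0)
  }
}
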