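#' Soft-mask repetitive bases of an end sequence
#'
#' A base is lowercased (masked) when every genome k-mer covering it occurs
#' more than `max_freq` times in the genome (counting both strands); masked
#' bases take no part in alignment seeding and are excluded from both the
#' numerator and the denominator of identity and query coverage. Idempotent.
#'
#' @param seq a query sequence.
#' @param genome_index a [kmer_index()] of the genome.
#' @param max_freq maximum genome frequency of a k-mer before it counts as
#'   repetitive (default 1).
#' @return the sequence with repetitive bases in lowercase.
#' @export
mask_repeats <- function(seq, genome_index, max_freq = 1L) {
  k <- genome_index$k
  up <- toupper(seq)
  n <- nchar(up)
  if (n < k) return(up)
  km <- seq_kmers(up, k)
  high <- kmer_freq(genome_index, km) > max_freq
  ## a base stays unmasked iff some covering k-mer is low-frequency
  keep <- logical(n)
  for (s in which(!high)) keep[s:(s + k - 1L)] <- TRUE
  ch <- strsplit(up, "")[[1]]
  ch[!keep] <- tolower(ch[!keep])
  paste(ch, collapse = "")
}

## Align one oriented query against the forward genome via tiled exact
## seeds and ungapped full-query placement on each candidate diagonal.
## `qc` is the uppercase character vector, `usable` marks unmasked ACGT
## positions (both already oriented).
seed_hits_one_strand <- function(qc, usable, genome, genome_index,
                                 min_identity, min_qcov, seed_k) {
  n <- length(qc)
  total_unmasked <- sum(usable)
  if (total_unmasked < 50L || n < seed_k) return(NULL)
  starts <- unique(c(seq.int(1L, n - seed_k + 1L, by = seed_k),
                     n - seed_k + 1L))
  ## a seed must be fully unmasked ACGT
  ok <- vapply(starts, function(s) all(usable[s:(s + seed_k - 1L)]), TRUE)
  starts <- starts[ok]
  if (length(starts) == 0L) return(NULL)
  seeds <- vapply(starts, function(s)
    paste(qc[s:(s + seed_k - 1L)], collapse = ""), "")
  sm <- genome_index$positions[J(seeds), nomatch = NULL]
  if (nrow(sm) == 0L) return(NULL)
  sm[, qpos := starts[match(kmer, seeds)]]
  cand <- unique(sm[, .(chrom, diag = pos - qpos)])
  seqlens <- genome_index$seqlengths
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    chrom <- cand$chrom[i]; dg <- cand$diag[i]
    glen <- seqlens[[chrom]]
    qa <- max(1L, 1L - dg); qb <- min(n, glen - dg)
    if (qb - qa + 1L < seed_k) next
    gseg <- strsplit(substr(genome[[chrom]], qa + dg, qb + dg), "")[[1]]
    qp <- qa:qb
    cmp <- usable[qp]
    n_cmp <- sum(cmp)
    if (n_cmp == 0L) next
    matches <- sum(qc[qp][cmp] == gseg[cmp])
    identity <- matches / n_cmp
    q_cov <- n_cmp / total_unmasked
    if (identity >= min_identity && q_cov >= min_qcov)
      hits[[length(hits) + 1L]] <- data.table(
        chrom = chrom, qs_start = qa - 1L, qs_end = qb,
        t_start = qa + dg - 1L, t_end = qb + dg,
        identity = identity, q_cov = q_cov, score = matches)
  }
  if (length(hits) == 0L) NULL else rbindlist(hits)
}

#' Align an end sequence to the genome (seed-and-extend)
#'
#' Tiled exact seeds of length `seed_k` on both strands locate candidate
#' diagonals; the full query is then compared ungapped on each diagonal and
#' a hit is reported only when identity and query coverage both meet the
#' strict contract (default 0.99/0.99 — the blastn-style `perc_identity` /
#' `qcov_hsp_perc` thresholds expressed as fractions). Soft-masked
#' (lowercase) query bases neither seed nor count toward identity or
#' coverage. Any qualifying ungapped alignment with fewer mismatches than
#' the number of tiled seeds is guaranteed to be found.
#'
#' @param query a query sequence (lowercase = masked); at least 50 unmasked
#'   bp.
#' @param genome named character vector of genome sequences.
#' @param genome_index a [kmer_index()] of `genome` with `k = seed_k`.
#' @param min_identity,min_qcov reporting thresholds (default 0.99).
#' @param seed_k seed length (default 21).
#' @return a `data.table` of hits sorted by decreasing score: `chrom`,
#'   `q_start`, `q_end` (0-based half-open on the query as given),
#'   `t_start`, `t_end`, `strand`, `identity`, `q_cov`, `score`.
#' @export
align_bes <- function(query, genome, genome_index, min_identity = 0.99,
                      min_qcov = 0.99, seed_k = 21L) {
  stopifnot(genome_index$k == seed_k)
  ch <- strsplit(query, "")[[1]]
  usable <- ch %in% c("A", "C", "G", "T")
  qc <- toupper(ch)
  n <- length(qc)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  qc_rc <- rev(unname(comp[match(qc, names(comp))]))
  qc_rc[is.na(qc_rc)] <- "N"
  res <- list()
  plus <- seed_hits_one_strand(qc, usable, genome, genome_index,
                               min_identity, min_qcov, seed_k)
  if (!is.null(plus)) {
    plus[, `:=`(strand = "+", q_start = qs_start, q_end = qs_end)]
    res$p <- plus
  }
  minus <- seed_hits_one_strand(qc_rc, rev(usable), genome, genome_index,
                                min_identity, min_qcov, seed_k)
  if (!is.null(minus)) {
    minus[, `:=`(strand = "-", q_start = n - qs_end, q_end = n - qs_start)]
    res$m <- minus
  }
  if (length(res) == 0L)
    return(data.table(chrom = character(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0), strand = character(0),
                      identity = numeric(0), q_cov = numeric(0),
                      score = numeric(0)))
  out <- rbindlist(res)[, .(chrom, q_start, q_end, t_start, t_end, strand,
                            identity, q_cov, score)]
  unique(out)[order(-score, chrom, t_start)]
}

#' Cull dominated hits and classify a query
#'
#' A hit is removed when its query interval is overlapped by at least
#' `culling_overlap` of its length by a strictly higher-scoring hit (the
#' role of blastn's `culling_limit = 1`). The query is then classed by the
#' number of surviving hits: `NONE`, `SINGLE` or `MULTI`.
#'
#' @param hits an [align_bes()] table.
#' @param culling_overlap dominating overlap fraction (default 0.5).
#' @return list with `class` and `hits` (the survivors).
#' @export
cull_and_classify <- function(hits, culling_overlap = 0.5) {
  if (nrow(hits) == 0L) return(list(class = "NONE", hits = hits))
  hits <- hits[order(-score)]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (j == i || hits$score[j] <= hits$score[i]) next
      ov <- min(hits$q_end[i], hits$q_end[j]) -
        max(hits$q_start[i], hits$q_start[j])
      if (ov >= culling_overlap * (hits$q_end[i] - hits$q_start[i])) {
        keep[i] <- FALSE; break
      }
    }
  }
  surv <- hits[keep]
  list(class = c("NONE", "SINGLE", "MULTI")[pmin(nrow(surv), 2L) + 1L],
       hits = surv)
}
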