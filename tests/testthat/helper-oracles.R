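## Independent oracles, deliberately written against the definitions rather
## than sharing code with the package.

## N50 by exhaustive definition: the largest L present in the list such
## that the pieces of length >= L sum to at least half the total.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  stop("unreachable")
}

## Brute-force ungapped sliding aligner: every diagonal of every chromosome
## on both strands, same identity / query-coverage thresholds. Returns the
## same columns as align_bes().
oracle_align <- function(query, genome, min_identity = 0.99,
                         min_qcov = 0.99) {
  n <- nchar(query)
  one_strand <- function(qs, strand) {
    qch <- strsplit(qs, "")[[1]]
    hits <- list()
    for (nm in names(genome)) {
      gch <- strsplit(genome[[nm]], "")[[1]]
      glen <- length(gch)
      ## matches per diagonal dg (t = q + dg), accumulated per query column
      m <- integer(glen + n - 1L)       # slot = dg - (1 - n) + 1 = dg + n
      for (j in seq_len(n)) {
        eq <- gch == qch[j] & qch[j] != "N"
        idx <- seq_len(glen) - j + n
        m[idx] <- m[idx] + eq
      }
      for (slot in which(m > 0L)) {
        dg <- slot - n
        qa <- max(1L, 1L - dg); qb <- min(n, glen - dg)
        n_cmp <- qb - qa + 1L
        if (n_cmp < 1L) next
        identity <- m[slot] / n_cmp
        q_cov <- n_cmp / n
        if (identity >= min_identity && q_cov >= min_qcov) {
          qs_start <- qa - 1L; qs_end <- qb
          hits[[length(hits) + 1L]] <- data.table(
            chrom = nm,
            q_start = if (strand == "+") qs_start else n - qs_end,
            q_end = if (strand == "+") qs_end else n - qs_start,
            t_start = qa + dg - 1L, t_end = qb + dg, strand = strand,
            identity = identity, q_cov = q_cov,
            score = m[slot])
        }
      }
    }
    if (length(hits)) rbindlist(hits) else NULL
  }
  out <- rbind(one_strand(query, "+"),
               one_strand(capss::revcomp(query), "-"))
  if (is.null(out))
    return(data.table(chrom = character(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0), strand = character(0),
                      identity = numeric(0), q_cov = numeric(0),
                      score = integer(0)))
  out[order(-score, chrom, t_start)]
}

## canonical form for hit-set comparison (score types differ)
hitset <- function(h) {
  d <- as.data.table(h)[, .(chrom, q_start, q_end, t_start, t_end, strand,
                            identity = round(identity, 10),
                            q_cov = round(q_cov, 10))]
  setkey(d, chrom, strand, t_start, t_end)
  d[]
}
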