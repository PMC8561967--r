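#' Demultiplex pooled reads by their index barcode
#'
#' Each mate-1 read starts with the 7-bp (configurable) pool barcode; a pair
#' is assigned to the unique pool whose barcode matches within
#' `max_mismatch`, otherwise it lands in the unassigned bin. The barcode and
#' its quality are stripped from assigned reads. The partition is exhaustive
#' and disjoint: per-pool counts plus unassigned always sum to the input.
#'
#' @param pairs read-pair `data.table` (`id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`); extra columns are carried through.
#' @param index_table a [make_index_table()] table.
#' @param max_mismatch allowed barcode mismatches (default 0, exact match;
#'   the index table must have pairwise Hamming distance > 2 * max_mismatch).
#' @return list with `pools` (named list of per-pool `data.table`s, names
#'   `"ROW:<i>"`/`"COL:<i>"`), `unassigned`, and `counts` (pool, raw count).
#' @export
demultiplex <- function(pairs, index_table, max_mismatch = 0L) {
  bl <- nchar(index_table$barcode[1L])
  stopifnot(all(nchar(index_table$barcode) == bl))
  if (max_mismatch > 0L) {
    bm <- do.call(rbind, strsplit(index_table$barcode, ""))
    dmin <- min(vapply(seq_len(nrow(bm) - 1L), function(i)
      min(rowSums(bm[-seq_len(i), , drop = FALSE] !=
                    matrix(bm[i, ], nrow(bm) - i, bl, byrow = TRUE))),
      0))
    if (dmin <= 2L * max_mismatch)
      stop("index table pairwise Hamming distance must exceed 2*max_mismatch")
  }
  obs <- substr(pairs$seq1, 1L, bl)
  hit <- match(obs, index_table$barcode)
  if (max_mismatch > 0L && anyNA(hit)) {
    miss <- which(is.na(hit))
    om <- do.call(rbind, strsplit(obs[miss], ""))
    for (b in seq_len(nrow(index_table))) {
      bchars <- strsplit(index_table$barcode[b], "")[[1]]
      d <- rowSums(om != matrix(bchars, nrow(om), bl, byrow = TRUE))
      hit[miss[d <= max_mismatch]] <- b
    }
  }
  key <- ifelse(is.na(hit), NA,
                paste0(index_table$pool_axis[hit], ":",
                       index_table$pool_index[hit]))
  assigned <- !is.na(key)
  pools <- split(pairs[assigned], key[assigned])
  pools <- lapply(pools, function(p) {
    p <- copy(p)
    p[, `:=`(seq1 = substring(seq1, bl + 1L),
             qual1 = substring(qual1, bl + 1L))]
    p
  })
  counts <- data.table(pool = names(pools),
                       raw = vapply(pools, nrow, 0L))
  list(pools = pools, unassigned = pairs[!assigned], counts = counts)
}

#' Quality/length filter for read pairs
#'
#' A minimal pair-atomic filter: a pair is dropped whole when either mate has
#' mean Phred quality below `min_mean_q` or length below `min_len`; no orphan
#' mates are ever produced.
#'
#' @param pairs read-pair `data.table`.
#' @param min_mean_q minimum mean Phred quality per mate (default 20).
#' @param min_len minimum mate length (default 50).
#' @return the filtered `data.table`.
#' @export
quality_trim <- function(pairs, min_mean_q = 20, min_len = 50L) {
  if (nrow(pairs) == 0L) return(pairs)
  keep <- nchar(pairs$seq1) >= min_len & nchar(pairs$seq2) >= min_len &
    mean_phred(pairs$qual1) >= min_mean_q &
    mean_phred(pairs$qual2) >= min_mean_q
  pairs[keep]
}

#' Build the host k-mer set used by the contamination screen
#'
#' K-mers are taken from both strands of the host genome, so read k-mers can
#' be matched directly regardless of read orientation (equivalent to
#' canonical-form matching).
#'
#' @param host_genome named character vector of host sequences.
#' @param k k-mer length (odd, 15-31; default 21).
#' @return a `data.table` of distinct k-mers keyed for joining.
#' @export
host_kmer_set <- function(host_genome, k = 21L) {
  stopifnot(k %% 2L == 1L, k >= 15L, k <= 31L, length(host_genome) > 0L)
  km <- unlist(lapply(host_genome, function(s)
    c(seq_kmers(s, k), seq_kmers(revcomp(s), k))), use.names = FALSE)
  out <- data.table(kmer = unique(km))
  setkey(out, kmer)
  setattr(out, "k", as.integer(k))
  out
}

#' Screen out host-derived read pairs
#'
#' A mate is called host when at least `hit_fraction` of its sampled k-mers
#' occur in the host k-mer set; a pair is removed when either mate is host.
#' K-mers are sampled at a fixed stride along each read, which preserves the
#' containment contract at a fraction of the lookup cost. Idempotent.
#'
#' @param pairs read-pair `data.table`.
#' @param host_kmers a [host_kmer_set()] table.
#' @param hit_fraction fraction of k-mers that must be host (default 0.5).
#' @param stride sampling stride along the read (default 10).
#' @return list with `kept` (valid pairs) and `removed` counts.
#' @export
filter_host <- function(pairs, host_kmers, hit_fraction = 0.5, stride = 10L) {
  if (nrow(pairs) == 0L) return(list(kept = pairs, removed = 0L))
  k <- attr(host_kmers, "k")
  is_host_mate <- function(seqs) {
    n <- nchar(seqs)
    starts <- lapply(n, function(len)
      if (len < k) integer(0) else seq.int(1L, len - k + 1L, by = stride))
    idx <- rep(seq_along(seqs), lengths(starts))
    st <- unlist(starts, use.names = FALSE)
    if (length(st) == 0L) return(rep(FALSE, length(seqs)))
    km <- substring(seqs[idx], st, st + k - 1L)
    present <- !is.na(host_kmers[J(km), which = TRUE, mult = "first"])
    frac <- vapply(split(present, idx), mean, 0)
    out <- rep(FALSE, length(seqs))
    out[as.integer(names(frac))] <- frac >= hit_fraction
    out
  }
  host <- is_host_mate(pairs$seq1) | is_host_mate(pairs$seq2)
  list(kept = pairs[!host], removed = sum(host))
}

#' Run the full preprocessing accounting for one pool
#'
#' Mirrors the three accounting stages of a pooled-library run: raw pairs,
#' pairs after quality control, and valid pairs after host filtering.
#'
#' @param pairs raw read pairs of one pool.
#' @param host_kmers a [host_kmer_set()] (or NULL to skip host filtering).
#' @param min_mean_q,min_len see [quality_trim()].
#' @param hit_fraction see [filter_host()].
#' @return list with `reads` (valid pairs) and `counts`
#'   (`raw`, `after_qc`, `valid`).
#' @export
preprocess_pool <- function(pairs, host_kmers = NULL, min_mean_q = 20,
                            min_len = 50L, hit_fraction = 0.5) {
  raw <- nrow(pairs)
  qc <- quality_trim(pairs, min_mean_q, min_len)
  valid <- if (is.null(host_kmers)) qc
  else filter_host(qc, host_kmers, hit_fraction)$kept
  list(reads = valid,
       counts = data.table(raw = raw, after_qc = nrow(qc),
                           valid = nrow(valid)))
}
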