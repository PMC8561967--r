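## Junction patterns: the terminal `anchor` bases of the vector flank
## immediately followed by the HindIII site, oriented vector -> insert.
junction_patterns <- function(vector, anchor) {
  nl <- nchar(vector$left_flank)
  list(
    FORWARD = paste0(substr(vector$left_flank, nl - anchor + 1L, nl), HINDIII),
    REVERSE = paste0(revcomp(substr(vector$right_flank, 1L, anchor)), HINDIII))
}

#' Find reads spanning a vector-insert junction
#'
#' A read qualifies for the FORWARD end when it contains at least
#' `min_vector_anchor` terminal bases of the left vector flank immediately
#' followed by AAGCTT (in either orientation), and symmetrically for the
#' REVERSE end with the right flank. The insert-side sequence from that
#' AAGCTT onward is reported in vector-to-insert orientation, and each
#' junction read's mate is carried along for consensus extension.
#'
#' @param pairs read-pair `data.table` of one pool (after preprocessing).
#' @param vector a [make_vector()] model.
#' @param min_vector_anchor minimum vector bases anchoring the junction
#'   (default 20).
#' @return a `data.table` with columns `end`, `insert_seq` (starts AAGCTT),
#'   `vector_len`, `mate_seq`, `read_id`.
#' @export
find_junction_reads <- function(pairs, vector, min_vector_anchor = 20L) {
  pat <- junction_patterns(vector, min_vector_anchor)
  out <- list()
  for (mate in 1:2) {
    seqs <- pairs[[paste0("seq", mate)]]
    mates <- pairs[[paste0("seq", c(2L, 1L)[mate])]]
    for (ori in c("fwd", "rc")) {
      s <- if (ori == "fwd") seqs else revcomp(seqs)
      for (end in names(pat)) {
        p <- regexpr(pat[[end]], s, fixed = TRUE)
        hitat <- which(p > 0L)
        if (length(hitat) == 0L) next
        pos <- as.integer(p[hitat])
        out[[length(out) + 1L]] <- data.table(
          end = end,
          insert_seq = substring(s[hitat], pos + min_vector_anchor),
          vector_len = pos + min_vector_anchor - 1L,
          mate_seq = mates[hitat],
          read_id = paste0(pairs$id[hitat], "/", mate))
      }
    }
  }
  if (length(out) == 0L)
    return(data.table(end = character(0), insert_seq = character(0),
                      vector_len = integer(0), mate_seq = character(0),
                      read_id = character(0)))
  jr <- rbindlist(out)
  ## a read matching in both orientations would be chimeric; keep first
  jr[!duplicated(read_id)]
}

## Majority-vote consensus over sequences placed at 1-based offsets.
## Truncated at the first column covered by fewer than min_depth sequences.
offset_consensus <- function(seqs, offsets, min_depth) {
  ends <- offsets + nchar(seqs) - 1L
  maxlen <- max(ends)
  cov <- integer(maxlen)
  tally <- list(A = integer(maxlen), C = integer(maxlen),
                G = integer(maxlen), T = integer(maxlen))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    at <- seq.int(offsets[i], ends[i])
    for (b in names(tally)) {
      hit <- at[ch == b]
      tally[[b]][hit] <- tally[[b]][hit] + 1L
    }
    cov[at] <- cov[at] + 1L
  }
  ok <- cov >= min_depth
  stop_at <- if (all(ok)) maxlen else min(which(!ok)) - 1L
  if (stop_at < 1L) return("")
  m <- cbind(tally$A, tally$C, tally$G, tally$T)[seq_len(stop_at), ,
                                                drop = FALSE]
  paste(c("A", "C", "G", "T")[max.col(m, ties.method = "first")],
        collapse = "")
}

#' Cluster junction reads and build per-cluster consensus sequences
#'
#' Junction reads of one pool and end all share the AAGCTT anchor at
#' position 1, so clustering reduces to anchored prefix comparison: reads
#' agreeing at >= `min_identity` over >= `min_overlap` bp join a cluster
#' (greedy, longest first). Clusters of size >= `min_depth` yield a
#' majority-vote consensus extended only as far as `min_depth` reads cover
#' each column; mates are then placed by exact 30-bp overlap with the
#' growing consensus and extend it under the same depth rule.
#'
#' @param junction_reads a [find_junction_reads()] table (one pool).
#' @param min_overlap minimum anchored overlap to cluster (default 50).
#' @param min_identity minimum agreement over the overlap (default 0.95).
#' @param min_depth minimum reads per cluster / per consensus column
#'   (default 3).
#' @return a `data.table` with `end`, `seq` (consensus, starts AAGCTT),
#'   `support`, plus attribute `dropped` (clusters below `min_depth`).
#' @export
cluster_and_consensus <- function(junction_reads, min_overlap = 50L,
                                  min_identity = 0.95, min_depth = 3L) {
  res <- list(); dropped <- 0L
  for (e in unique(junction_reads$end)) {
    jr <- junction_reads[end == e & nchar(insert_seq) >= min_overlap]
    if (nrow(jr) == 0L) next
    jr <- jr[order(-nchar(insert_seq))]
    reps <- character(0); members <- list()
    for (i in seq_len(nrow(jr))) {
      s <- jr$insert_seq[i]; placed <- FALSE
      for (cl in seq_along(reps)) {
        ov <- min(nchar(s), nchar(reps[cl]))
        if (ov < min_overlap) next
        if (seq_mismatches(substr(s, 1L, ov), substr(reps[cl], 1L, ov)) <=
            (1 - min_identity) * ov) {
          members[[cl]] <- c(members[[cl]], i); placed <- TRUE; break
        }
      }
      if (!placed) { reps <- c(reps, s); members[[length(reps)]] <- i }
    }
    for (cl in seq_along(reps)) {
      idx <- members[[cl]]
      if (length(idx) < min_depth) { dropped <- dropped + 1L; next }
      seqs <- jr$insert_seq[idx]; offs <- rep(1L, length(idx))
      cons <- offset_consensus(seqs, offs, min_depth)
      ## mate extension: place mates by exact 30-bp overlap, re-vote
      for (m in unique(jr$mate_seq[idx])) {
        for (ori in c(m, revcomp(m))) {
          p <- regexpr(substr(ori, 1L, 30L), cons, fixed = TRUE)
          if (p > 0L) {
            ov <- min(nchar(cons) - p + 1L, nchar(ori))
            if (seq_mismatches(substr(cons, p, p + ov - 1L),
                               substr(ori, 1L, ov)) <= 0.05 * ov) {
              seqs <- c(seqs, ori); offs <- c(offs, as.integer(p))
            }
            break
          }
        }
      }
      cons <- offset_consensus(seqs, offs, min_depth)
      if (nchar(cons) >= 6L)
        res[[length(res) + 1L]] <- data.table(end = e, seq = cons,
                                              support = length(idx))
    }
  }
  out <- if (length(res) == 0L)
    data.table(end = character(0), seq = character(0), support = integer(0))
  else rbindlist(res)
  setattr(out, "dropped", dropped)
  out
}

#' Trim vector sequence off a junction consensus
#'
#' Removes every vector base so the returned end sequence starts exactly at
#' AAGCTT, reorienting vector-to-insert if the junction is on the other
#' strand. Idempotent on sequences already starting with AAGCTT.
#'
#' @param seq a consensus (or contig) sequence containing the junction.
#' @param vector a [make_vector()] model.
#' @param min_vector_anchor vector bases required to recognise the junction.
#' @return list with `seq` (starting AAGCTT, or `NA` when no junction is
#'   recognisable) and `end` ("FORWARD"/"REVERSE"/`NA`).
#' @export
trim_to_bes <- function(seq, vector, min_vector_anchor = 20L) {
  pat <- junction_patterns(vector, min_vector_anchor)
  for (s in c(seq, revcomp(seq))) {
    for (e in names(pat)) {
      p <- regexpr(pat[[e]], s, fixed = TRUE)
      if (p > 0L)
        return(list(seq = substring(s, p + min_vector_anchor), end = e))
    }
  }
  if (startsWith(seq, HINDIII)) return(list(seq = seq, end = NA_character_))
  list(seq = NA_character_, end = NA_character_)
}

#' Extract short end sequences from one pool's reads
#'
#' The first extraction pathway: junction reads are found, clustered and
#' collapsed to consensus per end; every emitted sequence starts with AAGCTT.
#'
#' @param pairs preprocessed read pairs of one pool.
#' @param vector a [make_vector()] model.
#' @param min_vector_anchor,min_overlap,min_identity,min_depth stage
#'   thresholds (see [find_junction_reads()] and [cluster_and_consensus()]).
#' @return a `data.table` with `end`, `seq`, `support`.
#' @export
extract_short_bes <- function(pairs, vector, min_vector_anchor = 20L,
                              min_overlap = 50L, min_identity = 0.95,
                              min_depth = 3L) {
  jr <- find_junction_reads(pairs, vector, min_vector_anchor)
  bes <- cluster_and_consensus(jr, min_overlap, min_identity, min_depth)
  stopifnot(all(substr(bes$seq, 1L, 6L) == HINDIII))
  bes
}
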