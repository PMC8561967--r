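#' Greedy overlap assembly of one pool's reads
#'
#' A deliberately small overlap-merge assembler adequate for simulated /
#' desk-scale pools (production-scale contigs can instead be supplied as an
#' external contig FASTA to [extract_long_bes()]). Reads are sorted
#' lexicographically (determinism), then contigs are grown read by read:
#' a read extends the contig when its prefix overlaps the contig suffix by
#' at least `min_overlap` bp at `min_identity` or better (either strand).
#' The appended extension is the majority vote of all candidate reads; when
#' a second extension variant has support of two or more reads the branch is
#' treated as genuinely ambiguous and the contig stops there.
#'
#' @param reads character vector of read sequences (both mates, quality
#'   filtered).
#' @param min_overlap minimum suffix-prefix overlap (default 40).
#' @param min_identity minimum identity over the overlap (default 0.98).
#' @param anchor_len exact seed length anchoring candidate overlaps
#'   (default 25; must be <= `min_overlap`).
#' @return a `data.table` of contigs: `contig_id`, `seq`, `n_reads`.
#' @export
assemble_pool <- function(reads, min_overlap = 40L, min_identity = 0.98,
                          anchor_len = 25L) {
  stopifnot(anchor_len <= min_overlap)
  reads <- sort(reads[nchar(reads) >= min_overlap], method = "radix")
  if (length(reads) == 0L)
    return(data.table(contig_id = character(0), seq = character(0),
                      n_reads = integer(0)))
  n_reads_total <- length(reads)
  reads_rc <- revcomp(reads)
  rlen <- nchar(reads)
  rl_max <- max(rlen)
  ## hashed prefix-anchor index: anchor -> signed read ids (<0 = revcomp)
  ids <- c(seq_len(n_reads_total), -seq_len(n_reads_total))
  anchors <- c(substr(reads, 1L, anchor_len),
               substr(reads_rc, 1L, anchor_len))
  idx <- list2env(split(ids, anchors), hash = TRUE)
  used <- logical(n_reads_total)
  max_mm <- function(o) floor((1 - min_identity) * o)

  ## A read that anchors, matches the contig well and then diverges hard at
  ## one coordinate witnesses a breakpoint: the contig has crossed a
  ## boundary that read knows to be a junction (vector), a gap, or a repeat
  ## edge. Two independent witnesses at the same coordinate truncate the
  ## contig there. This is what makes greedy extension safe against
  ## chimeras joining clones that overlap on the genome: the majority vote
  ## at the extension frontier can cross the far junction before most
  ## junction reads are anchored, but those reads then arrive as witnesses.
  extend_right <- function(contig) {
    scanned_to <- 0L   # window positions <= scanned_to already evaluated
    breaks <- integer(0)
    repeat {
      L <- nchar(contig)
      p_lo <- max(1L, L - rl_max + 1L, scanned_to + 1L)
      p_hi <- L - min_overlap + 1L
      if (p_hi < p_lo) return(contig)
      p <- seq.int(p_lo, p_hi)
      scanned_to <- p_hi
      cand <- mget(substring(contig, p, p + anchor_len - 1L),
                   envir = idx, ifnotfound = list(NULL))
      npos <- lengths(cand)
      if (sum(npos) == 0L) next   # window exhausted -> p_lo > p_hi next turn
      pos_v <- rep(p, npos)
      id_v <- unlist(cand, use.names = FALSE)
      exts <- character(0)
      for (h in order(pos_v, abs(id_v))) {
        ri <- abs(id_v[h])
        r <- if (id_v[h] < 0L) reads_rc[ri] else reads[ri]
        o <- L - pos_v[h] + 1L
        if (o > rlen[ri]) o <- rlen[ri]   # read contained in contig
        a <- substr(contig, pos_v[h], pos_v[h] + o - 1L)
        b <- substr(r, 1L, o)
        if (a != b && seq_mismatches(a, b) > max_mm(o)) {
          ## anchored but strongly divergent: a breakpoint witness even if
          ## the read was already consumed by another contig
          ca <- strsplit(a, "", fixed = TRUE)[[1]]
          cb <- strsplit(b, "", fixed = TRUE)[[1]]
          mm <- which(ca != cb | ca == "N" | cb == "N")
          d <- mm[1L]
          if (d > anchor_len &&
              length(mm) / (o - d + 1L) >= 0.3)
            breaks <- c(breaks, pos_v[h] + d - 2L)  # last agreeing base
          next
        }
        if (used[ri]) next
        used[ri] <<- TRUE
        n_used <<- n_used + 1L
        e <- substring(r, o + 1L)
        if (nchar(e) > 0L) exts <- c(exts, e)
      }
      ## two witnesses within 3 bp confirm a breakpoint: truncate and stop
      if (length(breaks) >= 2L) {
        b <- sort(breaks)
        conf <- b[which(diff(b) <= 3L)]
        if (length(conf) > 0L) return(substr(contig, 1L, conf[1L]))
      }
      if (length(exts) == 0L) next
      ## majority-vote extension with a branch test; fast path when all
      ## proposed extensions agree (are prefixes of the longest)
      longest <- exts[which.max(nchar(exts))]
      if (all(substr(longest, 1L, nchar(exts)) == exts)) {
        contig <- paste0(contig, longest)
        next
      }
      bases <- c("A", "C", "G", "T", "N")
      maxe <- max(nchar(exts))
      add <- character(0)
      for (j in seq_len(maxe)) {
        col <- substr(exts[nchar(exts) >= j], j, j)
        tab <- tabulate(match(col, bases), nbins = 5L)
        top2 <- sort(tab, decreasing = TRUE)[1:2]
        if (top2[2L] >= 2L) break  # genuine branch
        add <- c(add, bases[which.max(tab)])
      }
      if (length(add) == 0L) return(contig)
      contig <- paste0(contig, paste(add, collapse = ""))
    }
  }

  contigs <- list()
  for (s in seq_len(n_reads_total)) {
    if (used[s]) next
    used[s] <- TRUE
    n_used <- 1L
    contig <- extend_right(reads[s])
    contig <- revcomp(extend_right(revcomp(contig)))
    contigs[[length(contigs) + 1L]] <- data.table(seq = contig,
                                                  n_reads = n_used)
  }
  out <- rbindlist(contigs)
  out[, contig_id := sprintf("ctg%04d", seq_len(.N))]
  setcolorder(out, c("contig_id", "seq", "n_reads"))
  out[]
}

#' Extract long end sequences from pool contigs
#'
#' The second extraction pathway: contigs containing at least
#' `min_vector_anchor` bases of a vector flank adjacent to AAGCTT (either
#' strand) are trimmed so the retained sequence starts at AAGCTT in
#' vector-to-insert orientation; vector sequence at the far end of a contig
#' that spans the whole insert is trimmed off as well, so the retained
#' sequence also ends at the insert's terminal AAGCTT. A contig carrying
#' junctions for both flanks yields one long BES per end and is flagged.
#'
#' @param contigs a contig `data.table` (`contig_id`, `seq`) from
#'   [assemble_pool()] or an external assembler.
#' @param vector a [make_vector()] model.
#' @param min_vector_anchor vector bases required to recognise the junction.
#' @return a `data.table` with `end`, `seq` (starts AAGCTT), `contig_id`,
#'   `both_ends`.
#' @export
extract_long_bes <- function(contigs, vector, min_vector_anchor = 20L) {
  pat <- junction_patterns(vector, min_vector_anchor)
  nl <- nchar(vector$left_flank)
  ## trailing (far-end) junctions in vector-to-insert orientation:
  ## insert-terminal AAGCTT followed by vector sequence
  far <- c(paste0(HINDIII, substr(vector$right_flank, 1L,
                                  min_vector_anchor)),
           paste0(HINDIII, revcomp(substr(vector$left_flank,
                                          nl - min_vector_anchor + 1L, nl))))
  trim_far <- function(s) {
    for (fp in far) {
      p <- regexpr(fp, s, fixed = TRUE)
      if (p > 0L) s <- substr(s, 1L, p + 5L)   # keep the terminal AAGCTT
    }
    s
  }
  out <- list()
  for (i in seq_len(nrow(contigs))) {
    found <- list()
    for (ori in c(contigs$seq[i], revcomp(contigs$seq[i]))) {
      for (e in names(pat)) {
        p <- regexpr(pat[[e]], ori, fixed = TRUE)
        if (p > 0L && is.null(found[[e]]))
          found[[e]] <- trim_far(substring(ori, p + min_vector_anchor))
      }
    }
    for (e in names(found))
      out[[length(out) + 1L]] <- data.table(
        end = e, seq = found[[e]], contig_id = contigs$contig_id[i],
        both_ends = length(found) == 2L)
  }
  res <- if (length(out) == 0L)
    data.table(end = character(0), seq = character(0),
               contig_id = character(0), both_ends = logical(0))
  else rbindlist(out)
  stopifnot(all(substr(res$seq, 1L, 6L) == HINDIII))
  res
}

#' N50 of a length distribution
#'
#' The largest length L such that the pieces of length at least L sum to at
#' least half the total.
#'
#' @param lengths positive numeric vector.
#' @return the N50 value.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50 of an empty length list is undefined")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[min(which(cumsum(s) >= sum(s) / 2))]
}
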