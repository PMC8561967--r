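## Anchored comparison of two end sequences (both start at AAGCTT):
## identity over the common prefix (the shorter sequence's full length).
anchored_share <- function(a, b, min_identity, min_cov) {
  ov <- min(nchar(a), nchar(b))
  if (ov < 30L || ov < min_cov * min(nchar(a), nchar(b))) return(FALSE)
  seq_mismatches(substr(a, 1L, ov), substr(b, 1L, ov)) <=
    (1 - min_identity) * ov
}

#' Match end sequences between row pools and column pools
#'
#' The heart of CAPSS deconvolution: an end sequence recovered in a row pool
#' and one recovered in a column pool "share" when they agree at
#' `min_identity` or better over at least `min_cov` of the shorter sequence,
#' anchored at their common AAGCTT start; every share is assigned to the
#' well at the intersection of the two pools. Forward and reverse ends (and
#' short- and long-source sequences) are matched in fully independent flows.
#'
#' @param row_bes,col_bes `data.table`s of per-pool end sequences with
#'   columns `pool_index`, `end`, `seq` (plus anything else, carried along);
#'   `row_bes` from ROW pools, `col_bes` from COL pools.
#' @param layout a [build_layout()] object.
#' @param min_identity minimum anchored identity (default 0.99).
#' @param min_cov minimum fraction of the shorter sequence compared
#'   (default 0.9).
#' @return a `data.table` of matches: `end`, `row_pool`, `col_pool`,
#'   `row_bes_id`, `col_bes_id`, `plate`, `row`, `col`, `seq` (the longer of
#'   the two shared sequences).
#' @export
match_pools <- function(row_bes, col_bes, layout,
                        min_identity = 0.99, min_cov = 0.9) {
  empty <- data.table(end = character(0), row_pool = integer(0),
                      col_pool = integer(0), row_bes_id = character(0),
                      col_bes_id = character(0), plate = integer(0),
                      row = integer(0), col = integer(0), seq = character(0))
  if (nrow(row_bes) == 0L || nrow(col_bes) == 0L) return(empty)
  rb <- copy(row_bes)[, bes_id := sprintf("R%d.%s.%d", pool_index, end,
                                          seq_len(.N))]
  cb <- copy(col_bes)[, bes_id := sprintf("C%d.%s.%d", pool_index, end,
                                          seq_len(.N))]
  out <- list()
  for (e in intersect(unique(rb$end), unique(cb$end))) {
    r <- rb[end == e]; c_ <- cb[end == e]
    ## candidate pairs share the exact 24-mer right after the AAGCTT anchor
    ## (cheap prescreen); each candidate is then verified in full
    cand <- merge(r[, .(ri = .I, pk = substr(seq, 7L, 30L))],
                  c_[, .(ci = .I, pk = substr(seq, 7L, 30L))],
                  by = "pk", allow.cartesian = TRUE)
    if (nrow(r) * nrow(c_) <= 250000L) {
      allp <- CJ(ri = seq_len(nrow(r)), ci = seq_len(nrow(c_)))
      cand <- unique(rbind(cand[, .(ri, ci)], allp))
    }
    for (i in seq_len(nrow(cand))) {
      a <- r$seq[cand$ri[i]]; b <- c_$seq[cand$ci[i]]
      if (anchored_share(a, b, min_identity, min_cov)) {
        w <- well_at_intersection(layout, r$pool_index[cand$ri[i]],
                                  c_$pool_index[cand$ci[i]])
        out[[length(out) + 1L]] <- data.table(
          end = e, row_pool = r$pool_index[cand$ri[i]],
          col_pool = c_$pool_index[cand$ci[i]],
          row_bes_id = r$bes_id[cand$ri[i]],
          col_bes_id = c_$bes_id[cand$ci[i]],
          plate = w$plate, row = w$row, col = w$col,
          seq = if (nchar(a) >= nchar(b)) a else b)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  rbindlist(out)
}

#' Resolve multi-well ambiguities in pool matches
#'
#' A single end sequence present in several row pools and several column
#' pools implies several candidate intersection wells and cannot be trusted:
#' under the default `STRICT` policy any pool-side sequence implying more
#' than `max_wells_per_bes` distinct wells (for one end) is dropped entirely
#' and counted as filtered — the conservative behaviour for stacks of more
#' than two overlapping clones. A well that still accumulates more than one
#' distinct sequence for an end keeps them all, marked `AMBIGUOUS` (the
#' situation genome mapping later arbitrates). `KEEP_ALL` skips the
#' filtering and retains every match for downstream rescue.
#'
#' @param matches a [match_pools()] table.
#' @param policy `"STRICT"` (default) or `"KEEP_ALL"`.
#' @param max_wells_per_bes maximum wells one pool-side sequence may imply
#'   (default 1).
#' @return a `data.table` of well assignments: `plate`, `row`, `col`, `end`,
#'   `seq`, `status` (`UNIQUE`/`AMBIGUOUS`), `row_pool`, `col_pool`; with
#'   attribute `filtered` (number of dropped pool-side sequences).
#' @export
resolve_conflicts <- function(matches, policy = c("STRICT", "KEEP_ALL"),
                              max_wells_per_bes = 1L) {
  policy <- match.arg(policy)
  m <- copy(matches)
  filtered <- 0L
  if (nrow(m) > 0L && policy == "STRICT") {
    m[, wk := paste(plate, row, col, sep = ":")]
    bad_r <- m[, .(nw = uniqueN(wk)), by = .(end, row_bes_id)][
      nw > max_wells_per_bes]
    bad_c <- m[, .(nw = uniqueN(wk)), by = .(end, col_bes_id)][
      nw > max_wells_per_bes]
    filtered <- nrow(bad_r) + nrow(bad_c)
    m <- m[!bad_r, on = c("end", "row_bes_id")][
      !bad_c, on = c("end", "col_bes_id")]
    m[, wk := NULL]
  }
  if (nrow(m) == 0L) {
    out <- data.table(plate = integer(0), row = integer(0), col = integer(0),
                      end = character(0), seq = character(0),
                      status = character(0), row_pool = integer(0),
                      col_pool = integer(0))
    setattr(out, "filtered", filtered)
    return(out)
  }
  out <- m[, .(plate, row, col, end, seq, row_pool, col_pool)]
  ## collapse duplicate matches of the same sequence into one assignment
  out <- unique(out, by = c("plate", "row", "col", "end", "seq"))
  out[, status := if (.N > 1L) "AMBIGUOUS" else "UNIQUE",
      by = .(plate, row, col, end)]
  setattr(out, "filtered", filtered)
  out[]
}

#' Well-assignment summary counts
#'
#' The Table 2-shaped upper block: wells with a forward end sequence, with a
#' reverse one, with both (paired), with exactly one, and with none.
#'
#' @param assignments a [resolve_conflicts()] table.
#' @param layout a [build_layout()] object.
#' @return a one-row `data.table` of counts.
#' @export
assignment_stats <- function(assignments, layout) {
  if (nrow(assignments) == 0L)
    return(data.table(wells_with_forward = 0L, wells_with_reverse = 0L,
                      wells_with_pair = 0L, wells_with_single = 0L,
                      wells_empty = layout$n_wells))
  per_well <- assignments[, .(has_f = any(end == "FORWARD"),
                              has_r = any(end == "REVERSE")),
                          by = .(plate, row, col)]
  data.table(
    wells_with_forward = sum(per_well$has_f),
    wells_with_reverse = sum(per_well$has_r),
    wells_with_pair = sum(per_well$has_f & per_well$has_r),
    wells_with_single = sum(xor(per_well$has_f, per_well$has_r)),
    wells_empty = layout$n_wells - nrow(per_well))
}
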