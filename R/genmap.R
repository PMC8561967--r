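#' Align every well-assigned end sequence and classify its placement
#'
#' Each assigned end sequence is (optionally) repeat-masked, aligned under
#' the strict identity/coverage contract and culled; sequences with exactly
#' one surviving hit carry a usable placement, multi-hit and unaligned
#' sequences do not.
#'
#' @param assignments a [resolve_conflicts()] table (`plate`, `row`, `col`,
#'   `end`, `seq`, ...).
#' @param genome named character vector of genome sequences.
#' @param genome_index a [kmer_index()] of `genome`.
#' @param min_identity,min_qcov,seed_k see [align_bes()].
#' @param culling_overlap see [cull_and_classify()].
#' @param mask repeat-mask queries before alignment (default TRUE).
#' @param max_freq see [mask_repeats()].
#' @return a `data.table` of per-sequence placements: assignment columns
#'   plus `class` and, for `SINGLE`-class rows, `chrom`, `t_start`, `t_end`,
#'   `strand`.
#' @export
map_wells <- function(assignments, genome, genome_index,
                      min_identity = 0.99, min_qcov = 0.99, seed_k = 21L,
                      culling_overlap = 0.5, mask = TRUE, max_freq = 1L) {
  if (nrow(assignments) == 0L)
    return(data.table(plate = integer(0), row = integer(0),
                      col = integer(0), end = character(0),
                      seq = character(0), class = character(0),
                      chrom = character(0), t_start = integer(0),
                      t_end = integer(0), strand = character(0)))
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    a <- assignments[i]
    q <- if (mask) mask_repeats(a$seq, genome_index, max_freq) else a$seq
    cc <- cull_and_classify(
      align_bes(q, genome, genome_index, min_identity, min_qcov, seed_k),
      culling_overlap)
    out <- data.table(plate = a$plate, row = a$row, col = a$col,
                      end = a$end, seq = a$seq, class = cc$class,
                      chrom = NA_character_, t_start = NA_integer_,
                      t_end = NA_integer_, strand = NA_character_)
    if (cc$class == "SINGLE")
      out[, `:=`(chrom = cc$hits$chrom, t_start = cc$hits$t_start,
                 t_end = cc$hits$t_end, strand = cc$hits$strand)]
    out
  })
  rbindlist(rows)
}

## Paired/single placement of one well from at most one placed sequence per
## end. Returns list(mapped = 0/1/2-row data.table, reasons = character).
pair_one <- function(well, f, r, max_span, fallback) {
  mk <- function(evidence, chrom, start, end, orient, fr, rr) data.table(
    plate = well$plate, row = well$row, col = well$col,
    chrom = chrom, start = start, end = end, evidence = evidence,
    span = end - start, orient = orient,
    fwd_chrom = if (is.null(fr)) NA_character_ else fr$chrom,
    fwd_start = if (is.null(fr)) NA_integer_ else fr$t_start,
    fwd_end = if (is.null(fr)) NA_integer_ else fr$t_end,
    fwd_strand = if (is.null(fr)) NA_character_ else fr$strand,
    fwd_seq = if (is.null(fr)) NA_character_ else fr$seq,
    rev_chrom = if (is.null(rr)) NA_character_ else rr$chrom,
    rev_start = if (is.null(rr)) NA_integer_ else rr$t_start,
    rev_end = if (is.null(rr)) NA_integer_ else rr$t_end,
    rev_strand = if (is.null(rr)) NA_character_ else rr$strand,
    rev_seq = if (is.null(rr)) NA_character_ else rr$seq)
  if (!is.null(f) && !is.null(r)) {
    inward <- !is.na(f$chrom) && f$chrom == r$chrom &&
      ((f$strand == "+" && r$strand == "-" && r$t_start >= f$t_start) ||
         (f$strand == "-" && r$strand == "+" && r$t_start <= f$t_start))
    if (inward) {
      start <- min(f$t_start, r$t_start); end <- max(f$t_end, r$t_end)
      if (end - start < max_span)
        return(list(mapped = mk("PAIRED", f$chrom, start, end, f$strand,
                                f, r),
                    reasons = character(0)))
      reason <- "SPAN_EXCEEDED"
    } else {
      reason <- if (f$chrom != r$chrom) "CHROM_CONFLICT" else
        "STRAND_CONFLICT"
    }
    if (fallback == "single")
      return(list(mapped = rbind(
        mk("SINGLE_FORWARD", f$chrom, f$t_start, f$t_end, f$strand, f, NULL),
        mk("SINGLE_REVERSE", r$chrom, r$t_start, r$t_end, r$strand, NULL, r)),
        reasons = reason))
    return(list(mapped = NULL, reasons = reason))
  }
  if (!is.null(f))
    return(list(mapped = mk("SINGLE_FORWARD", f$chrom, f$t_start, f$t_end,
                            f$strand, f, NULL), reasons = character(0)))
  if (!is.null(r))
    return(list(mapped = mk("SINGLE_REVERSE", r$chrom, r$t_start, r$t_end,
                            r$strand, NULL, r), reasons = character(0)))
  list(mapped = NULL, reasons = "NO_PLACEMENT")
}

#' Place clones from per-end placements (paired where possible)
#'
#' A clone is recorded as `PAIRED` when its forward and reverse end
#' placements land on the same chromosome, on opposite strands facing
#' inward, with an interval span under `max_span` (default 250 kb); the
#' clone interval is the hull of the two end placements. Wells where
#' pairing fails, or where only one end is placed, fall back to single-end
#' records (`SINGLE_FORWARD` / `SINGLE_REVERSE`) when `fallback = "single"`.
#' Wells carrying more than one placed candidate sequence for an end are
#' left unresolved for cross-source arbitration by [integrate_sources()].
#'
#' @param placements a [map_wells()] table.
#' @param max_span maximum paired interval length in bp (default 250000).
#' @param fallback `"single"` (default) or `"discard"` for wells whose pair
#'   test fails.
#' @return list with `mapped` (clone table), `unresolved` (placements of
#'   wells with ambiguous ends) and `discarded` (well + reason, including
#'   `MULTI_HIT` sequences).
#' @export
pair_and_place <- function(placements, max_span = 250000L,
                           fallback = c("single", "discard")) {
  fallback <- match.arg(fallback)
  mapped <- list(); unresolved <- list(); disc <- list()
  wells <- unique(placements[, .(plate, row, col)])
  for (i in seq_len(nrow(wells))) {
    w <- wells[i]
    p <- placements[w, on = c("plate", "row", "col")]
    for (m in which(p$class == "MULTI"))
      disc[[length(disc) + 1L]] <- data.table(w, end = p$end[m],
                                              reason = "MULTI_HIT")
    fwd <- p[end == "FORWARD" & class == "SINGLE"]
    rev_ <- p[end == "REVERSE" & class == "SINGLE"]
    if (nrow(fwd) > 1L || nrow(rev_) > 1L) {
      unresolved[[length(unresolved) + 1L]] <- p
      next
    }
    res <- pair_one(w, if (nrow(fwd)) fwd else NULL,
                    if (nrow(rev_)) rev_ else NULL, max_span, fallback)
    if (!is.null(res$mapped)) mapped[[length(mapped) + 1L]] <- res$mapped
    for (rs in res$reasons)
      disc[[length(disc) + 1L]] <- data.table(w, end = NA_character_,
                                              reason = rs)
  }
  bind <- function(x, proto) if (length(x)) rbindlist(x) else proto
  empty_mapped <- data.table(
    plate = integer(0), row = integer(0), col = integer(0),
    chrom = character(0), start = integer(0), end = integer(0),
    evidence = character(0), span = integer(0), orient = character(0),
    fwd_chrom = character(0), fwd_start = integer(0), fwd_end = integer(0),
    fwd_strand = character(0), fwd_seq = character(0),
    rev_chrom = character(0), rev_start = integer(0), rev_end = integer(0),
    rev_strand = character(0), rev_seq = character(0))
  list(
    mapped = bind(mapped, empty_mapped),
    unresolved = bind(unresolved, placements[0]),
    discarded = bind(disc, data.table(plate = integer(0), row = integer(0),
                                      col = integer(0), end = character(0),
                                      reason = character(0))))
}

## anchored sequence agreement used during integration
ends_agree <- function(a, b, min_identity) {
  if (is.na(a) || is.na(b)) return(FALSE)
  ov <- min(nchar(a), nchar(b))
  ov >= 30L &&
    seq_mismatches(substr(a, 1L, ov), substr(b, 1L, ov)) <=
    (1 - min_identity) * ov
}

#' Integrate short- and long-source clone placements
#'
#' Wells present in only one source are taken as-is. Wells placed by both
#' keep the long-source coordinates when the two placements agree (same
#' chromosome, boundaries within 1 kb); on disagreement an end whose short
#' and long sequences themselves agree decides in favour of the long
#' placement, and irreconcilable wells are dropped and counted. Wells left
#' unresolved in one source (several placed candidates for an end) are
#' rescued by the other source: the candidate whose sequence matches the
#' other source's sequence for that end is kept and the rest discarded —
#' the consistency rule motivated by wells that collect two long forward
#' sequences of which only one matches the independent evidence.
#'
#' @param short_res,long_res results of [pair_and_place()] for the
#'   short-source and long-source assignments.
#' @param max_span,fallback see [pair_and_place()] (used when re-pairing
#'   rescued candidates).
#' @param min_agreement_identity sequence-agreement threshold (default
#'   0.99).
#' @return list with `mapped` (final clone table with a `source` column:
#'   `SHORT`, `LONG` or `INTEGRATED`) and `dropped` (wells with reasons).
#' @export
integrate_sources <- function(short_res, long_res, max_span = 250000L,
                              fallback = "single",
                              min_agreement_identity = 0.99) {
  sm <- copy(short_res$mapped); lm <- copy(long_res$mapped)
  sm[, wk := well_key(.SD)]; lm[, wk := well_key(.SD)]
  su <- copy(short_res$unresolved); lu <- copy(long_res$unresolved)
  if (nrow(su)) su[, wk := well_key(.SD)]
  if (nrow(lu)) lu[, wk := well_key(.SD)]
  out <- list(); dropped <- list()
  add <- function(rows, src) {
    rows <- copy(rows); rows[, source := src]
    out[[length(out) + 1L]] <<- rows
  }
  drop_well <- function(wk, reason)
    dropped[[length(dropped) + 1L]] <<- data.table(wk = wk, reason = reason)

  handled <- character(0)
  ## wells placed in both sources
  for (w in intersect(unique(sm$wk), unique(lm$wk))) {
    s <- sm[wk == w]; l <- lm[wk == w]
    s1 <- s[1]; l1 <- l[1]
    agree <- !is.na(s1$chrom) && !is.na(l1$chrom) &&
      s1$chrom == l1$chrom && abs(s1$start - l1$start) <= 1000L &&
      abs(s1$end - l1$end) <= 1000L
    if (agree) add(l[, !"wk"], "INTEGRATED")
    else if (ends_agree(s1$fwd_seq, l1$fwd_seq, min_agreement_identity) ||
             ends_agree(s1$rev_seq, l1$rev_seq, min_agreement_identity))
      add(l[, !"wk"], "INTEGRATED")
    else drop_well(w, "INTEGRATION_CONFLICT")
    handled <- c(handled, w)
  }
  ## single-source wells
  for (w in setdiff(unique(lm$wk), handled)) {
    add(lm[wk == w][, !"wk"], "LONG"); handled <- c(handled, w)
  }
  for (w in setdiff(unique(sm$wk), handled)) {
    ## rescue from long candidates if the well is unresolved there
    s <- sm[wk == w]
    resc <- NULL
    if (nrow(lu) && w %in% lu$wk) {
      cands <- lu[wk == w]
      keep <- vapply(seq_len(nrow(cands)), function(i) {
        ref <- if (cands$end[i] == "FORWARD") s$fwd_seq[1] else s$rev_seq[1]
        ends_agree(cands$seq[i], ref, min_agreement_identity)
      }, TRUE)
      ok <- cands[keep & class == "SINGLE"]
      if (nrow(ok) > 0L && !anyDuplicated(ok$end)) {
        f <- ok[end == "FORWARD"]; r <- ok[end == "REVERSE"]
        resc <- pair_one(unique(cands[, .(plate, row, col)]),
                         if (nrow(f)) f else NULL,
                         if (nrow(r)) r else NULL, max_span, fallback)$mapped
      }
    }
    if (!is.null(resc)) add(resc, "INTEGRATED") else add(s[, !"wk"], "SHORT")
    handled <- c(handled, w)
  }
  ## wells unresolved in both or unresolved-only: dropped
  for (w in setdiff(unique(c(su$wk, lu$wk)), handled))
    drop_well(w, "UNRESOLVED_AMBIGUITY")

  mapped <- if (length(out)) rbindlist(out, fill = TRUE) else
    cbind(short_res$mapped[0], data.table(source = character(0)))
  list(mapped = mapped,
       dropped = if (length(dropped)) rbindlist(dropped) else
         data.table(wk = character(0), reason = character(0)))
}

#' Screen well-assigned end sequences against organelle genomes
#'
#' Wells with at least one end sequence placing on an organelle genome
#' under the strict contract are called organelle clones; wells whose
#' sequences also place on the nuclear genome are flagged `NUCLEAR_ALSO`
#' (integration/transfer segments), and wells with both ends hitting are
#' reported as paired evidence.
#'
#' @param assignments a [resolve_conflicts()] table.
#' @param organelle_genomes named character vector of organelle sequences.
#' @param organelle_types optional named character vector mapping organelle
#'   sequence names to `"CHLOROPLAST"`/`"MITOCHONDRION"`; guessed from the
#'   names by default.
#' @param genome,genome_index optional nuclear genome (enables the
#'   `NUCLEAR_ALSO` flag).
#' @param min_identity,min_qcov,seed_k see [align_bes()].
#' @return a `data.table`: `plate`, `row`, `col`, `target`, `paired`,
#'   `nuclear_also`.
#' @export
screen_organelle <- function(assignments, organelle_genomes,
                             organelle_types = NULL, genome = NULL,
                             genome_index = NULL, min_identity = 0.99,
                             min_qcov = 0.99, seed_k = 21L) {
  if (is.null(organelle_types))
    organelle_types <- setNames(
      ifelse(grepl("mito", names(organelle_genomes), ignore.case = TRUE),
             "MITOCHONDRION", "CHLOROPLAST"),
      names(organelle_genomes))
  org_idx <- kmer_index(organelle_genomes, seed_k)
  calls <- list()
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i]
    hits <- align_bes(a$seq, organelle_genomes, org_idx, min_identity,
                      min_qcov, seed_k)
    if (nrow(hits) == 0L) next
    nuc <- FALSE
    if (!is.null(genome_index))
      nuc <- nrow(align_bes(a$seq, genome, genome_index, min_identity,
                            min_qcov, seed_k)) > 0L
    calls[[length(calls) + 1L]] <- data.table(
      plate = a$plate, row = a$row, col = a$col, end = a$end,
      target = unname(organelle_types[hits$chrom[1]]), nuclear_also = nuc)
  }
  if (length(calls) == 0L)
    return(data.table(plate = integer(0), row = integer(0), col = integer(0),
                      target = character(0), paired = logical(0),
                      nuclear_also = logical(0)))
  d <- rbindlist(calls)
  d[, .(target = if (any(nuclear_also)) "NUCLEAR_ALSO" else target[1],
        paired = any(end == "FORWARD") && any(end == "REVERSE"),
        nuclear_also = any(nuclear_also)),
    by = .(plate, row, col)]
}

#' Write placed clones as sorted GFF3
#'
#' Each `PAIRED` clone becomes exactly three feature lines (a `BAC_clone`
#' parent spanning the interval plus one `BAC_end` child per end placement)
#' and each single-end clone exactly two; coordinates are converted to the
#' 1-based inclusive GFF3 convention — the only 1-based surface of the
#' package. Lines are sorted by chromosome then start, parents before their
#' children.
#'
#' @param mapped a clone table from [pair_and_place()] or
#'   [integrate_sources()].
#' @param path output file.
#' @param layout a [build_layout()] object (for well labels).
#' @return the path, invisibly.
#' @export
write_gff3 <- function(mapped, path, layout) {
  fmt <- function(chrom, start0, end0, type, strand, attrs)
    paste(chrom, "capss", type, start0 + 1L, end0, ".",
          ifelse(is.na(strand), ".", strand), ".", attrs, sep = "\t")
  blocks <- lapply(seq_len(nrow(mapped)), function(i) {
    m <- mapped[i]
    lab <- well_label(layout, m)
    id <- paste0("bac_", lab, "_", tolower(m$evidence))
    lines <- fmt(m$chrom, m$start, m$end, "BAC_clone", m$orient,
                 paste0("ID=", id, ";Name=", lab, ";evidence=", m$evidence))
    if (m$evidence == "PAIRED") {
      lines <- c(lines,
        fmt(m$fwd_chrom, m$fwd_start, m$fwd_end, "BAC_end", m$fwd_strand,
            paste0("ID=", id, ".F;Parent=", id, ";bes_end=FORWARD")),
        fmt(m$rev_chrom, m$rev_start, m$rev_end, "BAC_end", m$rev_strand,
            paste0("ID=", id, ".R;Parent=", id, ";bes_end=REVERSE")))
    } else if (m$evidence == "SINGLE_FORWARD") {
      lines <- c(lines,
        fmt(m$fwd_chrom, m$fwd_start, m$fwd_end, "BAC_end", m$fwd_strand,
            paste0("ID=", id, ".F;Parent=", id, ";bes_end=FORWARD")))
    } else {
      lines <- c(lines,
        fmt(m$rev_chrom, m$rev_start, m$rev_end, "BAC_end", m$rev_strand,
            paste0("ID=", id, ".R;Parent=", id, ";bes_end=REVERSE")))
    }
    list(chrom = m$chrom, start = m$start, lines = lines)
  })
  ord <- order(vapply(blocks, `[[`, "", "chrom"),
               vapply(blocks, `[[`, 0L, "start"))
  writeLines(c("##gff-version 3",
               unlist(lapply(blocks[ord], `[[`, "lines"))), path)
  invisible(path)
}
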