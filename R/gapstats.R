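#' Find assembly gaps (maximal N-runs)
#'
#' @param genome named character vector of sequences, or a
#'   [simulate_genome()] object.
#' @param min_run minimum run length to report (default 1: any N counts).
#' @return a `data.frame` of gaps: `chrom`, `start`, `end` (0-based
#'   half-open), sorted by chromosome then start.
#' @export
find_gaps <- function(genome, min_run = 1L) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$sequences
  out <- lapply(names(genome), function(nm) {
    m <- gregexpr("N+", genome[[nm]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_run
    if (!any(keep)) return(NULL)
    data.frame(chrom = nm, start = as.integer(m[keep]) - 1L,
               end = as.integer(m[keep]) - 1L + len[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Gaps strictly spanned by paired-placed clones
#'
#' A gap counts as covered only when some `PAIRED` clone interval strictly
#' contains it (`clone.start < gap.start` and `clone.end > gap.end`):
#' single-end placements bound the clone on one side only and are never
#' used. Adding clones can only grow the covered set.
#'
#' @param mapped a clone table (only `evidence == "PAIRED"` rows are used).
#' @param gaps a [find_gaps()] table.
#' @return the covered subset of `gaps`.
#' @export
covered_gaps <- function(mapped, gaps) {
  paired <- mapped[mapped$evidence == "PAIRED", , drop = FALSE]
  if (nrow(paired) == 0L || nrow(gaps) == 0L)
    return(gaps[0, , drop = FALSE])
  cov <- vapply(seq_len(nrow(gaps)), function(i) {
    g <- gaps[i, ]
    any(paired$chrom == g$chrom & paired$start < g$start &
          paired$end > g$end)
  }, TRUE)
  gaps[cov, , drop = FALSE]
}

#' Per-chromosome clone coverage report
#'
#' For every chromosome: its length, number of gaps, number of paired
#' clones, the length of the union of paired clone intervals (interval
#' merge, order independent) and the number of gaps strictly covered, with
#' a totals row.
#'
#' @param mapped a clone table.
#' @param genome named character vector of sequences, or a
#'   [simulate_genome()] object.
#' @param min_run see [find_gaps()].
#' @return a `data.table`, one row per chromosome plus `TOTAL`.
#' @export
chromosome_coverage <- function(mapped, genome, min_run = 1L) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$sequences
  gaps <- find_gaps(genome, min_run)
  paired <- as.data.table(mapped)[evidence == "PAIRED"]
  cov_gaps <- covered_gaps(mapped, gaps)
  per <- rbindlist(lapply(names(genome), function(nm) {
    cl <- paired[chrom == nm]
    union_len <- if (nrow(cl) == 0L) 0L else
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = cl$start + 1L, end = cl$end))))
    data.table(chrom = nm, length = nchar(genome[[nm]]),
               n_gaps = sum(gaps$chrom == nm), n_clones = nrow(cl),
               covered_length = union_len,
               n_gaps_covered = sum(cov_gaps$chrom == nm))
  }))
  totals <- per[, .(chrom = "TOTAL", length = sum(length),
                    n_gaps = sum(n_gaps), n_clones = sum(n_clones),
                    covered_length = sum(covered_length),
                    n_gaps_covered = sum(n_gaps_covered))]
  rbind(per, totals)
}

#' Insert-size statistics of paired-placed clones
#'
#' @param mapped a clone table; spans of `PAIRED` rows are used.
#' @param bin_width histogram bin width in bp (default 10000).
#' @return list with `n`, `mean`, `sd` and `histogram`
#'   (a [hist()] object, not plotted).
#' @export
insert_stats <- function(mapped, bin_width = 10000L) {
  spans <- mapped$span[mapped$evidence == "PAIRED"]
  if (length(spans) == 0L) stop("no paired-placed clones")
  breaks <- seq(0, (max(spans) %/% bin_width + 1L) * bin_width,
                by = bin_width)
  list(n = length(spans), mean = mean(spans), sd = sd(spans),
       histogram = graphics::hist(spans, breaks = breaks, plot = FALSE))
}

#' Effective clone size used for pool depth accounting
#'
#' The sequenced molecule of a BAC clone is its insert plus the vector
#' backbone, so per-pool depth is computed against insert estimate + vector
#' length (the classic 132 kb + 7 kb = 139 kb accounting).
#'
#' @param insert_kb insert-size estimate in kb (default 132, the
#'   gel-based library estimate).
#' @param vector_kb vector length in kb (default 7).
#' @return effective clone size in kb.
#' @export
effective_clone_size_kb <- function(insert_kb = 132, vector_kb = 7) {
  insert_kb + vector_kb
}

#' Per-pool sequencing depth from read accounting
#'
#' @param valid_pairs number of valid read pairs in the pool.
#' @param read_len read length (bp).
#' @param members clones in the pool.
#' @param clone_size_kb effective clone size in kb
#'   (see [effective_clone_size_kb()]).
#' @return depth (fold coverage) per pool.
#' @export
pool_depth <- function(valid_pairs, read_len, members, clone_size_kb) {
  (valid_pairs * 2 * read_len) / (members * clone_size_kb * 1000)
}
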