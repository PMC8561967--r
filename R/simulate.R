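#' Simulate a reference genome with known gaps and repeats
#'
#' Builds a random nuclear genome with planted assembly gaps (runs of `N`)
#' and, optionally, a family of near-identical dispersed repeat copies (to
#' exercise multi-hit classification downstream). The returned truth tables
#' record every planted feature, and the gap truth is by construction exactly
#' the set of maximal N-runs of the sequences.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_gaps total number of gaps planted across the genome.
#' @param gap_length length of each N-run (bp).
#' @param repeat_unit_length length of the repeat unit (0 = no repeats).
#' @param repeat_copies number of dispersed copies of the unit.
#' @param gc GC content of the random background (default 0.46).
#' @param seed RNG seed; fixed seed gives identical sequences.
#' @return an object of class `synthetic_genome`: list with `sequences`
#'   (named character vector), `gap_truth` and `repeat_truth` (data.frames
#'   with `chrom`, `start`, `end`, 0-based half-open).
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_length = 5e5, n_gaps = 3L,
                            gap_length = 500L, repeat_unit_length = 0L,
                            repeat_copies = 0L, gc = 0.46, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom_length <- as.integer(chrom_length)
  n_feat_per_chrom <- ceiling((n_gaps + repeat_copies) / n_chrom)
  if (n_feat_per_chrom * (max(gap_length, repeat_unit_length) + 2L) >
      chrom_length)
    stop("planted gaps and repeats do not fit in the chromosomes")

  seqs <- setNames(
    vapply(seq_len(n_chrom), function(i) random_dna(chrom_length, gc), ""),
    paste0("chr", seq_len(n_chrom)))

  repeat_unit <- if (repeat_unit_length > 0L) random_dna(repeat_unit_length, gc)

  ## Place features on random chromosomes at interior, mutually separated
  ## positions (>= 2 bp apart so every N-run stays maximal).
  feats <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), kind = character(0))
  place <- function(len, kind) {
    for (attempt in seq_len(1000L)) {
      chrom <- sample(names(seqs), 1L)
      start <- sample.int(chrom_length - len - 4L, 1L) + 1L  # 0-based, interior
      end <- start + len
      same <- feats[feats$chrom == chrom, , drop = FALSE]
      if (nrow(same) == 0L ||
          all(end + 2L <= same$start | start >= same$end + 2L)) {
        feats <<- rbind(feats, data.frame(chrom = chrom, start = start,
                                          end = end, kind = kind))
        return(invisible(NULL))
      }
    }
    stop("could not pack planted features into the genome")
  }
  if (repeat_copies > 0L && repeat_unit_length > 0L)
    for (i in seq_len(repeat_copies)) place(repeat_unit_length, "repeat")
  for (i in seq_len(n_gaps)) place(as.integer(gap_length), "gap")

  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    piece <- if (f$kind == "gap") {
      strrep("N", f$end - f$start)
    } else {
      ## near-identical copies: ~0.1% divergence per copy
      u <- strsplit(repeat_unit, "")[[1]]
      nmut <- max(1L, round(0.001 * length(u)))
      at <- sample.int(length(u), nmut)
      u[at] <- vapply(u[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      paste(u, collapse = "")
    }
    substr(seqs[[f$chrom]], f$start + 1L, f$end) <- piece
  }

  ord <- function(d) d[order(d$chrom, d$start), , drop = FALSE]
  structure(list(
    sequences = seqs,
    gap_truth = ord(feats[feats$kind == "gap", c("chrom", "start", "end")]),
    repeat_truth = ord(feats[feats$kind == "repeat",
                             c("chrom", "start", "end")])
  ), class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome: ", length(x$sequences), " sequence(s), ",
      sum(nchar(x$sequences)), " bp; ", nrow(x$gap_truth), " gap(s), ",
      nrow(x$repeat_truth), " planted repeat copy(ies)\n", sep = "")
  invisible(x)
}

#' Model of the cloning vector around its HindIII site
#'
#' Only the sequence immediately flanking the cloning site matters for end
#' profiling: `left_flank` ends right before the insert and `right_flank`
#' starts right after it, and neither contains an internal AAGCTT, so a
#' vector-anchor + AAGCTT match identifies the junction unambiguously.
#' `backbone_length` is carried for depth accounting (the 7-kb class of
#' single-copy BAC vectors).
#'
#' @param flank_len length of each simulated flank (>= 100 bp).
#' @param backbone_length total vector length in bp (default 7000).
#' @param name vector name.
#' @param seed RNG seed.
#' @return an object of class `vector_model` with fields `left_flank`,
#'   `right_flank`, `backbone_length`, `name`.
#' @export
make_vector <- function(flank_len = 300L, backbone_length = 7000L,
                        name = "pBACsim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (flank_len < 100L) stop("vector flanks must be >= 100 bp")
  strip_site <- function(s) {
    while (grepl(HINDIII, s, fixed = TRUE)) {
      at <- regexpr(HINDIII, s, fixed = TRUE)
      substr(s, at, at) <- sample(c("C", "G"), 1L)
    }
    s
  }
  structure(list(left_flank = strip_site(random_dna(flank_len, 0.5)),
                 right_flank = strip_site(random_dna(flank_len, 0.5)),
                 backbone_length = as.integer(backbone_length),
                 name = name),
            class = "vector_model")
}

#' Generate the pool-to-index barcode table
#'
#' One distinct barcode per secondary pool (row pools and column pools), with
#' a minimum pairwise Hamming distance so demultiplexing can tolerate
#' `floor((min_hamming - 1) / 2)` index errors.
#'
#' @param layout a [build_layout()] object.
#' @param barcode_len barcode length (default 7).
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @param seed RNG seed.
#' @return a `data.table` with columns `pool_axis` ("ROW"/"COL"),
#'   `pool_index` (0-based), `barcode`.
#' @export
make_index_table <- function(layout, barcode_len = 7L, min_hamming = 3L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- layout$n_row_pools + layout$n_col_pools
  chosen <- character(0)
  chosen_mat <- NULL
  attempts <- 0L
  while (length(chosen) < n) {
    if ((attempts <- attempts + 1L) > 200000L)
      stop("could not generate ", n, " barcodes at pairwise distance ",
           min_hamming)
    cand <- paste(sample(c("A", "C", "G", "T"), barcode_len, replace = TRUE),
                  collapse = "")
    cm <- strsplit(cand, "")[[1]]
    if (is.null(chosen_mat) ||
        min(colSums(chosen_mat != cm)) >= min_hamming) {
      chosen <- c(chosen, cand)
      chosen_mat <- cbind(chosen_mat, cm)
    }
  }
  data.table(
    pool_axis = rep(c("ROW", "COL"),
                    c(layout$n_row_pools, layout$n_col_pools)),
    pool_index = c(seq_len(layout$n_row_pools) - 1L,
                   seq_len(layout$n_col_pools) - 1L),
    barcode = chosen)
}

## Extract the (vector-orientation) insert sequence of one clone.
clone_insert_seq <- function(clone, sequences) {
  s <- substr(sequences[[clone$chrom]], clone$start + 1L, clone$end)
  if (clone$strand == "-") revcomp(s) else s
}

#' Place one BAC clone per well, bounded by HindIII sites
#'
#' Emulates a HindIII partial digest cloned into the vector: each nuclear
#' insert runs from the start of one AAGCTT occurrence to the end of another,
#' so both trimmed ends read AAGCTT in the insert's own orientation (the site
#' is palindromic). Insert lengths are drawn from a normal distribution
#' truncated to `[insert_min, insert_max]` and snapped to the nearest
#' feasible site pair. Start sites are sampled without replacement and end
#' sites prefer unused positions, so distinct clones carry distinct end
#' sequences; when the site supply forces an end-site reuse the two clones
#' simply share a reverse (or forward) end sequence and are resolved
#' downstream by the strict assignment policy. A fraction of wells receive an
#' organelle-derived insert instead.
#'
#' @param genome a [simulate_genome()] object (or a list with `sequences`).
#' @param layout a [build_layout()] object.
#' @param insert_mean,insert_sd,insert_max,insert_min insert-length model in
#'   bp (defaults 123480 / 20000 / 50000 / 300000: the mapped-estimate mean
#'   with the library size-selection range relaxed).
#' @param organelle_fraction fraction of wells carrying an organelle insert.
#' @param organelle_genome named character vector of organelle sequences
#'   (required if `organelle_fraction > 0`).
#' @param organelle_source label for organelle clones (default
#'   `"CHLOROPLAST"`).
#' @param seed RNG seed.
#' @return a `data.table` of clone truth, one row per well: `clone_id`,
#'   `plate`, `row`, `col`, `row_pool`, `col_pool`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `source`.
#' @export
place_clones <- function(genome, layout,
                         insert_mean = 123480, insert_sd = 20000,
                         insert_min = 50000, insert_max = 300000,
                         organelle_fraction = 0, organelle_genome = NULL,
                         organelle_source = "CHLOROPLAST", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sequences <- genome$sequences
  wells <- all_wells(layout)
  n <- nrow(wells)
  n_org <- round(organelle_fraction * n)
  if (n_org > 0L && is.null(organelle_genome))
    stop("organelle_fraction > 0 requires an organelle_genome")
  org_wells <- if (n_org > 0L) sample.int(n, n_org) else integer(0)

  ## site catalogue: all HindIII starts per chromosome (1-based)
  sites <- rbindlist(lapply(names(sequences), function(nm)
    data.table(chrom = nm, site = hindiii_sites(sequences[[nm]]))))
  if (nrow(sites) == 0L) stop("genome contains no AAGCTT site")
  sites[, key := paste(chrom, site)]

  draw_len <- function() {
    for (i in seq_len(100L)) {
      l <- rnorm(1L, insert_mean, insert_sd)
      if (l >= insert_min && l <= insert_max) return(l)
    }
    min(max(insert_mean, insert_min), insert_max)
  }

  ## feasible starts: sites with at least one partner in the length window
  feasible_start <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i]
    any(sites$chrom == s$chrom &
          sites$site + 6L - s$site >= insert_min &
          sites$site + 6L - s$site <= insert_max)
  }, TRUE)
  starts_avail <- sites[feasible_start]
  n_nuc <- n - n_org
  if (nrow(starts_avail) < n_nuc)
    stop("not enough feasible HindIII start sites (", nrow(starts_avail),
         ") for ", n_nuc, " nuclear clones")
  start_free <- rep(TRUE, nrow(starts_avail))
  used_end <- character(0)

  clones <- vector("list", n)
  nuc_i <- 0L
  for (w in seq_len(n)) {
    if (w %in% org_wells) {
      org_sites <- rbindlist(lapply(names(organelle_genome), function(nm)
        data.table(chrom = nm, site = hindiii_sites(organelle_genome[[nm]]))))
      if (nrow(org_sites) < 2L)
        stop("organelle genome needs >= 2 AAGCTT sites")
      target <- draw_len()
      pairs <- org_sites[, {
        o <- .SD
        cand <- CJ(a = o$site, b = o$site)[b > a]
        cand[, chrom2 := rep(.BY$chrom, .N)]
      }, by = chrom]
      pairs[, len := b + 6L - a]
      best <- pairs[which.min(abs(len - target))]
      clones[[w]] <- data.table(
        chrom = best$chrom, start = best$a - 1L, end = best$b + 5L,
        strand = sample(c("+", "-"), 1L), source = organelle_source)
    } else {
      nuc_i <- nuc_i + 1L
      ## distinct start sites (sampled without replacement) and distinct
      ## end sites: when a drawn start has no unused end site in its
      ## length window, resample the start rather than share an end —
      ## shared end sequences are the pooling design's blind spot
      pick <- NULL
      for (try in seq_len(50L)) {
        free_idx <- which(start_free)
        if (length(free_idx) == 0L) break
        si <- free_idx[sample.int(length(free_idx), 1L)]
        s <- starts_avail[si]
        target <- draw_len()
        cand <- sites[chrom == s$chrom &
                        site + 6L - s$site >= insert_min &
                        site + 6L - s$site <= insert_max]
        cand[, len := site + 6L - s$site]
        fresh <- cand[!key %in% used_end]
        if (nrow(fresh) > 0L) {
          pick <- fresh[which.min(abs(len - target))]
          start_free[si] <- FALSE
          break
        }
      }
      if (is.null(pick)) {   # site supply exhausted: share an end site
        free_idx <- which(start_free)
        si <- if (length(free_idx)) free_idx[1L] else
          stop("no start sites left for nuclear clones")
        s <- starts_avail[si]
        target <- draw_len()
        cand <- sites[chrom == s$chrom &
                        site + 6L - s$site >= insert_min &
                        site + 6L - s$site <= insert_max]
        cand[, len := site + 6L - s$site]
        pick <- cand[which.min(abs(len - target))]
        start_free[si] <- FALSE
      }
      used_end <- c(used_end, pick$key)
      clones[[w]] <- data.table(
        chrom = s$chrom, start = s$site - 1L, end = pick$site + 5L,
        strand = sample(c("+", "-"), 1L), source = "NUCLEAR")
    }
  }
  out <- cbind(data.table(wells), rbindlist(clones))
  out[, `:=`(clone_id = paste0("bac_", well_label(layout, wells)))]
  pools <- pools_for_well(layout, wells)
  out[, `:=`(row_pool = pools$row_pool, col_pool = pools$col_pool)]
  setcolorder(out, c("clone_id", "plate", "row", "col", "row_pool",
                     "col_pool", "chrom", "start", "end", "strand", "source"))
  out[]
}

#' Expected end sequences and per-pool accounting for a clone set
#'
#' The expected forward BES of a clone is the first `bes_len` bases of its
#' insert in vector orientation and the expected reverse BES is the first
#' `bes_len` bases of the reverse-complemented insert; both start with
#' AAGCTT. These are the sequences the extraction and assignment stages
#' should recover (as prefixes).
#'
#' @param clones a [place_clones()] table.
#' @param genome the [simulate_genome()] object the clones were placed on.
#' @param organelle_genome optional organelle sequences.
#' @param bes_len length of the recorded expected end sequence (default 500).
#' @return list with `clones` (the input) and `bes`, a `data.table` with
#'   `clone_id`, `end` ("FORWARD"/"REVERSE"), `seq`.
#' @export
truth_tables <- function(clones, genome, organelle_genome = NULL,
                         bes_len = 500L) {
  sequences <- c(genome$sequences, organelle_genome)
  bes <- rbindlist(lapply(seq_len(nrow(clones)), function(i) {
    cl <- clones[i]
    ins <- clone_insert_seq(cl, sequences)
    s <- min(bes_len, nchar(ins))
    data.table(clone_id = cl$clone_id, end = c("FORWARD", "REVERSE"),
               seq = c(substr(ins, 1L, s),
                       substr(revcomp(ins), 1L, s)))
  }))
  stopifnot(all(substr(bes$seq, 1L, 6L) == HINDIII))
  list(clones = clones, bes = bes)
}

#' Simulate indexed pooled paired-end reads for both libraries
#'
#' Every secondary pool is sequenced as one indexed library: fragments are
#' drawn from the linearised clone molecules (left vector flank + insert +
#' right flank) of the pool's member clones to the target depth, a fraction
#' of fragments come from the host genome (E. coli carry-over), substitution
#' errors are applied at `error_rate` (errored bases get low quality scores),
#' and each mate-1 read carries its pool's 7-bp barcode as a prefix. Row
#' pools form library X and column pools library Y, mirroring the two mixed
#' sequencing libraries.
#'
#' @param clones a [place_clones()] table.
#' @param genome the genome the clones were placed on.
#' @param layout a [build_layout()] object.
#' @param vector a [make_vector()] model.
#' @param index_table a [make_index_table()] table.
#' @param organelle_genome,host_genome optional named sequence vectors.
#' @param read_len read length (default 150, PE150).
#' @param frag_mean,frag_sd fragment-length model (default 450/50 bp).
#' @param depth_per_pool target read depth over each pool's molecules.
#' @param error_rate per-base substitution rate.
#' @param host_fraction fraction of fragments drawn from the host genome.
#' @param seed RNG seed; fixed seed gives identical reads.
#' @return list with `library_X` and `library_Y` read-pair `data.table`s
#'   (columns `id`, `pool_axis`, `pool_index`, `clone_id`, `frag_start`,
#'   `frag_end`, `seq1`, `qual1`, `seq2`, `qual2`; `seq1` starts with the
#'   pool barcode) and `pool_counts`.
#' @export
simulate_pool_reads <- function(clones, genome, layout, vector, index_table,
                                organelle_genome = NULL, host_genome = NULL,
                                read_len = 150L, frag_mean = 450, frag_sd = 50,
                                depth_per_pool = 30, error_rate = 0.001,
                                host_fraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (anyDuplicated(index_table$barcode))
    stop("index table contains duplicate barcodes")
  if (read_len > frag_mean) stop("read_len must not exceed frag_mean")
  if (host_fraction > 0 && is.null(host_genome))
    stop("host_fraction > 0 requires a host_genome")
  sequences <- c(genome$sequences, organelle_genome)

  pool_reads <- function(axis, index) {
    members <- if (axis == "ROW") clones[row_pool == index]
    else clones[col_pool == index]
    if (nrow(members) == 0L) return(NULL)
    mols <- vapply(seq_len(nrow(members)), function(i) paste0(
      vector$left_flank, clone_insert_seq(members[i], sequences),
      vector$right_flank), "")
    mol_len <- nchar(mols)
    n_frags <- round(depth_per_pool * sum(mol_len) / (2 * read_len))
    n_host <- round(host_fraction * n_frags)
    ## fragments per molecule proportional to length
    src <- sample.int(length(mols), n_frags - n_host, replace = TRUE,
                      prob = mol_len)
    src_seq <- c(mols[src],
                 rep(host_genome[1L], n_host))
    src_id <- c(members$clone_id[src], rep("HOST", n_host))
    src_len <- nchar(src_seq)
    fl <- pmin(pmax(round(rnorm(length(src_seq), frag_mean, frag_sd)),
                    read_len), src_len)
    fs <- floor(runif(length(src_seq)) * (src_len - fl + 1)) + 1L
    frag <- substring(src_seq, fs, fs + fl - 1L)
    flip <- runif(length(frag)) < 0.5
    frag[flip] <- revcomp(frag[flip])
    r1 <- substring(frag, 1L, read_len)
    r2 <- revcomp(substring(frag, fl - read_len + 1L, fl))
    q1 <- strrep("I", nchar(r1)); q2 <- strrep("I", nchar(r2))
    ## sparse substitution errors with low quality at the errored base
    if (error_rate > 0) {
      for (mate in 1:2) {
        reads <- if (mate == 1L) r1 else r2
        quals <- if (mate == 1L) q1 else q2
        nb <- sum(nchar(reads))
        n_err <- stats::rbinom(1L, nb, error_rate)
        if (n_err > 0L) {
          at_read <- sample.int(length(reads), n_err, replace = TRUE,
                                prob = nchar(reads))
          at_pos <- ceiling(runif(n_err) * nchar(reads)[at_read])
          for (e in seq_len(n_err)) {
            old <- substr(reads[at_read[e]], at_pos[e], at_pos[e])
            if (old == "N") next
            substr(reads[at_read[e]], at_pos[e], at_pos[e]) <-
              sample(setdiff(c("A", "C", "G", "T"), old), 1L)
            substr(quals[at_read[e]], at_pos[e], at_pos[e]) <- "#"
          }
        }
        if (mate == 1L) { r1 <- reads; q1 <- quals }
        else { r2 <- reads; q2 <- quals }
      }
    }
    bc <- index_table[pool_axis == axis & pool_index == index]$barcode
    stopifnot(length(bc) == 1L)
    data.table(
      id = sprintf("%s%03d:%s:%d:%d:%d", substr(axis, 1, 1), index, src_id,
                   fs, fs + fl - 1L, seq_along(frag)),
      pool_axis = axis, pool_index = index, clone_id = src_id,
      frag_start = fs, frag_end = fs + fl - 1L,
      seq1 = paste0(bc, r1), qual1 = paste0(strrep("I", nchar(bc)), q1),
      seq2 = r2, qual2 = q2)
  }

  lib_x <- rbindlist(lapply(seq_len(layout$n_row_pools) - 1L,
                            function(i) pool_reads("ROW", i)))
  lib_y <- rbindlist(lapply(seq_len(layout$n_col_pools) - 1L,
                            function(i) pool_reads("COL", i)))
  counts <- rbindlist(list(
    lib_x[, .(n_pairs = .N), by = .(pool_axis, pool_index)],
    lib_y[, .(n_pairs = .N), by = .(pool_axis, pool_index)]))
  list(library_X = lib_x, library_Y = lib_y, pool_counts = counts)
}
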