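toy_defaults <- function() list(
  ## layout: 2x2 plate grid of 4x6-well plates = 96 wells
  plate_grid_rows = 2L, plate_grid_cols = 2L, well_rows = 4L, well_cols = 6L,
  ## genome
  n_chrom = 1L, chrom_length = 5e5, n_gaps = 3L, gap_length = 500L,
  repeat_unit_length = 0L, repeat_copies = 0L, gc = 0.46,
  ## clones
  ## truncation band symmetric around the mean so HindIII site snapping
  ## leaves the realized mean unbiased
  insert_mean = 5000, insert_sd = 1500, insert_min = 1500,
  insert_max = 8500, organelle_fraction = 0,
  ## reads
  read_len = 150L, frag_mean = 450, frag_sd = 50, depth_per_pool = 30,
  error_rate = 0.001, host_fraction = 0.02, host_length = 5e4,
  barcode_len = 7L,
  ## stage thresholds
  max_mismatch = 0L, min_mean_q = 20, min_len = 50L, host_k = 21L,
  host_hit_fraction = 0.5, min_vector_anchor = 20L,
  short_min_overlap = 50L, short_min_identity = 0.95, short_min_depth = 3L,
  asm_min_overlap = 40L, asm_min_identity = 0.98,
  share_min_identity = 0.99, share_min_cov = 0.9, policy = "STRICT",
  map_min_identity = 0.99, map_min_qcov = 0.99, seed_k = 21L,
  culling_overlap = 0.5, max_span = 250000L, fallback = "single",
  mask = TRUE, mask_max_freq = 1L, min_agreement_identity = 0.99,
  bes_truth_len = 500L)

production_defaults <- function() {
  d <- toy_defaults()
  d[c("plate_grid_rows", "plate_grid_cols", "well_rows", "well_cols")] <-
    list(6L, 4L, 16L, 24L)
  d[c("n_chrom", "chrom_length", "n_gaps", "gap_length")] <-
    list(18L, 5e7, 46L, 10000L)
  d[c("insert_mean", "insert_sd", "insert_min", "insert_max")] <-
    list(123480, 20000, 50000, 300000)
  d
}

#' Build a pipeline run configuration
#'
#' Collects every layout, simulator and stage-threshold parameter in one
#' validated list. The `"toy"` preset is a desk-scale superpool (2x2 plates
#' of 4x6 wells = 96 clones on a 500 kb genome with 5 kb mean inserts) used
#' throughout the test suite; the `"production"` preset carries the full-scale
#' geometry (24 plates in a 6x4 grid of 16x24 wells, 123.48 kb mean
#' inserts). Unknown parameter names are rejected.
#'
#' @param preset `"toy"` or `"production"`.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param ... named overrides of individual parameters.
#' @return an object of class `capss_config`.
#' @export
capss_config <- function(preset = c("toy", "production"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "toy") toy_defaults() else production_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration parameter(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "capss_config")
}

#' @export
print.capss_config <- function(x, ...) {
  cat("capss run configuration (preset ", x$preset, ", seed ", x$seed,
      ")\n", sep = "")
  cat("  layout: ", x$plate_grid_rows, "x", x$plate_grid_cols,
      " plates of ", x$well_rows, "x", x$well_cols, " wells\n", sep = "")
  cat("  genome: ", x$n_chrom, " x ", format(x$chrom_length, big.mark = ","),
      " bp; inserts ~N(", x$insert_mean, ", ", x$insert_sd, ") bp\n",
      sep = "")
  cat("  depth/pool ", x$depth_per_pool, ", error ", x$error_rate,
      ", host fraction ", x$host_fraction, "\n", sep = "")
  invisible(x)
}

#' Run the full CAPSS end-profiling pipeline on simulated data
#'
#' Executes simulate -> demultiplex -> quality/host filter -> short-BES
#' extraction -> pool assembly + long-BES extraction -> intersection
#' assignment -> genome mapping and integration -> gap statistics, entirely
#' in memory, and optionally writes every intermediate artifact in plain
#' standard formats (FASTA/FASTQ/TSV/GFF3) to `outdir`. Deterministic for a
#' fixed config seed.
#'
#' @param config a [capss_config()].
#' @param outdir output directory for artifacts, or `NULL` to skip writing.
#' @param organelle_genome optional named organelle sequences (required
#'   when `organelle_fraction > 0`).
#' @return an object of class `capss_run`: the truth tables, per-stage
#'   tables and summary accounting.
#' @export
run_pipeline <- function(config, outdir = NULL, organelle_genome = NULL) {
  stopifnot(inherits(config, "capss_config"))
  cf <- config
  layout <- build_layout(cf$plate_grid_rows, cf$plate_grid_cols,
                         cf$well_rows, cf$well_cols)
  ## --- simulate -------------------------------------------------------
  genome <- simulate_genome(cf$n_chrom, cf$chrom_length, cf$n_gaps,
                            cf$gap_length, cf$repeat_unit_length,
                            cf$repeat_copies, cf$gc, seed = cf$seed)
  set.seed(cf$seed + 1L)
  host_genome <- c(host = random_dna(cf$host_length, 0.5))
  vector <- make_vector(seed = cf$seed + 2L)
  index_table <- make_index_table(layout, cf$barcode_len, seed = cf$seed + 3L)
  clones <- place_clones(genome, layout, cf$insert_mean, cf$insert_sd,
                         cf$insert_min, cf$insert_max,
                         cf$organelle_fraction, organelle_genome,
                         seed = cf$seed + 4L)
  truth <- truth_tables(clones, genome, organelle_genome, cf$bes_truth_len)
  reads <- simulate_pool_reads(clones, genome, layout, vector, index_table,
                               organelle_genome, host_genome,
                               cf$read_len, cf$frag_mean, cf$frag_sd,
                               cf$depth_per_pool, cf$error_rate,
                               cf$host_fraction, seed = cf$seed + 5L)
  ## --- demultiplex + preprocess --------------------------------------
  host_kmers <- host_kmer_set(host_genome, cf$host_k)
  dmx_x <- demultiplex(reads$library_X, index_table, cf$max_mismatch)
  dmx_y <- demultiplex(reads$library_Y, index_table, cf$max_mismatch)
  pools_raw <- c(dmx_x$pools, dmx_y$pools)
  pools <- lapply(pools_raw, preprocess_pool, host_kmers = host_kmers,
                  min_mean_q = cf$min_mean_q, min_len = cf$min_len,
                  hit_fraction = cf$host_hit_fraction)
  accounting <- rbindlist(lapply(names(pools), function(nm)
    data.table(pool = nm, pools[[nm]]$counts)))
  ## --- BES extraction -------------------------------------------------
  pool_tab <- data.table(
    pool = names(pools),
    pool_axis = sub(":.*", "", names(pools)),
    pool_index = as.integer(sub(".*:", "", names(pools))))
  short_out <- lapply(seq_len(nrow(pool_tab)), function(i)
    extract_short_bes(pools[[pool_tab$pool[i]]]$reads, vector,
                      cf$min_vector_anchor, cf$short_min_overlap,
                      cf$short_min_identity, cf$short_min_depth))
  short_bes <- rbindlist(lapply(seq_len(nrow(pool_tab)), function(i)
    if (nrow(short_out[[i]]))
      cbind(pool_tab[i, .(pool_axis, pool_index)], short_out[[i]])))
  short_clusters <- data.table(
    pool_tab[, .(pool_axis, pool_index)],
    n_bes = vapply(short_out, nrow, 0L),
    dropped = vapply(short_out, function(b)
      as.integer(attr(b, "dropped") %||% 0L), 0L))
  long_out <- lapply(seq_len(nrow(pool_tab)), function(i) {
    rd <- pools[[pool_tab$pool[i]]]$reads
    contigs <- assemble_pool(c(rd$seq1, rd$seq2), cf$asm_min_overlap,
                             cf$asm_min_identity)
    list(n50 = if (nrow(contigs)) n50(nchar(contigs$seq)) else NA_real_,
         bes = extract_long_bes(contigs, vector, cf$min_vector_anchor))
  })
  long_bes <- rbindlist(lapply(seq_len(nrow(pool_tab)), function(i)
    if (nrow(long_out[[i]]$bes))
      cbind(pool_tab[i, .(pool_axis, pool_index)], long_out[[i]]$bes)))
  n50_tab <- data.table(pool_tab,
                        n50 = vapply(long_out, `[[`, 0, "n50"))
  ## --- assignment ------------------------------------------------------
  assign_one <- function(bes) {
    if (nrow(bes) == 0L)
      return(resolve_conflicts(match_pools(bes, bes, layout)))
    m <- match_pools(bes[pool_axis == "ROW"], bes[pool_axis == "COL"],
                     layout, cf$share_min_identity, cf$share_min_cov)
    resolve_conflicts(m, cf$policy)
  }
  short_assign <- assign_one(short_bes)
  long_assign <- assign_one(long_bes)
  stats <- rbind(
    cbind(data.table(source = "SHORT"),
          assignment_stats(short_assign, layout)),
    cbind(data.table(source = "LONG"),
          assignment_stats(long_assign, layout)))
  ## --- genome mapping --------------------------------------------------
  gidx <- kmer_index(genome$sequences, cf$seed_k)
  place_one <- function(assign) {
    if (nrow(assign) == 0L)
      return(pair_and_place(map_wells(assign, genome$sequences, gidx)))
    pl <- map_wells(assign, genome$sequences, gidx, cf$map_min_identity,
                    cf$map_min_qcov, cf$seed_k, cf$culling_overlap,
                    cf$mask, cf$mask_max_freq)
    pair_and_place(pl, cf$max_span, cf$fallback)
  }
  short_res <- place_one(short_assign)
  long_res <- place_one(long_assign)
  final <- integrate_sources(short_res, long_res, cf$max_span, cf$fallback,
                             cf$min_agreement_identity)
  organelle_calls <- if (!is.null(organelle_genome)) {
    screen_organelle(rbind(short_assign, long_assign),
                     organelle_genome, genome = genome$sequences,
                     genome_index = gidx, min_identity = cf$map_min_identity,
                     min_qcov = cf$map_min_qcov, seed_k = cf$seed_k)
  }
  ## --- gap statistics --------------------------------------------------
  gaps <- find_gaps(genome)
  coverage <- chromosome_coverage(final$mapped, genome)
  inserts <- if (any(final$mapped$evidence == "PAIRED"))
    insert_stats(final$mapped)
  run <- structure(list(
    config = cf, layout = layout, genome = genome, vector = vector,
    index_table = index_table, truth = truth, accounting = accounting,
    short_bes = short_bes, short_clusters = short_clusters,
    long_bes = long_bes, n50 = n50_tab,
    short_assign = short_assign, long_assign = long_assign,
    assignment_stats = stats, short_res = short_res, long_res = long_res,
    final = final, organelle_calls = organelle_calls, gaps = gaps,
    gaps_covered = covered_gaps(final$mapped, gaps),
    coverage = coverage, inserts = inserts
  ), class = "capss_run")
  if (!is.null(outdir)) write_run_artifacts(run, reads, outdir)
  run
}

## Write every pipeline artifact in plain standard formats.
write_run_artifacts <- function(run, reads, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_fasta(run$genome$sequences, p("genome.fa"))
  write_tsv(run$truth$clones, p("clones_truth.tsv"))
  write_fasta(setNames(run$truth$bes$seq,
                       paste0(run$truth$bes$clone_id, "_",
                              run$truth$bes$end)),
              p("expected_bes.fa"))
  write_tsv(run$index_table, p("index_table.tsv"))
  write_fastq_pairs(reads$library_X, p("libX_R1.fastq"), p("libX_R2.fastq"))
  write_fastq_pairs(reads$library_Y, p("libY_R1.fastq"), p("libY_R2.fastq"))
  write_tsv(run$accounting, p("pool_accounting.tsv"))
  if (nrow(run$short_bes))
    write_fasta(setNames(run$short_bes$seq, sprintf(
      "short_%s%d_%s_%d", run$short_bes$pool_axis, run$short_bes$pool_index,
      run$short_bes$end, seq_len(nrow(run$short_bes)))), p("short_bes.fa"))
  if (nrow(run$long_bes))
    write_fasta(setNames(run$long_bes$seq, sprintf(
      "long_%s%d_%s_%d", run$long_bes$pool_axis, run$long_bes$pool_index,
      run$long_bes$end, seq_len(nrow(run$long_bes)))), p("long_bes.fa"))
  write_tsv(run$n50, p("pool_n50.tsv"))
  write_tsv(run$short_clusters, p("short_cluster_accounting.tsv"))
  asn <- rbind(cbind(source = "SHORT", run$short_assign),
               cbind(source = "LONG", run$long_assign))
  if (nrow(asn)) {
    asn$well <- well_label(run$layout, asn)
    write_tsv(asn[, c("well", "source", "end", "status", "row_pool",
                      "col_pool", "seq")], p("assignments.tsv"))
  }
  write_tsv(run$assignment_stats, p("assignment_stats.tsv"))
  ## discard accounting with reason codes, per source plus integration
  disc <- rbind(
    if (nrow(run$short_res$discarded))
      cbind(source = "SHORT", run$short_res$discarded),
    if (nrow(run$long_res$discarded))
      cbind(source = "LONG", run$long_res$discarded))
  if (!is.null(disc) && nrow(disc)) {
    disc$well <- well_label(run$layout, disc)
    write_tsv(disc[, c("source", "well", "end", "reason")],
              p("discards.tsv"))
  }
  if (nrow(run$final$dropped))
    write_tsv(run$final$dropped, p("integration_dropped.tsv"))
  ## run log: every parameter and the seed each stochastic stage derives
  cf <- run$config
  writeLines(c(
    sprintf("preset\t%s", cf$preset),
    sprintf("master_seed\t%d", cf$seed),
    sprintf("stage_seed\tgenome\t%d", cf$seed),
    sprintf("stage_seed\thost\t%d", cf$seed + 1L),
    sprintf("stage_seed\tvector\t%d", cf$seed + 2L),
    sprintf("stage_seed\tindex_table\t%d", cf$seed + 3L),
    sprintf("stage_seed\tclones\t%d", cf$seed + 4L),
    sprintf("stage_seed\treads\t%d", cf$seed + 5L),
    vapply(setdiff(names(unclass(cf)), c("preset", "seed")),
           function(nm) sprintf("param\t%s\t%s", nm,
                                paste(cf[[nm]], collapse = ",")), "")),
    p("run_log.tsv"))
  if (nrow(run$final$mapped))
    write_gff3(run$final$mapped, p("clones.gff3"), run$layout)
  write_tsv(run$coverage, p("coverage_report.tsv"))
  gaps_bed <- run$gaps
  write.table(gaps_bed[, c("chrom", "start", "end")], p("gaps.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(outdir)
}

#' @export
print.capss_run <- function(x, ...) {
  cat("CAPSS pipeline run (preset ", x$config$preset, ", seed ",
      x$config$seed, ")\n", sep = "")
  print(x$layout)
  cat("  clones simulated: ", nrow(x$truth$clones), "\n", sep = "")
  cat("  short BESs: ", nrow(x$short_bes), "; long BESs: ",
      nrow(x$long_bes), "\n", sep = "")
  st <- x$assignment_stats
  for (i in seq_len(nrow(st)))
    cat("  ", st$source[i], " assignment: ", st$wells_with_forward[i],
        " wells with forward, ", st$wells_with_reverse[i],
        " with reverse, ", st$wells_with_pair[i], " paired\n", sep = "")
  ev <- table(x$final$mapped$evidence)
  cat("  final placements: ", nrow(x$final$mapped), " (",
      paste(names(ev), as.integer(ev), collapse = ", "), ")\n", sep = "")
  cat("  gaps covered: ", nrow(x$gaps_covered), " of ", nrow(x$gaps),
      "\n", sep = "")
  if (!is.null(x$inserts))
    cat("  paired insert size: mean ", round(x$inserts$mean), " bp (n = ",
        x$inserts$n, ")\n", sep = "")
  invisible(x)
}

#' @method summary capss_run
#' @export
summary.capss_run <- function(object, ...) {
  print(object)
  cat("\nPer-chromosome coverage:\n")
  print(object$coverage)
  invisible(object)
}

#' Score a pipeline run against its simulation truth
#'
#' Computes per-well recovery of the final placements against the clone
#' truth: the fraction of wells with a final placement, the fraction of
#' placements whose coordinates match the true clone interval within a
#' tolerance (paired placements on both boundaries, single-end placements
#' on their anchored boundary), and the number of assignments whose
#' sequence does not belong to the well's true clone (wrong-well
#' assignments).
#'
#' @param run a [run_pipeline()] result.
#' @param tol coordinate tolerance in bp (default 2).
#' @return list with `n_wells`, `n_placed`, `placement_rate`,
#'   `n_placements`, `n_matching`, `match_rate`, `n_assignments`,
#'   `n_wrong_well`.
#' @export
evaluate_against_truth <- function(run, tol = 2L) {
  truth <- run$truth$clones
  tkey <- well_key(truth)
  mapped <- run$final$mapped
  placed_wells <- unique(well_key(mapped))
  n_wells <- run$layout$n_wells

  match_one <- function(m, tc) {
    if (is.na(m$chrom) || m$chrom != tc$chrom) return(FALSE)
    if (m$evidence == "PAIRED")
      return(abs(m$start - tc$start) <= tol && abs(m$end - tc$end) <= tol)
    ## single-end: the anchored boundary of the placed end must match the
    ## corresponding insert boundary given the clone's insertion strand
    fwd <- m$evidence == "SINGLE_FORWARD"
    anchored_left <- (fwd && tc$strand == "+") || (!fwd && tc$strand == "-")
    if (anchored_left) abs(m$start - tc$start) <= tol
    else abs(m$end - tc$end) <= tol
  }
  ok <- vapply(seq_len(nrow(mapped)), function(i) {
    m <- mapped[i]
    tc <- truth[tkey == well_key(m)]
    nrow(tc) == 1L && match_one(m, tc[1])
  }, TRUE)

  ## wrong-well assignments: an assigned sequence must be a prefix-match of
  ## its well's true expected end sequence; positions where either side is
  ## N (a gap inside the insert) carry no information and are skipped
  agree_n_aware <- function(a, b) {
    ov <- min(nchar(a), nchar(b))
    if (ov < 30L) return(FALSE)
    ca <- strsplit(substr(a, 1L, ov), "")[[1]]
    cb <- strsplit(substr(b, 1L, ov), "")[[1]]
    informative <- ca != "N" & cb != "N"
    sum(ca[informative] != cb[informative]) <= 0.02 * sum(informative)
  }
  asn <- rbind(run$short_assign, run$long_assign)
  wrong <- 0L
  if (nrow(asn) > 0L) {
    bes <- run$truth$bes
    wrong <- sum(!vapply(seq_len(nrow(asn)), function(i) {
      a <- asn[i]
      tc <- truth[tkey == well_key(a)]
      if (nrow(tc) != 1L) return(FALSE)
      ref <- bes[clone_id == tc$clone_id & end == a$end]$seq
      length(ref) == 1L && agree_n_aware(a$seq, ref)
    }, TRUE))
  }
  list(n_wells = n_wells, n_placed = length(placed_wells),
       placement_rate = length(placed_wells) / n_wells,
       n_placements = nrow(mapped), n_matching = sum(ok),
       match_rate = if (nrow(mapped)) sum(ok) / nrow(mapped) else NA_real_,
       n_assignments = nrow(asn), n_wrong_well = wrong)
}
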