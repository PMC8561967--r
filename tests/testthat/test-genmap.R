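## hand-built per-end placements for one well
plc <- function(end, class, chrom = "chr1", t_start = NA, t_end = NA,
                strand = NA, seq = "AAGCTTACGT") {
  data.table::data.table(plate = 0L, row = 0L, col = 0L, end = end,
                         seq = seq, class = class, chrom = chrom,
                         t_start = as.integer(t_start),
                         t_end = as.integer(t_end), strand = strand)
}

test_that("inward-facing opposite-strand ends under 250 kb pair up", {
  p <- rbind(plc("FORWARD", "SINGLE", t_start = 100000, t_end = 100400,
                 strand = "+"),
             plc("REVERSE", "SINGLE", t_start = 220000, t_end = 220350,
                 strand = "-"))
  res <- pair_and_place(p)
  expect_equal(nrow(res$mapped), 1)
  m <- res$mapped
  expect_equal(m$evidence, "PAIRED")
  expect_equal(m$start, 100000)
  expect_equal(m$end, 220350)
  expect_equal(m$span, 120350)
  expect_equal(m$orient, "+")
})

test_that("over-span and strand conflicts fall back to single-end records", {
  far <- rbind(plc("FORWARD", "SINGLE", t_start = 100000, t_end = 100400,
                   strand = "+"),
               plc("REVERSE", "SINGLE", t_start = 480000, t_end = 480350,
                   strand = "-"))
  res <- pair_and_place(far)
  expect_equal(sort(res$mapped$evidence),
               c("SINGLE_FORWARD", "SINGLE_REVERSE"))
  expect_equal(res$discarded$reason, "SPAN_EXCEEDED")
  expect_true(all(res$mapped$span < 250000))
  ## discard policy drops the well instead
  res2 <- pair_and_place(far, fallback = "discard")
  expect_equal(nrow(res2$mapped), 0)
  ## same-strand ends cannot pair
  ss <- rbind(plc("FORWARD", "SINGLE", t_start = 1000, t_end = 1400,
                  strand = "+"),
              plc("REVERSE", "SINGLE", t_start = 5000, t_end = 5400,
                  strand = "+"))
  expect_equal(pair_and_place(ss)$discarded$reason, "STRAND_CONFLICT")
  ## outward-facing opposite strands cannot pair either
  out <- rbind(plc("FORWARD", "SINGLE", t_start = 5000, t_end = 5400,
                   strand = "+"),
               plc("REVERSE", "SINGLE", t_start = 1000, t_end = 1400,
                   strand = "-"))
  expect_equal(pair_and_place(out)$discarded$reason, "STRAND_CONFLICT")
  ## multi-hit sequences give no placement and are counted
  mh <- rbind(plc("FORWARD", "MULTI"),
              plc("REVERSE", "SINGLE", t_start = 1000, t_end = 1400,
                  strand = "-"))
  res3 <- pair_and_place(mh)
  expect_equal(res3$mapped$evidence, "SINGLE_REVERSE")
  expect_true("MULTI_HIT" %in% res3$discarded$reason)
})

test_that("placed intervals equal the clone truth on the mini simulation", {
  pl <- map_wells(.mini_assignments, mini_genome$sequences,
                  kmer_index(mini_genome$sequences, 21))
  res <- pair_and_place(pl)
  expect_gt(sum(res$mapped$evidence == "PAIRED"), 0)
  for (i in which(res$mapped$evidence == "PAIRED")) {
    m <- res$mapped[i]
    cl <- mini_clones[plate == m$plate & row == m$row & col == m$col]
    expect_equal(m$chrom, cl$chrom)
    expect_equal(m$start, cl$start)
    expect_equal(m$end, cl$end)
  }
})

test_that("integration keeps agreeing placements with long coordinates and
           rescues ambiguous wells by cross-source sequence evidence", {
  set.seed(61)
  sseq <- paste0("AAGCTT", capss:::random_dna(150, 0.5))
  lseq <- paste0(sseq, capss:::random_dna(500, 0.5))
  other <- paste0("AAGCTT", capss:::random_dna(650, 0.5))
  short_m <- pair_and_place(rbind(
    plc("FORWARD", "SINGLE", t_start = 1000, t_end = 1156, strand = "+",
        seq = sseq),
    plc("REVERSE", "SINGLE", t_start = 5000, t_end = 5350, strand = "-")))
  long_m <- pair_and_place(rbind(
    plc("FORWARD", "SINGLE", t_start = 1000, t_end = 1656, strand = "+",
        seq = lseq),
    plc("REVERSE", "SINGLE", t_start = 5000, t_end = 5350, strand = "-")))
  both <- integrate_sources(short_m, long_m)
  expect_equal(nrow(both$mapped), 1)
  expect_equal(both$mapped$source, "INTEGRATED")
  expect_equal(both$mapped$end[1], long_m$mapped$end[1])
  ## long-only and short-only wells pass through
  none <- pair_and_place(plc("FORWARD", "SINGLE")[0])
  expect_equal(integrate_sources(none, long_m)$mapped$source, "LONG")
  expect_equal(integrate_sources(short_m, none)$mapped$source, "SHORT")
  ## a well with two placed long forward candidates is unresolved until the
  ## short forward sequence picks the matching candidate
  long_amb <- pair_and_place(rbind(
    plc("FORWARD", "SINGLE", t_start = 1000, t_end = 1656, strand = "+",
        seq = lseq),
    plc("FORWARD", "SINGLE", t_start = 90000, t_end = 90656, strand = "+",
        seq = other)))
  expect_equal(nrow(long_amb$mapped), 0)
  expect_equal(nrow(long_amb$unresolved), 2)
  resc <- integrate_sources(short_m, long_amb)
  expect_equal(nrow(resc$mapped), 1)
  expect_equal(resc$mapped$source, "INTEGRATED")
  expect_equal(resc$mapped$fwd_start, 1000)   # the agreeing candidate wins
  ## irreconcilable placements are dropped and counted
  long_conf <- pair_and_place(rbind(
    plc("FORWARD", "SINGLE", t_start = 70000, t_end = 70656, strand = "+",
        seq = other),
    plc("REVERSE", "SINGLE", t_start = 75000, t_end = 75350, strand = "-",
        seq = other)))
  conf <- integrate_sources(short_m, long_conf)
  expect_equal(nrow(conf$mapped), 0)
  expect_equal(conf$dropped$reason, "INTEGRATION_CONFLICT")
})

test_that("organelle clones are called with paired evidence and
           genome-shared sequences flagged", {
  set.seed(62)
  org <- c(chloroplast = paste0(capss:::random_dna(3000, 0.4), "AAGCTT",
                                capss:::random_dna(8000, 0.4), "AAGCTT",
                                capss:::random_dna(3000, 0.4)))
  sites <- capss:::hindiii_sites(org[[1]])
  ins <- substr(org[[1]], sites[1], sites[2] + 5)
  asn <- data.table::data.table(
    plate = 0L, row = 0L, col = 0L,
    end = c("FORWARD", "REVERSE"),
    seq = c(substr(ins, 1, 400), substr(revcomp(ins), 1, 400)),
    status = "UNIQUE", row_pool = 0L, col_pool = 0L)
  gidx <- kmer_index(mini_genome$sequences, 21)
  calls <- screen_organelle(asn, org, genome = mini_genome$sequences,
                            genome_index = gidx)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$target, "CHLOROPLAST")
  expect_true(calls$paired)
  expect_false(calls$nuclear_also)
  ## a nuclear end sequence is never called
  nuc <- .mini_assignments[1]
  expect_equal(nrow(screen_organelle(nuc, org)), 0)
  ## a sequence present in both compartments is flagged NUCLEAR_ALSO
  shared <- substr(mini_genome$sequences[["chr1"]], 40001, 40400)
  org2 <- c(chloroplast = paste0(org[[1]], shared))
  asn2 <- data.table::copy(asn[1])[, seq := shared]
  calls2 <- screen_organelle(asn2, org2, genome = mini_genome$sequences,
                             genome_index = gidx)
  expect_equal(calls2$target, "NUCLEAR_ALSO")
  expect_true(calls2$nuclear_also)
})

test_that("GFF3 output has 3 lines per paired clone, 2 per single, sorted,
           and round-trips through an independent parser", {
  pl <- map_wells(.mini_assignments, mini_genome$sequences,
                  kmer_index(mini_genome$sequences, 21))
  res <- pair_and_place(pl)
  path <- tempfile(fileext = ".gff3")
  write_gff3(res$mapped, path, mini_layout)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  body <- lines[-1]
  n_paired <- sum(res$mapped$evidence == "PAIRED")
  n_single <- sum(res$mapped$evidence != "PAIRED")
  expect_equal(length(body), 3 * n_paired + 2 * n_single)
  f <- read.table(path, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  parents <- f[f$V3 == "BAC_clone", ]
  expect_false(is.unsorted(parents$V4[parents$V1 == "chr1"]))
  ## children always follow their parent
  expect_true(all(diff(which(f$V3 == "BAC_clone")) >= 2))
  ## round-trip: 1-based inclusive GFF3 back to the 0-based intervals
  skip_if_not_installed("rtracklayer")
  g <- rtracklayer::import(path)
  cl <- g[g$type == "BAC_clone"]
  got <- data.frame(start = BiocGenerics::start(cl) - 1L,
                    end = BiocGenerics::end(cl))
  want <- res$mapped[order(chrom, start)][, .(start, end)]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})
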