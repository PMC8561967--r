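test_that("simulated genomes carry exactly the planted N-run gaps", {
  g <- simulate_genome(1, 2e5, 3, 500, seed = 1)
  gaps <- find_gaps(g)
  expect_equal(nrow(gaps), 3)
  expect_true(all(gaps$end - gaps$start == 500))
  expect_equal(gaps$start, g$gap_truth$start)
  expect_equal(gaps$end, g$gap_truth$end)
})

test_that("genome simulation is deterministic for a fixed seed", {
  g1 <- simulate_genome(2, 5e4, 2, 200, seed = 9)
  g2 <- simulate_genome(2, 5e4, 2, 200, seed = 9)
  expect_identical(g1$sequences, g2$sequences)
  g3 <- simulate_genome(2, 5e4, 2, 200, seed = 10)
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("planted repeats are recorded and near-identical", {
  g <- simulate_genome(1, 1e5, 0, 0, repeat_unit_length = 300,
                       repeat_copies = 3, seed = 5)
  expect_equal(nrow(g$repeat_truth), 3)
  copies <- vapply(seq_len(3), function(i)
    substr(g$sequences[[g$repeat_truth$chrom[i]]],
           g$repeat_truth$start[i] + 1, g$repeat_truth$end[i]), "")
  mm <- capss:::seq_mismatches(copies[1], copies[2])
  expect_lt(mm / 300, 0.02)
  expect_gt(length(unique(copies)), 1)   # near-identical, not identical
})

test_that("vector flanks are long enough and AAGCTT-free", {
  v <- make_vector(seed = 3)
  expect_gte(nchar(v$left_flank), 100)
  expect_gte(nchar(v$right_flank), 100)
  expect_false(grepl("AAGCTT", v$left_flank, fixed = TRUE))
  expect_false(grepl("AAGCTT", v$right_flank, fixed = TRUE))
  expect_error(make_vector(flank_len = 50), ">= 100")
})

test_that("index barcodes are distinct with the promised Hamming margin", {
  it <- make_index_table(build_layout(2, 2, 4, 6), seed = 11)
  expect_equal(nrow(it), 8 + 12)
  expect_false(anyDuplicated(it$barcode) > 0)
  expect_true(all(nchar(it$barcode) == 7))
  bm <- do.call(rbind, strsplit(it$barcode, ""))
  for (i in seq_len(nrow(bm) - 1))
    for (j in seq(i + 1, nrow(bm)))
      expect_gte(sum(bm[i, ] != bm[j, ]), 3)
})

test_that("every nuclear insert is bounded by AAGCTT on both ends", {
  ins <- vapply(seq_len(nrow(mini_clones)), function(i)
    capss:::clone_insert_seq(mini_clones[i], mini_genome$sequences), "")
  expect_true(all(substr(ins, 1, 6) == "AAGCTT"))
  expect_true(all(substr(ins, nchar(ins) - 5, nchar(ins)) == "AAGCTT"))
  ## and in genome coordinates, start/end sites read AAGCTT forward
  for (i in seq_len(nrow(mini_clones))) {
    cl <- mini_clones[i]
    s <- mini_genome$sequences[[cl$chrom]]
    expect_equal(substr(s, cl$start + 1, cl$start + 6), "AAGCTT")
    expect_equal(substr(s, cl$end - 5, cl$end), "AAGCTT")
  }
})

test_that("insert lengths track the truncated-normal model", {
  set.seed(100)
  lay <- build_layout(2, 2, 4, 6)
  g <- simulate_genome(1, 5e5, 0, 0, seed = 101)
  cl <- place_clones(g, lay, insert_mean = 5000, insert_sd = 1500,
                     insert_min = 1500, insert_max = 8500, seed = 102)
  len <- cl$end - cl$start
  expect_true(all(len >= 1500 & len <= 8500))
  ## mean within 3 standard errors (site snapping adds symmetric noise)
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 5000), 3 * se)
})

test_that("organelle wells appear at the requested fraction", {
  set.seed(55)
  org <- c(chloroplast = paste0("AAGCTT", capss:::random_dna(2e4, 0.4),
                                "AAGCTT", capss:::random_dna(5e3, 0.4),
                                "AAGCTT"))
  cl <- place_clones(mini_genome, mini_layout, insert_mean = 3000,
                     insert_sd = 800, insert_min = 1000, insert_max = 8000,
                     organelle_fraction = 1 / 3, organelle_genome = org,
                     seed = 77)
  expect_equal(sum(cl$source == "CHLOROPLAST"), 2)
  expect_equal(sum(cl$source == "NUCLEAR"), 4)
  cl0 <- place_clones(mini_genome, mini_layout, insert_mean = 3000,
                      insert_sd = 800, insert_min = 1000, insert_max = 8000,
                      organelle_fraction = 0, seed = 77)
  expect_true(all(cl0$source == "NUCLEAR"))
})

test_that("expected end sequences are the insert termini and start AAGCTT", {
  expect_equal(nrow(mini_truth$bes), 2 * nrow(mini_clones))
  expect_true(all(substr(mini_truth$bes$seq, 1, 6) == "AAGCTT"))
  cl <- mini_clones[1]
  ins <- capss:::clone_insert_seq(cl, mini_genome$sequences)
  fwd <- mini_truth$bes[clone_id == cl$clone_id & end == "FORWARD"]$seq
  rev_ <- mini_truth$bes[clone_id == cl$clone_id & end == "REVERSE"]$seq
  expect_equal(fwd, substr(ins, 1, nchar(fwd)))
  expect_equal(rev_, substr(revcomp(ins), 1, nchar(rev_)))
})

test_that("error-free reads are exact substrings of their clone molecule", {
  rd <- mini_reads$library_X[clone_id != "HOST"][1:50]
  mols <- setNames(vapply(seq_len(nrow(mini_clones)), function(i) paste0(
    mini_vector$left_flank,
    capss:::clone_insert_seq(mini_clones[i], mini_genome$sequences),
    mini_vector$right_flank), ""), mini_clones$clone_id)
  for (i in seq_len(nrow(rd))) {
    mol <- mols[[rd$clone_id[i]]]
    r1 <- substring(rd$seq1[i], 8)   # strip the 7-bp barcode
    expect_true(grepl(r1, mol, fixed = TRUE) ||
                  grepl(revcomp(r1), mol, fixed = TRUE))
    expect_true(grepl(rd$seq2[i], mol, fixed = TRUE) ||
                  grepl(revcomp(rd$seq2[i]), mol, fixed = TRUE))
  }
})

test_that("per-pool depth and junction coverage meet the sampling model", {
  counts <- mini_reads$pool_counts
  expect_equal(nrow(counts), 2 + 3)   # 2 row pools + 3 column pools
  for (i in seq_len(nrow(counts))) {
    members <- if (counts$pool_axis[i] == "ROW")
      mini_clones[row_pool == counts$pool_index[i]]
    else mini_clones[col_pool == counts$pool_index[i]]
    mol_len <- sum(members$end - members$start) +
      nrow(members) * (nchar(mini_vector$left_flank) +
                         nchar(mini_vector$right_flank))
    depth <- counts$n_pairs[i] * 2 * 150 / mol_len
    expect_lt(abs(depth - 30) / 30, 0.1)
  }
  ## nearly all clone ends have >= 3 junction-spanning reads per pool:
  ## a read spans when it covers >= 20 vector bases and >= 26 insert bases
  rd <- rbind(mini_reads$library_X, mini_reads$library_Y)
  rd <- rd[clone_id != "HOST"]
  fl <- nchar(mini_vector$left_flank)
  n_jx <- unlist(lapply(split(rd, paste(rd$pool_axis, rd$pool_index,
                                        rd$clone_id)), function(d) {
    ins_len <- mini_clones[clone_id == d$clone_id[1], end - start]
    a1 <- d$frag_start; b1 <- d$frag_start + 149L
    a2 <- d$frag_end - 149L; b2 <- d$frag_end
    left <- sum((a1 <= fl - 19L & b1 >= fl + 26L) |
                  (a2 <= fl - 19L & b2 >= fl + 26L))
    jr <- fl + ins_len   # last insert base
    right <- sum((a1 <= jr - 25L & b1 >= jr + 20L) |
                   (a2 <= jr - 25L & b2 >= jr + 20L))
    c(left, right)
  }))
  expect_gte(mean(n_jx >= 3), 0.95)
})

test_that("read simulation is byte-deterministic for a fixed seed", {
  rd2 <- simulate_pool_reads(mini_clones, mini_genome, mini_layout,
                             mini_vector, mini_index,
                             host_genome = mini_host, depth_per_pool = 30,
                             error_rate = 0, host_fraction = 0.1, seed = 6)
  expect_identical(mini_reads$library_X, rd2$library_X)
  expect_identical(mini_reads$library_Y, rd2$library_Y)
})

test_that("duplicate barcodes in the index table are rejected", {
  bad <- copy(mini_index)
  bad$barcode[2] <- bad$barcode[1]
  expect_error(simulate_pool_reads(mini_clones, mini_genome, mini_layout,
                                   mini_vector, bad, seed = 1),
               "duplicate")
})
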