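## a synthetic read pair whose mate-1 spans the left vector-insert junction
make_junction_pair <- function(vec, insert, vlen = 40) {
  nl <- nchar(vec$left_flank)
  r1 <- paste0(substr(vec$left_flank, nl - vlen + 1, nl), "AAGCTT",
               substr(insert, 7, 106))
  data.table::data.table(id = "jx1", seq1 = r1, qual1 = strrep("I", nchar(r1)),
                         seq2 = substr(insert, 200, 349),
                         qual2 = strrep("I", 150))
}

test_that("junction reads are recognised and oriented vector-to-insert", {
  set.seed(21)
  insert <- paste0("AAGCTT", capss:::random_dna(500, 0.5))
  pr <- make_junction_pair(mini_vector, insert)
  jr <- find_junction_reads(pr, mini_vector)
  expect_equal(nrow(jr), 1)
  expect_equal(jr$end, "FORWARD")
  expect_true(startsWith(jr$insert_seq, "AAGCTT"))
  expect_equal(jr$insert_seq, paste0("AAGCTT", substr(insert, 7, 106)))
  expect_equal(jr$vector_len, 40)
  ## the same read reverse-complemented is still found
  pr_rc <- copy(pr); pr_rc$seq1 <- revcomp(pr_rc$seq1)
  jr_rc <- find_junction_reads(pr_rc, mini_vector)
  expect_equal(jr_rc$insert_seq, jr$insert_seq)
  ## a read wholly inside the insert is not a junction read
  inside <- data.table::data.table(id = "in1",
                                   seq1 = substr(insert, 10, 159),
                                   qual1 = strrep("I", 150),
                                   seq2 = substr(insert, 300, 449),
                                   qual2 = strrep("I", 150))
  expect_equal(nrow(find_junction_reads(inside, mini_vector)), 0)
})

test_that("consensus is the majority vote of a junction-read cluster", {
  set.seed(22)
  base <- paste0("AAGCTT", capss:::random_dna(94, 0.5))
  jr <- data.table::data.table(
    end = "FORWARD", insert_seq = rep(base, 5), vector_len = 20,
    mate_seq = strrep("A", 30), read_id = paste0("r", 1:5))
  cons <- cluster_and_consensus(jr)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$seq, base)
  expect_equal(cons$support, 5)
  ## one read carrying one substitution is outvoted
  mut <- base
  substr(mut, 50, 50) <- chartr("ACGT", "CATG", substr(mut, 50, 50))
  jr$insert_seq[5] <- mut
  cons2 <- cluster_and_consensus(jr)
  expect_equal(cons2$seq, base)
  ## clusters below min_depth are dropped and counted
  cons3 <- cluster_and_consensus(jr[1:2])
  expect_equal(nrow(cons3), 0)
  expect_equal(attr(cons3, "dropped"), 1)
})

test_that("distinct clone ends in one pool give distinct consensi that
           prefix-match the expected end sequences", {
  bes <- extract_short_bes(mini_pool, mini_vector)
  expect_true(all(startsWith(bes$seq, "AAGCTT")))
  members <- mini_clones[row_pool == 0]
  truth_fwd <- mini_truth$bes[clone_id %in% members$clone_id &
                                end == "FORWARD"]$seq
  truth_rev <- mini_truth$bes[clone_id %in% members$clone_id &
                                end == "REVERSE"]$seq
  ## every emitted consensus is a prefix of some true end sequence
  for (i in seq_len(nrow(bes))) {
    ref <- if (bes$end[i] == "FORWARD") truth_fwd else truth_rev
    hit <- vapply(ref, function(r)
      startsWith(r, substr(bes$seq[i], 1, min(nchar(bes$seq[i]),
                                              nchar(r)))), TRUE)
    expect_true(any(hit))
  }
  ## and every member clone end is recovered by some consensus
  for (tr in c(truth_fwd, truth_rev)) {
    hit <- vapply(seq_len(nrow(bes)), function(i)
      startsWith(tr, substr(bes$seq[i], 1, min(nchar(bes$seq[i]),
                                               nchar(tr)))), TRUE)
    expect_true(any(hit))
  }
})

test_that("vector trimming leaves sequences starting exactly at AAGCTT", {
  set.seed(23)
  x <- capss:::random_dna(200, 0.5)
  nl <- nchar(mini_vector$left_flank)
  cons <- paste0(substr(mini_vector$left_flank, nl - 60 + 1, nl),
                 "AAGCTT", x)
  tr <- trim_to_bes(cons, mini_vector)
  expect_equal(tr$seq, paste0("AAGCTT", x))
  expect_equal(tr$end, "FORWARD")
  ## idempotent on already-trimmed input
  tr2 <- trim_to_bes(tr$seq, mini_vector)
  expect_equal(tr2$seq, tr$seq)
  ## junction on the other strand is normalised
  tr3 <- trim_to_bes(revcomp(cons), mini_vector)
  expect_equal(tr3$seq, paste0("AAGCTT", x))
  ## no junction and no AAGCTT start: rejected
  expect_true(is.na(trim_to_bes(x, mini_vector)$seq))
})
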