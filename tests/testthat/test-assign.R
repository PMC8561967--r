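## helper: a BES list row
bes_row <- function(pool_index, end, seq)
  data.table::data.table(pool_index = pool_index, end = end, seq = seq)

test_that("a sequence shared by a row and a column pool lands at their
           intersection well", {
  set.seed(41)
  lay <- build_layout(2, 2, 4, 6)
  s <- paste0("AAGCTT", capss:::random_dna(200, 0.5))
  other <- paste0("AAGCTT", capss:::random_dna(200, 0.5))
  m <- match_pools(bes_row(3L, "FORWARD", s),
                   rbind(bes_row(10L, "FORWARD", s),
                         bes_row(4L, "FORWARD", other)), lay)
  expect_equal(nrow(m), 1)
  w <- well_at_intersection(lay, 3, 10)
  expect_equal(m$plate, w$plate)
  expect_equal(m$row, w$row)
  expect_equal(m$col, w$col)
  ## a sequence present only on one axis is never assigned
  m2 <- match_pools(bes_row(1L, "FORWARD", other),
                    bes_row(10L, "FORWARD", s), lay)
  expect_equal(nrow(m2), 0)
  ## truncated copies still share (anchored prefix agreement)
  m3 <- match_pools(bes_row(0L, "FORWARD", s),
                    bes_row(0L, "FORWARD", substr(s, 1, 120)), lay)
  expect_equal(nrow(m3), 1)
})

test_that("a sequence implying several wells is filtered under STRICT", {
  set.seed(42)
  lay <- build_layout(2, 2, 4, 6)
  s <- paste0("AAGCTT", capss:::random_dna(200, 0.5))
  ## the same end sequence in two row pools and two column pools:
  ## four candidate intersections, unresolvable
  m <- match_pools(rbind(bes_row(0L, "FORWARD", s), bes_row(5L, "FORWARD", s)),
                   rbind(bes_row(1L, "FORWARD", s), bes_row(7L, "FORWARD", s)),
                   lay)
  expect_equal(nrow(m), 4)
  strict <- resolve_conflicts(m, "STRICT")
  expect_equal(nrow(strict), 0)
  expect_gt(attr(strict, "filtered"), 0)
  keep <- resolve_conflicts(m, "KEEP_ALL")
  expect_equal(nrow(keep), 4)
  expect_error(resolve_conflicts(m, "NO_SUCH_POLICY"))
})

test_that("a well collecting two different sequences keeps both, AMBIGUOUS", {
  set.seed(43)
  lay <- build_layout(2, 2, 4, 6)
  s1 <- paste0("AAGCTT", capss:::random_dna(200, 0.5))
  s2 <- paste0("AAGCTT", capss:::random_dna(200, 0.5))
  m <- match_pools(rbind(bes_row(2L, "FORWARD", s1),
                         bes_row(2L, "FORWARD", s2)),
                   rbind(bes_row(9L, "FORWARD", s1),
                         bes_row(9L, "FORWARD", s2)), lay)
  res <- resolve_conflicts(m, "STRICT")
  expect_equal(nrow(res), 2)
  expect_true(all(res$status == "AMBIGUOUS"))
})

test_that("assignment statistics recount the assignment table", {
  lay <- build_layout(2, 2, 4, 6)
  empty <- resolve_conflicts(
    match_pools(bes_row(integer(0), character(0), character(0)),
                bes_row(integer(0), character(0), character(0)), lay))
  st0 <- assignment_stats(empty, lay)
  expect_equal(st0$wells_with_forward, 0)
  expect_equal(st0$wells_empty, 96)
  ## on the mini simulation, stats match a direct recount
  bes <- rbindlist(lapply(names(.mini_pools_bes), function(nm) {
    cbind(data.table::data.table(
      pool_axis = sub(":.*", "", nm),
      pool_index = as.integer(sub(".*:", "", nm))), .mini_pools_bes[[nm]])
  }))
  m <- match_pools(bes[pool_axis == "ROW"], bes[pool_axis == "COL"],
                   mini_layout)
  asn <- resolve_conflicts(m)
  st <- assignment_stats(asn, mini_layout)
  per_well <- asn[, .(f = any(end == "FORWARD"), r = any(end == "REVERSE")),
                  by = .(plate, row, col)]
  expect_equal(st$wells_with_forward, sum(per_well$f))
  expect_equal(st$wells_with_pair, sum(per_well$f & per_well$r))
  expect_lte(st$wells_with_pair,
             min(st$wells_with_forward, st$wells_with_reverse))
  expect_equal(st$wells_with_forward +
                 (mini_layout$n_wells - st$wells_with_forward),
               mini_layout$n_wells)
})

test_that("assignments stay inside the source pools and recover true wells
           on error-free simulation", {
  asn <- .mini_assignments
  expect_gt(nrow(asn), 0)
  ## no assignment outside the intersection of its source pools
  for (i in seq_len(nrow(asn))) {
    w <- well_at_intersection(mini_layout, asn$row_pool[i], asn$col_pool[i])
    expect_equal(unlist(w), unlist(asn[i, .(plate, row, col)]))
  }
  ## precision: each assigned sequence prefixes the true end sequence of
  ## its well's clone
  for (i in seq_len(nrow(asn))) {
    cl <- mini_clones[plate == asn$plate[i] & row == asn$row[i] &
                        col == asn$col[i]]
    ref <- mini_truth$bes[clone_id == cl$clone_id & end == asn$end[i]]$seq
    ov <- min(nchar(ref), nchar(asn$seq[i]))
    expect_equal(substr(asn$seq[i], 1, ov), substr(ref, 1, ov))
  }
  ## recall: near-complete recovery of the 12 clone ends (a single pool
  ## can miss the junction-read depth threshold by sampling chance)
  expect_gte(nrow(unique(asn[, .(plate, row, col, end)])),
             2 * nrow(mini_clones) - 1)
})

test_that("forward and reverse assignment flows are independent", {
  bes <- .mini_bes_table
  full <- resolve_conflicts(match_pools(bes[pool_axis == "ROW"],
                                        bes[pool_axis == "COL"],
                                        mini_layout))
  fwd_only <- bes[end == "FORWARD"]
  f <- resolve_conflicts(match_pools(fwd_only[pool_axis == "ROW"],
                                     fwd_only[pool_axis == "COL"],
                                     mini_layout))
  expect_equal(
    data.table::setkey(full[end == "FORWARD",
                            .(plate, row, col, seq)], plate, row, col, seq),
    data.table::setkey(f[, .(plate, row, col, seq)], plate, row, col, seq))
})
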