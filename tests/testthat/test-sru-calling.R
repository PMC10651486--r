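mk_full <- function(start, end, contig = "c1", id = paste0("r", start),
                    bits = 50, subtype = "I-F") {
  tibble::tibble(repeat_id = id, subtype = subtype, contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 strand = "+", identity = 98, coverage = 100,
                 bit_score = bits, e_value = 1e-8, coverage_class = "full")
}

test_that("full matches within 100 bp cluster into arrays; beyond stay solitary", {
  near <- dplyr::bind_rows(mk_full(100, 130), mk_full(190, 220))  # 60-bp gap
  cl <- cluster_full_matches(near, 100)
  expect_equal(nrow(cl$arrays), 2)
  expect_equal(nrow(cl$solitary), 0)
  expect_equal(length(unique(cl$arrays$array_id)), 1)

  far <- dplyr::bind_rows(mk_full(100, 130), mk_full(280, 310))  # 150-bp gap
  cl2 <- cluster_full_matches(far, 100)
  expect_equal(nrow(cl2$arrays), 0)
  expect_equal(nrow(cl2$solitary), 2)

  single <- mk_full(500, 530)
  cl3 <- cluster_full_matches(single, 100)
  expect_equal(nrow(cl3$solitary), 1)

  # boundary: gap of exactly 100 links
  at100 <- dplyr::bind_rows(mk_full(100, 130), mk_full(230, 260))
  expect_equal(nrow(cluster_full_matches(at100, 100)$arrays), 2)
  at101 <- dplyr::bind_rows(mk_full(100, 130), mk_full(231, 261))
  expect_equal(nrow(cluster_full_matches(at101, 100)$arrays), 0)
})

test_that("clustering equals brute-force transitive closure on random intervals", {
  set.seed(31)
  for (trial in 1:200) {
    n <- sample(1:15, 1)
    start <- sort(sample(0:2000, n))
    m <- mk_full(start, start + sample(25:35, n, TRUE),
                 id = paste0("r", seq_len(n)))
    # make overlap-free as the pipeline guarantees
    m <- resolve_overlaps(m)
    cl <- cluster_full_matches(m, 100)
    comp <- oracle_cluster(m, 100)
    sizes <- table(comp)[as.character(comp)]
    expect_equal(nrow(cl$arrays), sum(sizes >= 2))
    expect_equal(nrow(cl$solitary), sum(sizes == 1))
    expect_equal(nrow(cl$arrays) + nrow(cl$solitary), nrow(m))
  }
})

test_that("mini-arrays need a partial within 100 bp at >=90% mutual identity", {
  set.seed(32)
  db_seq <- rand_seq(28)
  # solitary at [1000,1028); partial subject planted 80 bp downstream
  make_case <- function(partner_seq) {
    g <- plant(plant(rand_seq(3000), db_seq, 1000), partner_seq, 1108)
    sol <- mk_full(1000, 1028)
    part <- dplyr::mutate(mk_full(1108, 1108 + nchar(partner_seq), id = "p"),
                          coverage = 60, coverage_class = "partial")
    call_mini_arrays(sol, part, c(c1 = g))
  }
  near_copy <- sub_at(db_seq, c(9, 18))             # 26/28 = 92.9%
  flagged <- make_case(near_copy)
  expect_true(flagged$mini_array_flag)
  expect_gte(flagged$mini_array_identity, 90)

  diverged <- sub_at(db_seq, c(4, 8, 12, 16, 20))    # 23/28 = 82.1%
  expect_false(make_case(diverged)$mini_array_flag)

  # exactly 90.0%: 20-mer truncated partner with 2 substitutions
  seq20 <- rand_seq(20)
  g <- plant(plant(rand_seq(3000), seq20, 1000), sub_at(seq20, c(7, 14)), 1100)
  sol <- mk_full(1000, 1020)
  part <- dplyr::mutate(mk_full(1100, 1120, id = "p"),
                        coverage = 60, coverage_class = "partial")
  at90 <- call_mini_arrays(sol, part, c(c1 = g))
  expect_true(at90$mini_array_flag)
  expect_equal(at90$mini_array_identity, 90)

  # no partial within 100 bp -> no flag
  far <- dplyr::mutate(mk_full(1200, 1228, id = "p"),
                       coverage = 60, coverage_class = "partial")
  g2 <- plant(rand_seq(3000), db_seq, 1000)
  expect_false(call_mini_arrays(mk_full(1000, 1028), far, c(c1 = g2))$mini_array_flag)
})

test_that("flank filter discards candidates with >70% identity flank copies", {
  set.seed(33)
  cand <- rand_seq(20)
  # flank copy at exactly 75% (5 substitutions evenly spaced) -> discard
  copy75 <- sub_at(cand, c(3, 7, 11, 15, 19))
  g75 <- plant(plant(rand_seq(2000), cand, 1000), copy75, 950)
  r75 <- flank_identity_filter(mk_full(1000, 1020), c(c1 = g75))
  expect_false(r75$passed_flank_filter)
  expect_gte(r75$flank_up_identity, 75)

  # random flanks -> kept, identities modest
  g_rand <- plant(rand_seq(2000), cand, 1000)
  r_ok <- flank_identity_filter(mk_full(1000, 1020), c(c1 = g_rand))
  expect_true(r_ok$passed_flank_filter)
  expect_lte(r_ok$flank_up_identity, 70)
  expect_lte(r_ok$flank_down_identity, 70)

  # candidate at contig start: upstream flank absent -> identity 0,
  # decision rests on the downstream flank alone
  g_edge <- plant(rand_seq(2000), cand, 0)
  r_edge <- flank_identity_filter(mk_full(0, 20), c(c1 = g_edge))
  expect_equal(r_edge$flank_up_identity, 0)
  expect_true(r_edge$passed_flank_filter)
})

test_that("flank identity of exactly 70% is kept (strictly-greater discards)", {
  # candidate aligned against a flank that IS a 70% copy and nothing else:
  # flank == degraded copy (contig starts right at the flank)
  set.seed(34)
  cand <- rand_seq(20)
  copy70 <- sub_at(cand, c(2, 5, 8, 11, 14, 17))  # 14/20 = 70.0%
  g <- plant(paste0(copy70, cand, rand_seq(500)), cand, 20)
  r <- flank_identity_filter(mk_full(20, 40), c(c1 = g),
                             sru_params(flank_length = 20))
  expect_equal(r$flank_up_identity, 70)
  expect_true(r$passed_flank_filter)
})

test_that("bit-score threshold is inclusive at 41.1", {
  cands <- dplyr::bind_rows(mk_full(0, 28, bits = 41.1),
                            mk_full(100, 128, bits = 41.0),
                            mk_full(200, 228, bits = 60))
  out <- apply_bitscore_threshold(cands)
  expect_equal(out$passed_threshold, c(TRUE, FALSE, TRUE))
  empty <- apply_bitscore_threshold(cands[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("subtype is inherited from the surviving highest-bit-score match", {
  overlapping <- dplyr::bind_rows(
    mk_full(100, 128, id = "rIF", bits = 45, subtype = "I-F"),
    mk_full(105, 133, id = "rIE", bits = 42, subtype = "I-E")
  )
  kept <- assign_subtype(resolve_overlaps(overlapping))
  expect_equal(kept$assigned_subtype, "I-F")
  unk <- assign_subtype(mk_full(0, 28, subtype = "unknown"))
  expect_equal(unk$assigned_subtype, "unknown")
})

test_that("every full match lands in exactly one funnel bucket", {
  fx <- tiny_scan_fixture(seed = 44)
  scan <- sru_scan(fx$bench$genomes, fx$db, fx$bench$orfs)
  f <- scan$funnel
  expect_equal(f[["full"]], f[["array_members"]] + f[["solitary"]])
  expect_equal(f[["solitary"]],
               f[["mini_arrays"]] + f[["flank_rejected"]] +
                 f[["threshold_rejected"]] + f[["final_srus"]])
  # partial matches never appear as final SRUs
  expect_true(all(scan$srus$coverage_class == "full"))
})
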