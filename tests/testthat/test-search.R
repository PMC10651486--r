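test_that("a verbatim planted repeat is found once, full coverage, 100% identity", {
  db <- fixture_db()
  rep28 <- db[nchar(db$sequence) == 28, ][1, ]
  set.seed(21)
  genome <- plant(rand_seq(5000), rep28$sequence, 2400)
  m <- search_repeats(c(c1 = genome), db[db$id == rep28$id, ])
  expect_equal(nrow(m), 1)
  expect_equal(m$identity, 100)
  expect_equal(m$coverage, 100)
  expect_equal(m$coverage_class, "full")
  expect_equal(m$start, 2400L)
  expect_equal(m$end, 2428L)
  expect_equal(m$strand, "+")
  expect_equal(m$subtype, rep28$subtype)
})

test_that("identity below 90% is discarded; exactly 90.0% is kept", {
  db <- fixture_db()
  rep28 <- db[nchar(db$sequence) == 28, ][1, ]
  set.seed(22)
  bg <- rand_seq(5000)
  # 3 evenly spaced substitutions: 25/28 = 89.3% on the full span, and no
  # clipped sub-alignment scores higher than the full span
  degraded <- sub_at(rep28$sequence, c(7, 14, 21))
  m <- search_repeats(c(c1 = plant(bg, degraded, 2400)),
                      db[db$id == rep28$id, ])
  expect_equal(nrow(m), 0)

  # a 20-mer with 2 interior substitutions: 18/20 = 90.0% exactly, kept
  # (chance short partials elsewhere in the random background are allowed;
  # the assertion is about the planted locus)
  rep20 <- tibble::tibble(id = "r20", sequence = rand_seq(20), subtype = "I-F")
  class(rep20) <- c("repeat_db", class(rep20))
  at90 <- sub_at(rep20$sequence, c(7, 14))
  m90 <- search_repeats(c(c1 = plant(bg, at90, 1000)), rep20)
  at_locus <- m90[m90$start == 1000 & m90$end == 1020, ]
  expect_equal(nrow(at_locus), 1)
  expect_equal(at_locus$identity, 90)
  expect_equal(at_locus$coverage_class, "full")
})

test_that("repeats planted inside masked intervals are not matched", {
  db <- fixture_db()
  rep1 <- db[1, ]
  set.seed(23)
  genome <- c(c1 = plant(rand_seq(3000), rep1$sequence, 1500))
  orfs <- tibble::tibble(contig = "c1", start = 1400L, end = 1700L,
                         strand = "+", confidence = 95)
  masked <- mask_sequence(genome, orfs)
  m <- search_repeats(masked, db)
  expect_equal(nrow(m), 0)

  # same plant, ORF below the masking threshold: found
  low <- mask_sequence(genome, dplyr::mutate(orfs, confidence = 60))
  expect_equal(nrow(search_repeats(low, db)), 1)
})

test_that("planted exact copies are recovered on both strands (property, 200 plants)", {
  db <- fixture_db()
  set.seed(24)
  found <- 0L
  n_genomes <- 10L
  per_genome <- 20L
  for (g in seq_len(n_genomes)) {
    bg <- rand_seq(11000)
    picks <- db[sample(nrow(db), per_genome), ]
    strands <- sample(c("+", "-"), per_genome, TRUE)
    starts <- seq(100, 10400, length.out = per_genome) |> round()
    for (i in seq_len(per_genome)) {
      s <- picks$sequence[i]
      if (strands[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      bg <- plant(bg, s, starts[i])
    }
    m <- search_repeats(c(c1 = bg), db)
    for (i in seq_len(per_genome)) {
      hit <- m[m$repeat_id == picks$id[i] & m$start == starts[i] &
                 m$strand == strands[i] & m$identity == 100 &
                 m$coverage == 100, ]
      found <- found + (nrow(hit) >= 1)
    }
  }
  expect_equal(found, n_genomes * per_genome)
})

test_that("coverage classes split at 90 and 50 exactly as specified", {
  expect_equal(classify_coverage(c(95, 90, 89.99, 70, 50, 49)),
               c("full", "full", "partial", "partial", "partial", "reject"))
  expect_error(classify_coverage(101))
})

test_that("overlap resolution keeps the highest bit score", {
  m <- tibble::tibble(
    repeat_id = c("a", "b"), subtype = "I-F", contig = "c1",
    start = c(100L, 110L), end = c(128L, 138L), strand = "+",
    identity = 100, coverage = 100, bit_score = c(45, 42), e_value = 1e-6,
    coverage_class = "full"
  )
  kept <- resolve_overlaps(m)
  expect_equal(kept$repeat_id, "a")
  expect_equal(kept$bit_score, 45)

  disjoint <- dplyr::mutate(m, start = c(100L, 300L), end = c(128L, 328L))
  expect_equal(nrow(resolve_overlaps(disjoint)), 2)
})

test_that("resolved matches are always pairwise overlap-free", {
  set.seed(26)
  for (trial in 1:20) {
    n <- sample(5:20, 1)
    start <- sample(0:500, n, TRUE)
    m <- tibble::tibble(
      repeat_id = paste0("r", seq_len(n)), subtype = "I-E", contig = "c1",
      start = start, end = start + sample(20:40, n, TRUE), strand = "+",
      identity = 95, coverage = 100,
      bit_score = round(runif(n, 30, 60), 1), e_value = 1e-5,
      coverage_class = "full"
    )
    r <- resolve_overlaps(m)
    if (nrow(r) > 1) {
      combs <- utils::combn(nrow(r), 2)
      ov <- apply(combs, 2, function(ij) {
        r$start[ij[1]] < r$end[ij[2]] & r$start[ij[2]] < r$end[ij[1]]
      })
      expect_false(any(ov))
    }
  }
})

test_that("internal and BLAST backends agree on planted matches", {
  db <- fixture_db()
  picks <- db[c(3, 17, 33), ]
  set.seed(27)
  bg <- rand_seq(8000)
  bg <- plant(bg, picks$sequence[1], 1000)
  bg <- plant(bg, sub_at(picks$sequence[2], c(10, 17)), 3000)  # interior subs
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(picks$sequence[3])))
  bg <- plant(bg, rc, 5000)
  genome <- c(c1 = bg)

  internal <- search_repeats(genome, picks, backend = "internal")
  external <- search_repeats(genome, picks, backend = "blast")
  key <- function(m) {
    m <- dplyr::select(m, "repeat_id", "start", "end", "strand", "bit_score")
    m[order(m$start), ]
  }
  expect_equal(key(internal), key(external), tolerance = 1e-6)
  expect_equal(nrow(internal), 3)
})
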