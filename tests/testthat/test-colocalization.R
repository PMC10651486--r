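mk_acr <- function(start, end, score = 0.9, e = 1e-6, bits = 80,
                   contig = "c1", id = paste0("a", start)) {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), score = score, e_value = e,
                 bit_score = bits, id = id)
}

mk_sru <- function(start, end, contig = "c1") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end))
}

test_that("acr hit screening: score strictly > 0.5, E <= 0.01, best of overlaps", {
  hits <- dplyr::bind_rows(
    mk_acr(0, 300, score = 0.5),              # boundary score -> removed
    mk_acr(1000, 1300, score = 0.51),         # kept
    mk_acr(2000, 2300, e = 0.01),             # boundary E -> kept
    mk_acr(3000, 3300, e = 0.011),            # removed
    mk_acr(4000, 4300, bits = 80, id = "hi"),
    mk_acr(4100, 4400, bits = 60, id = "lo")  # overlaps hi -> dropped
  )
  kept <- filter_acr_hits(hits)
  expect_setequal(kept$id, c("a1000", "a2000", "hi"))
  expect_error(filter_acr_hits(dplyr::select(hits, -"score")), "score")
})

test_that("acr counting uses gap distance with a 1-kb window, each acr once", {
  srus <- mk_sru(10000, 10030)
  expect_equal(count_acr_within(srus, mk_acr(10530, 10830)), 1)   # 500 bp gap
  expect_equal(count_acr_within(srus, mk_acr(11530, 11830)), 0)   # 1500 bp gap
  expect_equal(count_acr_within(srus, mk_acr(10010, 10310)), 1)   # overlap = 0
  # boundary: gap of exactly 1000 counts
  expect_equal(count_acr_within(srus, mk_acr(11030, 11330)), 1)
  expect_equal(count_acr_within(srus, mk_acr(11031, 11331)), 0)
  # one acr near two SRUs counts once
  two <- dplyr::bind_rows(mk_sru(10000, 10030), mk_sru(11000, 11030))
  expect_equal(count_acr_within(two, mk_acr(10500, 10600)), 1)
  # different contigs never pair
  expect_equal(count_acr_within(srus, mk_acr(10100, 10200, contig = "c2")), 0)
})

test_that("an acr overlapping the only SRU gives P = 1/(n_perm + 1)", {
  srus <- mk_sru(50000, 50030)
  acrs <- mk_acr(50010, 50200)
  res <- acr_permutation_test(srus, acrs, c(c1 = 1e6), n_perm = 1000, seed = 3)
  expect_equal(res$observed, 1)
  # permuted counts can never exceed the single-acr observed count of 1
  expect_equal(res$p_value, 1 / 1001)
})

test_that("the P value matches direct evaluation of the displayed formula", {
  set.seed(61)
  for (trial in 1:10) {
    srus <- mk_sru(0, 30)
    acrs <- dplyr::bind_rows(mk_acr(1500, 1600), mk_acr(1800, 1900, id = "b"))
    res <- acr_permutation_test(srus, acrs, c(c1 = 3000),
                                n_perm = sample(2:5, 1), seed = trial)
    expect_equal(res$p_value,
                 (sum(res$permuted > res$observed) + 1) / (res$n_perm + 1))
    expect_gte(res$p_value, 1 / (res$n_perm + 1))
    expect_lte(res$p_value, 1)
  }
})

test_that("an isolated SRU among clustered acrs can reach P = 1", {
  # observed 0; on a short replicon nearly every relocation lands within
  # the window, so all permuted counts exceed the observed count
  srus <- mk_sru(0, 30)
  acrs <- mk_acr(1400, 1450)
  found_p1 <- FALSE
  for (seed in 1:20) {
    res <- acr_permutation_test(srus, acrs, c(c1 = 1481), n_perm = 5,
                                seed = seed)
    expect_equal(res$observed, 0)
    if (res$p_value == 1) found_p1 <- TRUE
  }
  expect_true(found_p1)
})

test_that("relocation preserves SRU lengths and contigs; empty acrs give the floor P", {
  set.seed(62)
  srus <- dplyr::bind_rows(mk_sru(100, 130), mk_sru(5000, 5040, contig = "c2"))
  lens <- c(c1 = 20000, c2 = 30000)
  for (r in 1:50) {
    moved <- srutools:::relocate_srus(srus, unname(lens[srus$contig]))
    expect_equal(moved$end - moved$start, srus$end - srus$start)
    expect_equal(moved$contig, srus$contig)
    expect_true(all(moved$start >= 0))
    expect_true(all(moved$end <= lens[moved$contig]))
  }
  none <- acr_permutation_test(srus, mk_acr(0, 10)[0, ], lens,
                               n_perm = 100, seed = 1)
  expect_equal(none$observed, 0)
  expect_true(all(none$permuted == 0))
  expect_equal(none$p_value, 1 / 101)

  # SRU longer than its contig is impossible
  expect_error(acr_permutation_test(mk_sru(0, 500), mk_acr(0, 10),
                                    c(c1 = 400), n_perm = 2, seed = 1),
               "shorter")
})

test_that("identical seeds reproduce the permutation result exactly", {
  srus <- dplyr::bind_rows(mk_sru(100, 130), mk_sru(9000, 9030))
  acrs <- dplyr::bind_rows(mk_acr(500, 700), mk_acr(8000, 8200, id = "b"))
  a <- acr_permutation_test(srus, acrs, c(c1 = 20000), n_perm = 200, seed = 99)
  b <- acr_permutation_test(srus, acrs, c(c1 = 20000), n_perm = 200, seed = 99)
  expect_identical(a$permuted, b$permuted)
  expect_identical(a$p_value, b$p_value)
})

test_that("subtype association: degenerate cohorts have zero permutation variance", {
  all_match <- tibble::tibble(sru_subtype = rep("I-F", 8),
                              host_subtypes = rep("I-F", 8))
  res <- subtype_association_test(all_match, n_perm = 50, seed = 1)
  expect_equal(res$observed_fraction, 100)
  expect_equal(res$permuted_mean, 100)
  expect_equal(res$permuted_sd, 0)

  half <- tibble::tibble(sru_subtype = rep(c("I-F", "I-E"), each = 4),
                         host_subtypes = rep("I-F", 8))
  res2 <- subtype_association_test(half, n_perm = 50, seed = 1)
  expect_equal(res2$observed_fraction, 50)
  expect_equal(res2$permuted_mean, 50)
  expect_equal(res2$permuted_sd, 0)

  expect_error(subtype_association_test(all_match[0, ]), "no SRUs")
  expect_error(subtype_association_test(all_match, n_perm = 0), "n_perm")
})

test_that("permuted mean matches full enumeration and the analytic expectation", {
  data <- tibble::tibble(
    sru_subtype = c("I-F", "I-F", "I-E", "V-A", "II-A"),
    host_subtypes = list(c("I-F", "I-E"), "I-F", "V-A", c("V-A", "II-A"), "I-C")
  )
  n <- nrow(data)
  # exhaustive oracle over all n! label orderings
  fracs <- vapply(all_perms(n), function(p) {
    lab <- data$sru_subtype[p]
    100 * mean(mapply(function(l, s) l %in% s, lab, data$host_subtypes))
  }, numeric(1))
  enum_mean <- mean(fracs)
  # analytic expectation: sum_i count(labels in host_i set) / N^2
  analytic <- 100 * sum(vapply(data$host_subtypes, function(s) {
    sum(data$sru_subtype %in% s)
  }, numeric(1))) / n^2
  expect_equal(enum_mean, analytic)
  res <- subtype_association_test(data, n_perm = 4000, seed = 7)
  expect_equal(res$permuted_mean, enum_mean, tolerance = 0.05)
  # host sets with multiple subtypes count membership, not equality
  expect_equal(res$observed_fraction, 100 * 3 / 5)
})

test_that("comma-separated host subtype strings behave like list columns", {
  as_list <- tibble::tibble(sru_subtype = c("I-F", "I-E"),
                            host_subtypes = list(c("I-F", "I-C"), "I-C"))
  as_chr <- tibble::tibble(sru_subtype = c("I-F", "I-E"),
                           host_subtypes = c("I-F, I-C", "I-C"))
  a <- subtype_association_test(as_list, n_perm = 100, seed = 5)
  b <- subtype_association_test(as_chr, n_perm = 100, seed = 5)
  expect_equal(a$observed_fraction, b$observed_fraction)
  expect_equal(a$permuted, b$permuted)
})
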