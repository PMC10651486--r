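# Shared fixtures and independent oracles. Everything is generated in
# code; alignment-free oracles are deliberately implemented differently
# from the package internals they check.

fixture_db <- function() {
  load_repeat_db(system.file("extdata", "repeats_synthetic.fa",
                             package = "srutools"))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

write_gff <- function(orfs, path = tempfile(fileext = ".gff3")) {
  type <- if ("type" %in% names(orfs)) orfs$type else rep("CDS", nrow(orfs))
  lines <- c("##gff-version 3",
             sprintf("%s\tcaller\t%s\t%d\t%d\t.\t%s\t0\tID=o%d;conf=%s",
                     orfs$contig, type, orfs$start + 1L, orfs$end, orfs$strand,
                     seq_len(nrow(orfs)), orfs$confidence))
  writeLines(lines, path)
  path
}

# Plant `insert` into `background` so that it occupies 0-based [at, at+len).
plant <- function(background, insert, at) {
  stopifnot(at + nchar(insert) <= nchar(background))
  paste0(substr(background, 1, at), insert,
         substr(background, at + nchar(insert) + 1, nchar(background)))
}

# Substitute bases at explicit 1-based positions (deterministic: A<->C,
# G<->T swaps), for boundary-exact identity constructions.
sub_at <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  v[positions] <- swap[v[positions]]
  paste(v, collapse = "")
}

# Brute-force oracle for overlap resolution: repeatedly pick the match
# with the highest bit score (ties: lower start, then repeat_id), keep it
# and delete everything overlapping it.
oracle_resolve <- function(m) {
  kept <- m[0, ]
  pool <- m
  while (nrow(pool) > 0) {
    o <- order(-pool$bit_score, pool$start, pool$repeat_id)
    best <- pool[o[1], ]
    kept <- rbind(kept, best)
    ov <- pool$start < best$end & best$start < pool$end
    pool <- pool[!ov, ]
  }
  kept[order(kept$start, kept$end, kept$repeat_id), ]
}

# Brute-force transitive-closure clustering oracle: link two intervals
# when their gap is <= array_gap, then take connected components.
oracle_cluster <- function(m, array_gap) {
  n <- nrow(m)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      gap <- max(0, max(m$start[i] - m$end[j], m$start[j] - m$end[i]))
      adj[i, j] <- gap <= array_gap
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# All permutations of 1..n (for full-enumeration permutation-test oracles).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# A small genome with one planted SRU and surrounding features, reused by
# several pipeline tests.
tiny_scan_fixture <- function(seed = 11) {
  set.seed(seed)
  db <- fixture_db()
  cfg <- benchmark_config(n_genomes = 2, genome_length = 20000)
  bench <- generate_benchmark(cfg, seed = seed, db = db)
  list(db = db, bench = bench)
}
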