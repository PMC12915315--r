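# Array detection, consensus, catalogs, diffs, self-targeting, clustering.

test_that("a planted 19-spacer array is recovered with exact structure", {
  sim <- simulate_genome(fixture_config(seed = 42))
  arrs <- detect_arrays(sim$genome)
  expect_length(arrs, 1L)
  a <- arrs[[1]]
  expect_equal(length(a$spacers), 19L)
  expect_equal(length(a$repeats), 20L)
  expect_equal(unique(nchar(a$repeats)), 36L)
  expect_equal(a$start, sim$truth$array$start)
  expect_equal(a$end, sim$truth$array$end)
  expect_identical(a$spacers, sim$truth$array$spacers)
  # concatenation invariant: units reconstruct the genome substring
  expect_identical(
    paste(tidy(a)$sequence, collapse = ""),
    substr(sim$genome$sequence, a$start + 1L, a$end)
  )
})

test_that("two repeat units do not form an array at min_units = 3", {
  withr::local_seed(13)
  rep36 <- rand_dna(36)
  toy <- plant_toy_array(4000, 1500, rep36, list(rand_dna(35)), seed = 13)
  # 2 repeats, 1 spacer planted
  expect_length(detect_arrays(toy$genome), 0L)
  expect_length(detect_arrays(toy$genome, min_units = 2L), 1L)
})

test_that("a randomized genome yields no arrays, consistent with a repeat census", {
  withr::local_seed(7)
  g <- genome_record("rnd", rand_dna(50000))
  expect_length(detect_arrays(g), 0L)
  # oracle: no duplicated 20-mer at an array-compatible period exists at all
  n <- nchar(g$sequence)
  kmers <- substring(g$sequence, 1:(n - 19L), 20:n)
  pos <- split(0:(n - 20L), kmers)
  pos <- pos[lengths(pos) >= 2L]
  periodic <- vapply(pos, function(p) {
    any(diff(sort(p)) >= 38L & diff(sort(p)) <= 100L)
  }, logical(1))
  expect_false(any(periodic))
})

test_that("consensus_repeat recovers the planted repeat despite terminal mutations", {
  a0 <- crispr_array("c", 0, 10, rep("ACGTACGTACGTACGTACGT", 3), rep("TTTTTTTTTTTTTTTTTT", 2))
  expect_equal(consensus_repeat(a0), "ACGTACGTACGTACGTACGT")

  # majority with a tie-free column: {A, A, G} -> A
  a1 <- crispr_array("c", 0, 10,
                     c("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAA", "GAAAAAAAAAAAAAAAAAAA"),
                     rep("TTTTTTTTTTTTTTTTTT", 2))
  expect_equal(substr(consensus_repeat(a1), 1, 1), "A")

  sim <- simulate_genome(fixture_config(
    seed = 3, array = list(terminal_repeat_mismatches = 2L)
  ))
  arrs <- detect_arrays(sim$genome)
  expect_length(arrs, 1L)
  expect_equal(length(arrs[[1]]$spacers), 19L)
  expect_equal(consensus_repeat(arrs[[1]]), sim$truth$array$repeat_seq)
})

test_that("spacer_stats reports counts, lengths and deterministic order", {
  expect_equal(nrow(spacer_stats(list())), 0L)
  sim <- simulate_genome(fixture_config(seed = 42))
  arrs <- detect_arrays(sim$genome)
  st <- spacer_stats(arrs)
  expect_equal(st$repeat_len, 36L)
  expect_equal(st$n_spacers, 19L)
  expect_equal(st$mean_spacer_len, mean(nchar(arrs[[1]]$spacers)))
})

test_that("spacer catalogs share ids across genomes and are bijective", {
  withr::local_seed(21)
  rep36 <- rand_dna(36)
  spacers <- replicate(6, rand_dna(35))
  mk <- function() {
    a <- crispr_array("c", 0, 10, rep(rep36, 7), spacers,
                      orientation = "leader-first")
    list(a)
  }
  cat2 <- build_spacer_catalog(list(gA = mk(), gB = mk()))
  expect_identical(cat2$profiles$gA, cat2$profiles$gB)

  dup <- crispr_array("c", 0, 10, rep(rep36, 5),
                      c(spacers[1], spacers[2], spacers[1], spacers[3]),
                      orientation = "leader-first")
  cat1 <- build_spacer_catalog(list(g = list(dup)))
  prof <- cat1$profiles$g[[1]]
  expect_equal(prof[1], prof[3])
  expect_equal(length(unique(prof)), 3L)

  # bijection: invert the map on 200 random spacers
  many <- unique(replicate(200, rand_dna(35)))
  arr <- crispr_array("c", 0, 10, rep(rep36, length(many) + 1L), many,
                      orientation = "leader-first")
  cc <- build_spacer_catalog(list(g = list(arr)))
  expect_equal(nrow(cc$ids), length(many))
  expect_equal(anyDuplicated(cc$ids$spacer_id), 0L)
  expect_equal(anyDuplicated(cc$ids$sequence), 0L)
  expect_identical(cc$ids$sequence[order(cc$ids$spacer_id)][cc$profiles$g[[1]]], many)
  # deterministic re-run
  expect_identical(cc, build_spacer_catalog(list(g = list(arr))))
})

test_that("repeated-spacer grouping follows the seed rule with transitive closure", {
  withr::local_seed(22)
  base <- rand_dna(35)
  mut <- function(s, p) {
    cyc <- c(A = "C", C = "G", G = "T", T = "A")
    paste0(substr(s, 1, p - 1), cyc[[substr(s, p, p)]], substr(s, p + 1, nchar(s)))
  }
  rep36 <- rand_dna(36)
  # one pair differing at 20 (outside seed), one spacer differing at 3 (inside)
  seqs <- c(base, mut(base, 20), mut(base, 3), rand_dna(35))
  arr <- crispr_array("c", 0, 10, rep(rep36, 5), seqs, orientation = "leader-first")
  groups <- find_repeated_spacers(build_spacer_catalog(list(g = list(arr))))
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$position, c(1L, 2L))

  # 12-spacer toy vs the transitive-closure oracle
  pool <- replicate(4, rand_dna(35))
  seqs12 <- c(pool[1], mut(pool[1], 15), mut(pool[1], 30), pool[2],
              mut(pool[2], 3), pool[3], pool[3], mut(pool[3], 9),
              pool[4], mut(pool[4], 1), mut(pool[4], 8), mut(pool[4], 35))
  arr12 <- crispr_array("c", 0, 10, rep(rep36, 13), seqs12,
                        orientation = "leader-first")
  got <- find_repeated_spacers(build_spacer_catalog(list(g = list(arr12))))
  comp <- closure_groups(seqs12)
  want <- Filter(function(ix) length(ix) >= 2L, split(seq_along(seqs12), comp))
  got_sets <- lapply(got, function(g) sort(g$position))
  expect_setequal(
    vapply(got_sets, paste, character(1), collapse = ","),
    vapply(want, function(ix) paste(sort(ix), collapse = ","), character(1))
  )
})

test_that("self-targeting scan finds planted protospacers and nothing else", {
  sim <- simulate_genome(fixture_config(seed = 42))
  arr <- detect_arrays(sim$genome)[[1]]
  expect_equal(nrow(self_target_scan(arr, sim$genome)), 0L)

  sim2 <- simulate_genome(fixture_config(seed = 11))
  arr2 <- detect_arrays(sim2$genome)[[1]]
  sim2 <- plant_offtarget(sim2, arr2$spacers[5], mismatch_position = 0L,
                          with_pam = TRUE)
  hits <- self_target_scan(arr2, sim2$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$spacer_index, 5L)
  expect_equal(hits$start, sim2$truth$decoys$start[1])
  expect_true(hits$pam_found)
  expect_equal(hits$strand, "+")

  # oracle: brute-force sliding-window comparison over both strands
  for (i in c(1L, 5L, 19L)) {
    sp <- arr2$spacers[i]
    plus <- naive_window_hits(sim2$genome$sequence, sp, 0L)
    minus <- naive_window_hits(sim2$genome$sequence, bio_revcomp(sp), 0L)
    outside <- function(s) s + nchar(sp) <= arr2$start | s >= arr2$end
    want <- sort(c(plus[outside(plus)], minus[outside(minus)]))
    got <- sort(hits$start[hits$spacer_index == i])
    expect_equal(got, want)
  }
})

test_that("array diffs recover insertions, deletions and duplications", {
  a <- 1:19
  b <- append(a, 101:103, after = 10)
  d <- diff_arrays(a, b)
  expect_equal(d$counts$n_insertions, 3L)
  expect_equal(d$counts$n_deletions, 0L)
  expect_equal(sort(d$insertions_in_B$id), 101:103)
  expect_equal(d$insertions_in_B$b_pos, 11:13)

  same <- diff_arrays(a, a)
  expect_equal(same$counts$n_insertions, 0L)
  expect_equal(same$counts$n_deletions, 0L)
  expect_equal(same$counts$n_shared, 19L)

  dup <- diff_arrays(c(1, 2, 2, 3), c(1, 2, 3))
  expect_true(2 %in% dup$duplicated_ids)
})

test_that("diff edit operations reconstruct B, and LCS matches exhaustive search", {
  withr::local_seed(31)
  for (i in 1:40) {
    a <- sample(1:4, sample(1:8, 1), replace = TRUE)
    b <- sample(1:4, sample(1:8, 1), replace = TRUE)
    d <- diff_arrays(a, b)
    expect_equal(d$counts$n_shared, lcs_exhaustive(a, b))
    expect_equal(apply_array_diff(a, d), b)
  }
})

test_that("protein dedup partitions at 100% identity in first-seen order", {
  seqs <- c(p1 = "MKV", p2 = "MKV", p3 = "MKI", p4 = "MKV", p5 = "MKV", p6 = "MKV")
  cl <- dedupe_proteins(seqs)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$n_members, c(5L, 1L))
  expect_equal(cl$representative_id, c("p1", "p3"))

  expect_equal(nrow(dedupe_proteins(character(0))), 0L)
  expect_error(dedupe_proteins(c(x = "MKZ")), class = "tig_alphabet_error")

  withr::local_seed(32)
  aa <- c("A","C","D","E","F","G","H","I","K","L")
  pool <- replicate(40, paste(sample(aa, 8, replace = TRUE), collapse = ""))
  many <- setNames(sample(pool, 500, replace = TRUE), sprintf("s%03d", 1:500))
  cl <- dedupe_proteins(many)
  oracle <- split(names(many), factor(many, levels = unique(many)))
  expect_equal(nrow(cl), length(oracle))
  expect_identical(cl$member_ids, unname(oracle))
})

test_that("pairwise identity is exact on known cases and matches exhaustive alignment", {
  expect_equal(pairwise_identity("MKVI", "MKVI"), 100)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  withr::local_seed(33)
  for (i in 1:40) {
    a <- rand_dna(sample(1:6, 1))
    b <- rand_dna(sample(1:6, 1))
    got <- pairwise_identity(a, b)
    expect_equal(got, exhaustive_align(a, b)$identity, info = paste(a, b))
    expect_equal(got, pairwise_identity(b, a))
    expect_true(got >= 0 && got <= 100)
    expect_equal(got == 100, identical(a, b))
  }
  m <- identity_matrix(c(x = "MKVLI", y = "MKVLI", z = "MAVLI"))
  expect_true(isSymmetric(m))
  expect_equal(m["x", "y"], 100)
})
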