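# Cassette assembly, restriction-site census, vector assembly, primers,
# GenBank export.

test_that("cassette assembly concatenates parts with two repeat features", {
  withr::local_seed(61)
  leader <- rand_dna(150); rep36 <- rand_dna(36)
  spacer <- rand_dna(35); term <- rand_dna(40)
  cas <- assemble_cassette(leader, rep36, spacer, term)
  expect_equal(nchar(cas$full_seq), 297L)  # 150 + 36 + 35 + 36 + 40
  expect_identical(cas$full_seq, paste0(leader, rep36, spacer, rep36, term))
  expect_equal(sum(cas$features$type == "repeat_region"), 2L)
  expect_equal(cas$features$end - cas$features$start,
               c(150L, 36L, 35L, 36L, 40L))

  expect_error(assemble_cassette(leader, rep36, rand_dna(34), term),
               class = "tig_length_error")
  expect_error(assemble_cassette(leader, rand_dna(19), spacer, term),
               class = "tig_length_error")
})

test_that("restriction-site counts cover strands, palindromes and junctions", {
  expect_equal(count_restriction_sites("ACATGTACATGT", "ACATGT", circular = FALSE)$count, 2L)

  # non-palindromic motif found on the minus strand
  res <- count_restriction_sites("CCCCTCATGACCCC", "TCATGA", circular = FALSE)
  expect_equal(res$count, 1L)
  res2 <- count_restriction_sites(paste0("CCCC", revcomp("GACTCA"), "CCCC"),
                                  "GACTCA", circular = FALSE)
  expect_equal(res2$count, 1L)
  expect_equal(res2$positions$strand, "-")

  # junction-spanning site on a circular plasmid
  withr::local_seed(62)
  circ <- paste0("TGT", rand_dna(300), "ACA")  # ACATGT spans the origin
  while (grepl("ACATGT", circ, fixed = TRUE)) {
    circ <- sub("ACATGT", "ACATCT", circ, fixed = TRUE)  # drop linear copies
  }
  expect_equal(count_restriction_sites(circ, "ACATGT", circular = TRUE)$count, 1L)
  expect_equal(count_restriction_sites(circ, "ACATGT", circular = FALSE)$count, 0L)

  # rotation invariance on a circular sequence
  seq <- paste0(rand_dna(200), "ACATGT", rand_dna(100), "TCATGA", rand_dna(50))
  n <- nchar(seq)
  base_counts <- vapply(c("ACATGT", "TCATGA"), function(m) {
    count_restriction_sites(seq, m, circular = TRUE)$count
  }, integer(1))
  for (rot in c(3L, 57L, 201L, n - 4L)) {
    rotated <- paste0(substr(seq, rot + 1L, n), substr(seq, 1L, rot))
    for (m in names(base_counts)) {
      expect_equal(count_restriction_sites(rotated, m, circular = TRUE)$count,
                   base_counts[[m]], info = sprintf("rot=%d motif=%s", rot, m))
    }
  }
})

test_that("vector assembly is scar-free with correct kind and bookkeeping", {
  withr::local_seed(63)
  bb <- make_backbone(seed = 63)
  cas <- assemble_cassette(rand_dna(150), rand_dna(36), rand_dna(35), rand_dna(40))
  g <- genome_record("host", rand_dna(8000))
  tpl <- extract_arms(g, interval("host", 3000L, 3500L), arm_len = 600L)

  sv <- assemble_vector(bb$record, cas, array_site_motif = bb$sites[["array_site"]],
                        template_site_motif = bb$sites[["template_site"]],
                        backbone_features = bb$features, name = "scr")
  expect_equal(sv$kind, "screening")
  expect_equal(nchar(sv$full_seq),
               nchar(bb$record$sequence) + nchar(cas$full_seq))

  ev <- assemble_vector(bb$record, cas, template = tpl,
                        array_site_motif = bb$sites[["array_site"]],
                        template_site_motif = bb$sites[["template_site"]],
                        backbone_features = bb$features, name = "edt")
  expect_equal(ev$kind, "editing")
  expect_equal(nchar(ev$full_seq),
               nchar(bb$record$sequence) + nchar(cas$full_seq) + tpl$total_len)

  # re-digestion view: the construct is backbone-prefix + insert + backbone-suffix
  cut <- sv$insertions$position[1]
  expect_identical(substr(sv$full_seq, cut + 1L, cut + nchar(cas$full_seq)),
                   cas$full_seq)
  expect_identical(paste0(substr(sv$full_seq, 1L, cut),
                          substr(sv$full_seq, cut + nchar(cas$full_seq) + 1L,
                                 nchar(sv$full_seq))),
                   bb$record$sequence)

  # annotated features slice out their own sequences
  f <- tidy(ev)
  sp_row <- f[f$part == "spacer", ]
  expect_identical(substr(ev$full_seq, sp_row$start + 1L, sp_row$end), cas$spacer)
  up_row <- f[f$part == "up_arm", ]
  expect_identical(substr(ev$full_seq, up_row$start + 1L, up_row$end), tpl$up_arm)

  # absent or duplicated site motifs are errors with counts
  err <- tryCatch(
    assemble_vector(bb$record, cas, array_site_motif = "GGGCCCGG"),
    condition = identity
  )
  expect_s3_class(err, "tig_site_error")
  expect_equal(err$count, 0L)
})

test_that("screen primers sit outside the arms and obey amplicon arithmetic", {
  withr::local_seed(64)
  g <- genome_record("c", rand_dna(10000))
  del <- interval("c", 4000L, 4500L)
  pp <- design_screen_primers(g, del, arm_len = 600L)
  expect_equal(pp$amplicon_wt - pp$amplicon_edited, 500L)
  expect_lte(pp$fwd_end, del$start - 600L)   # strictly outside the up arm
  expect_gte(pp$rev_start, del$end + 600L)   # strictly outside the down arm
  expect_identical(pp$fwd, substr(g$sequence, pp$fwd_start + 1L, pp$fwd_end))
  expect_identical(pp$rev, bio_revcomp(substr(g$sequence, pp$rev_start + 1L, pp$rev_end)))
  # Wallace rule on both primers
  for (s in c(pp$fwd, pp$rev)) {
    ch <- strsplit(s, "")[[1]]
    expect_equal(2L * sum(ch %in% c("A", "T")) + 4L * sum(ch %in% c("G", "C")),
                 if (s == pp$fwd) pp$tm_fwd else pp$tm_rev)
  }
  gc <- mean(strsplit(pp$fwd, "")[[1]] %in% c("G", "C"))
  expect_true(gc >= 0.40 && gc <= 0.60)
  # a 20-mer at 50% GC melts at 60 by the Wallace rule
  even <- strrep("ATGC", 5)
  ch <- strsplit(even, "")[[1]]
  expect_equal(2L * sum(ch %in% c("A", "T")) + 4L * sum(ch %in% c("G", "C")), 60L)

  # no admissible primer when the flanks are GC deserts
  flat <- genome_record("c", paste0(strrep("A", 5000), strrep("T", 5000)))
  expect_error(design_screen_primers(flat, interval("c", 4000L, 4500L), 600L),
               class = "tig_primer_error")
})

test_that("amplicon arithmetic holds across 100 random fixtures", {
  for (seed in 1:100) {
    withr::local_seed(seed)
    g <- genome_record("c", rand_dna(6000))
    dlen <- sample(200:800, 1)
    d0 <- sample(2200:2600, 1)
    del <- interval("c", d0, d0 + dlen)
    arm <- sample(c(600L, 1000L), 1)
    pp <- tryCatch(design_screen_primers(g, del, arm_len = arm),
                   tig_primer_error = function(e) NULL)
    expect_false(is.null(pp), info = sprintf("seed %d", seed))
    expect_equal(pp$amplicon_wt - pp$amplicon_edited, dlen,
                 info = sprintf("seed %d", seed))
    expect_equal(pp$amplicon_edited,
                 (pp$rev_end - pp$fwd_start) - dlen,
                 info = sprintf("seed %d", seed))
  }
})

test_that("GenBank export annotates all parts and round-trips", {
  withr::local_seed(65)
  bb <- make_backbone(seed = 65)
  cas <- assemble_cassette(rand_dna(150), rand_dna(36), rand_dna(35), rand_dna(40))
  g <- genome_record("host", rand_dna(8000))
  tpl <- extract_arms(g, interval("host", 3000L, 3500L), arm_len = 600L)
  sv <- assemble_vector(bb$record, cas, array_site_motif = bb$sites[["array_site"]],
                        template_site_motif = bb$sites[["template_site"]],
                        backbone_features = bb$features, name = "scr")
  ev <- assemble_vector(bb$record, cas, template = tpl,
                        array_site_motif = bb$sites[["array_site"]],
                        template_site_motif = bb$sites[["template_site"]],
                        backbone_features = bb$features, name = "edt")
  p <- withr::local_tempfile(fileext = ".gb")

  export_vector_genbank(sv, p)
  parsed <- parse_genbank_mini(p)
  expect_identical(parsed$sequence, sv$full_seq)
  labels <- vapply(parsed$features, `[[`, character(1), "label")
  expect_true(all(c("leader", "repeat_1", "spacer", "repeat_2", "terminator",
                    "abr_marker") %in% labels))
  expect_false(any(c("up_arm", "down_arm") %in% labels))

  export_vector_genbank(ev, p)
  parsed <- parse_genbank_mini(p)
  labels <- vapply(parsed$features, `[[`, character(1), "label")
  expect_true(all(c("up_arm", "down_arm") %in% labels))
  # feature spans survive the round trip
  for (i in seq_len(nrow(ev$features))) {
    j <- which(labels == ev$features$part[i])
    expect_equal(parsed$features[[j]]$from, ev$features$start[i] + 1L)
    expect_equal(parsed$features[[j]]$to, ev$features$end[i])
  }
})
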