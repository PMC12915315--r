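# Deterministic synthetic fixtures: genomes with embedded genes, one planted
# CRISPR array, planted PAM/protospacer sites, off-target decoys, and toy
# circular backbones with unique cloning sites. Every planted feature is
# recorded in a truth table so scanners can be tested for exact recovery.
#
# Background sequence is i.i.d. at the configured GC content with no repeats
# beyond the planted ones, keeping brute-force oracles unambiguous. The
# default planted array mirrors the modal Type I-G architecture: a 36 bp
# repeat and 19 spacers of 34-37 nt, mutually distinct over the 8 nt seed.

#' Fixture configuration
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical fixtures.
#' @param genome_len Genome length in bp (default 60000, large enough for
#'   1 kb homology arms plus primer search spans around every gene).
#' @param gc Background GC fraction.
#' @param genes List of \code{list(length =, strand =)} entries.
#' @param array List with \code{repeat_len} (default 36), \code{n_spacers}
#'   (default 19), \code{spacer_len_range} (default 34-37) and
#'   \code{terminal_repeat_mismatches} (substitutions planted into the last
#'   repeat; default 0).
#' @param planted_pams Per-gene planted PAM counts, \code{list(plus =, minus =)}.
#' @param decoys List of \code{list(mismatch_position =, with_pam =)} off-target
#'   decoys planted against the first planted protospacer of gene 1.
#' @param pam PAM sequence planted (default \code{"TAT"}).
#' @param spacer_len Protospacer length for planted PAM sites (default 35).
#' @return A list of class \code{fixture_config}.
#' @export
fixture_config <- function(seed = 42L, genome_len = 60000L, gc = 0.5,
                           genes = list(
                             list(length = 1500L, strand = "+"),
                             list(length = 1500L, strand = "-"),
                             list(length = 1500L, strand = "+")
                           ),
                           array = list(
                             repeat_len = 36L, n_spacers = 19L,
                             spacer_len_range = c(34L, 37L),
                             terminal_repeat_mismatches = 0L
                           ),
                           planted_pams = list(plus = 2L, minus = 2L),
                           decoys = list(),
                           pam = "TAT", spacer_len = 35L) {
  defaults_array <- list(repeat_len = 36L, n_spacers = 19L,
                         spacer_len_range = c(34L, 37L),
                         terminal_repeat_mismatches = 0L)
  array <- utils::modifyList(defaults_array, array)
  structure(
    list(seed = as.integer(seed), genome_len = as.integer(genome_len), gc = gc,
         genes = genes, array = array, planted_pams = planted_pams,
         decoys = decoys, pam = pam, spacer_len = as.integer(spacer_len)),
    class = "fixture_config"
  )
}

# run `expr` under a fixed seed, restoring the caller's RNG state afterwards
with_fixture_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute: base at 1-based position p cycles A->C->G->T->A
substitute_base <- function(seq, p) {
  cyc <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  b <- substr(seq, p, p)
  paste0(substr(seq, 1L, p - 1L), cyc[[b]], substr(seq, p + 1L, nchar(seq)))
}

splice_in <- function(seq, at, part) {
  # overwrite seq with `part` starting at 0-based position `at`
  paste0(substr(seq, 1L, at), part, substr(seq, at + nchar(part) + 1L, nchar(seq)))
}

#' Simulate a genome with planted ground truth
#'
#' Lays out the configured genes, one CRISPR array and any decoys at
#' deterministic, well-separated positions over an i.i.d. background; plants
#' PAM sites inside each gene; and records every planted feature with exact
#' coordinates in a truth table.
#'
#' @param config A \code{\link{fixture_config}}.
#' @return A list of class \code{tig_sim}: \code{genome}
#'   (\code{\link{genome_record}}), \code{genes} (tibble), \code{truth} (list
#'   with \code{array}, \code{pams}, \code{decoys}), \code{config}.
#' @export
simulate_genome <- function(config = fixture_config()) {
  with_fixture_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  margin <- 2500L
  n <- config$genome_len
  seq <- random_dna(n, config$gc)

  # deterministic layout: genes, then the array, then decoy slots
  cursor <- margin
  gene_rows <- list()
  for (i in seq_along(config$genes)) {
    g <- config$genes[[i]]
    if (cursor + g$length + margin > n) {
      tig_error("tig_config_error", "genome too short to pack the requested genes")
    }
    gene_rows[[i]] <- tibble::tibble(
      gene_id = sprintf("gene%02d", i), contig_id = "synth_contig",
      start = cursor, end = cursor + as.integer(g$length), strand = g$strand
    )
    cursor <- cursor + as.integer(g$length) + margin
  }
  genes <- if (length(gene_rows) > 0L) dplyr::bind_rows(gene_rows) else
    tibble::tibble(gene_id = character(), contig_id = character(),
                   start = integer(), end = integer(), strand = character())

  # planted CRISPR array: exact internal repeats, seed-distinct spacers
  arr <- config$array
  repeat_seq <- random_dna(arr$repeat_len, config$gc)
  spacers <- character(0)
  seeds_used <- character(0)
  while (length(spacers) < arr$n_spacers) {
    sl <- sample(arr$spacer_len_range[1]:arr$spacer_len_range[2], 1L)
    sp <- random_dna(sl, config$gc)
    sd <- substr(sp, 1L, 8L)
    if (sd %in% seeds_used) next
    spacers <- c(spacers, sp)
    seeds_used <- c(seeds_used, sd)
  }
  units <- character(0)
  for (i in seq_along(spacers)) units <- c(units, repeat_seq, spacers[i])
  last_repeat <- repeat_seq
  if (arr$terminal_repeat_mismatches > 0L) {
    mut_at <- sample(seq_len(arr$repeat_len), arr$terminal_repeat_mismatches)
    for (p in mut_at) last_repeat <- substitute_base(last_repeat, p)
  }
  units <- c(units, last_repeat)
  array_seq <- paste(units, collapse = "")
  array_start <- cursor
  if (array_start + nchar(array_seq) + margin > n) {
    tig_error("tig_config_error", "genome too short for the planted array")
  }
  seq <- splice_in(seq, array_start, array_seq)
  cursor <- array_start + nchar(array_seq) + margin

  # planted PAM sites inside genes, near the start codon in gene orientation
  # (mirrored for minus-strand genes) so they fall inside default deletion
  # windows; "coding" sites sit on the gene strand, "template" sites opposite
  pam_rows <- list()
  plen <- nchar(config$pam)
  plant_pam <- function(seq, gi, offset, pam_strand) {
    if (genes$strand[gi] == "+") {
      ps <- genes$start[gi] + offset
      strand <- pam_strand
    } else {
      ps <- genes$end[gi] - offset - plen
      strand <- if (pam_strand == "+") "-" else "+"
    }
    motif <- if (strand == "+") config$pam else revcomp(config$pam)
    seq <- splice_in(seq, ps, motif)
    row <- tibble::tibble(
      gene_id = genes$gene_id[gi], strand = strand, pam_start = ps,
      proto_start = if (strand == "+") ps + plen else ps - config$spacer_len,
      proto_end = if (strand == "+") ps + plen + config$spacer_len else ps
    )
    list(seq = seq, row = row)
  }
  for (gi in seq_len(nrow(genes))) {
    np <- config$planted_pams$plus %||% 0L
    nm <- config$planted_pams$minus %||% 0L
    for (j in seq_len(np)) {
      r <- plant_pam(seq, gi, 40L + (j - 1L) * 160L, "+")
      seq <- r$seq
      pam_rows[[length(pam_rows) + 1L]] <- r$row
    }
    for (j in seq_len(nm)) {
      r <- plant_pam(seq, gi, 120L + (j - 1L) * 160L, "-")
      seq <- r$seq
      pam_rows[[length(pam_rows) + 1L]] <- r$row
    }
  }
  pams <- if (length(pam_rows) > 0L) dplyr::bind_rows(pam_rows) else
    tibble::tibble(gene_id = character(), strand = character(),
                   pam_start = integer(), proto_start = integer(),
                   proto_end = integer())

  sim <- structure(
    list(
      genome = genome_record("synth_contig", seq),
      genes = genes,
      truth = list(
        array = list(
          start = array_start, end = array_start + nchar(array_seq),
          repeat_seq = repeat_seq, spacers = spacers,
          n_repeats = length(spacers) + 1L
        ),
        pams = pams,
        decoys = tibble::tibble(
          start = integer(), end = integer(), strand = character(),
          mismatch_position = integer(), with_pam = logical(),
          spacer_seq = character()
        )
      ),
      config = config,
      free_cursor = cursor
    ),
    class = "tig_sim"
  )
  for (d in config$decoys) {
    sim <- plant_offtarget(
      sim, first_planted_protospacer(sim),
      d$mismatch_position, d$with_pam
    )
  }
  sim
}

#' @export
print.tig_sim <- function(x, ...) {
  cat(sprintf(
    "<tig_sim> %d bp genome, %d gene(s), planted array with %d spacers, %d decoy(s)\n",
    nchar(x$genome$sequence), nrow(x$genes),
    length(x$truth$array$spacers), nrow(x$truth$decoys)
  ))
  invisible(x)
}

#' Spacer sequence of the first planted plus-strand PAM site of gene 1
#' @param sim A \code{tig_sim}.
#' @return The 35 nt protospacer sequence (plus strand).
#' @export
first_planted_protospacer <- function(sim) {
  p <- sim$truth$pams
  p <- p[p$strand == "+", ]
  if (nrow(p) == 0L) tig_error("tig_structure_error", "no planted plus-strand PAM")
  substr(sim$genome$sequence, p$proto_start[1] + 1L, p$proto_end[1])
}

#' Plant an off-target decoy copy of a spacer
#'
#' Inserts one copy of the spacer carrying a single substitution at the stated
#' PAM-proximal position, with or without an upstream PAM, at the next free
#' slot outside genes and array; the decoy is recorded in the truth table.
#'
#' @param sim A \code{tig_sim} from \code{\link{simulate_genome}}.
#' @param spacer_seq The spacer to copy.
#' @param mismatch_position 1-based PAM-proximal position of the substitution
#'   (0 for an exact copy).
#' @param with_pam Plant the PAM immediately upstream (\code{TRUE}) or a
#'   non-PAM triplet (\code{FALSE}).
#' @return The updated \code{tig_sim}.
#' @export
plant_offtarget <- function(sim, spacer_seq, mismatch_position, with_pam) {
  config <- sim$config
  decoy <- spacer_seq
  if (mismatch_position > 0L) decoy <- substitute_base(decoy, mismatch_position)
  upstream <- if (with_pam) config$pam else "GCC"
  insert <- paste0(upstream, decoy)
  at <- sim$free_cursor
  if (at + nchar(insert) + 500L > nchar(sim$genome$sequence)) {
    tig_error("tig_placement_error", "no room left outside genes and array")
  }
  sim$genome$sequence <- splice_in(sim$genome$sequence, at, insert)
  proto_start <- at + nchar(upstream)
  sim$truth$decoys <- rbind(
    sim$truth$decoys,
    tibble::tibble(
      start = proto_start, end = proto_start + nchar(decoy), strand = "+",
      mismatch_position = as.integer(mismatch_position), with_pam = with_pam,
      spacer_seq = spacer_seq
    )
  )
  sim$free_cursor <- at + nchar(insert) + 500L
  sim
}

#' Derive array id profiles with known edits
#'
#' Applies an ordered list of edits to a base spacer-id profile, recording the
#' ground truth for \code{\link{diff_arrays}} testing.
#'
#' @param base_profile Vector of spacer ids.
#' @param edits List of \code{list(op =, position =, ids =)} entries with op
#'   one of \code{"insert"} (ids inserted after \code{position}),
#'   \code{"delete"} (\code{position} removed) or \code{"duplicate"} (id at
#'   \code{position} re-inserted after \code{position}).
#' @return A list with \code{base}, \code{variant} and \code{edits} (tibble of
#'   the applied operations).
#' @export
make_array_variants <- function(base_profile, edits) {
  prof <- base_profile
  rows <- list()
  for (e in edits) {
    op <- e$op
    pos <- e$position
    if (op == "insert") {
      prof <- append(prof, e$ids, after = pos)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        op = "insert", position = pos, n = length(e$ids)
      )
    } else if (op == "delete") {
      prof <- prof[-pos]
      rows[[length(rows) + 1L]] <- tibble::tibble(op = "delete", position = pos, n = 1L)
    } else if (op == "duplicate") {
      prof <- append(prof, prof[pos], after = pos)
      rows[[length(rows) + 1L]] <- tibble::tibble(op = "duplicate", position = pos, n = 1L)
    } else {
      tig_error("tig_structure_error", sprintf("unknown edit op '%s'", op))
    }
  }
  list(base = base_profile, variant = prof, edits = dplyr::bind_rows(rows))
}

#' Generate a random cassette part avoiding given motifs
#'
#' Draws an i.i.d. DNA sequence that contains none of the listed motifs on
#' either strand — useful for synthetic leaders and terminators that must not
#' carry the cloning-site motifs used for vector assembly. Uses the current
#' RNG state.
#'
#' @param n Length in bp.
#' @param avoid Character vector of motifs to exclude (both strands).
#' @param gc GC fraction.
#' @return A DNA string of length \code{n}.
#' @export
random_cassette_part <- function(n, avoid = c("ACATGT", "TCATGA"), gc = 0.5) {
  for (i in 1:1000) {
    s <- random_dna(n, gc)
    hit <- any(vapply(avoid, function(m) {
      grepl(m, s, fixed = TRUE) || grepl(revcomp(m), s, fixed = TRUE)
    }, logical(1)))
    if (!hit) return(s)
  }
  tig_error("tig_config_error", "could not draw a part avoiding the given motifs")
}

#' Generate a toy circular backbone with unique cloning sites
#'
#' Random circular plasmid sequence from which all occurrences of the named
#' site motifs (and their reverse complements) are scrubbed, then one copy of
#' each motif is planted, so each occurs exactly once. Standard part
#' annotations (two origins and a resistance marker) are placed at fixed
#' positions.
#'
#' @param seed Integer RNG seed.
#' @param len Backbone length in bp (default 3000, >= 2500 required).
#' @param sites Named character vector of site motifs (default PciI
#'   \code{ACATGT} for the cassette, BspHI \code{TCATGA} for the template).
#' @param gc Background GC fraction.
#' @return A list: \code{record} (circular \code{\link{genome_record}}),
#'   \code{features} (tibble), \code{sites}.
#' @export
make_backbone <- function(seed = 1L, len = 3000L,
                          sites = c(array_site = "ACATGT", template_site = "TCATGA"),
                          gc = 0.5) {
  if (len < 2500L) tig_error("tig_config_error", "backbone length must be >= 2500")
  seq <- with_fixture_seed(seed, random_dna(len, gc))
  scrub <- function(seq, motif) {
    for (iter in 1:200) {
      hits <- count_restriction_sites(seq, motif, circular = TRUE)
      if (hits$count == 0L) return(seq)
      p <- hits$positions$start[1]
      mid <- (p + 2L) %% len + 1L  # 1-based position of the motif's 3rd base
      seq <- substitute_base(seq, mid)
    }
    tig_error("tig_config_error", "failed to scrub site motif from backbone")
  }
  for (m in sites) seq <- scrub(seq, m)
  plant_at <- floor(len * seq(1L, length(sites)) / (length(sites) + 1L))
  for (i in seq_along(sites)) seq <- splice_in(seq, plant_at[i], sites[[i]])
  for (m in sites) {
    if (count_restriction_sites(seq, m, circular = TRUE)$count != 1L) {
      tig_error("tig_config_error", "planted site motif is not unique; choose another seed")
    }
  }
  list(
    record = genome_record("toy_backbone", seq, topology = "circular"),
    features = tibble::tibble(
      part = c("ori_ecoli", "ori_host", "abr_marker"),
      type = c("rep_origin", "rep_origin", "CDS"),
      start = c(100L, 800L, 1600L), end = c(700L, 1500L, 2260L)
    ),
    sites = sites
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
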