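# Guide design: PAM scanning, protospacer/spacer extraction, genome-wide
# off-target screening under the PAM-proximal seed rule, and spacer panel
# selection.
#
# Position numbering: protospacer position 1 is the base immediately 3' of
# the PAM on the PAM strand, so the seed (default positions 1-8) is the
# PAM-proximal segment. A candidate off-target site is BLOCKING when the PAM
# is present and the seed is a perfect match.

#' Scan a genome region for PAM sites
#'
#' Reports every occurrence of the PAM, on both strands, whose full PAM lies
#' inside \code{region} and whose downstream protospacer of
#' \code{spacer_len} nt fits within the contig. Minus-strand sites are PAMs
#' read 5'->3' on the reverse strand. Results are sorted by genomic position,
#' plus strand first at ties.
#'
#' @param genome A \code{\link{genome_record}}.
#' @param region Optional \code{\link{interval}} restricting the scan
#'   (default: whole contig).
#' @param pam PAM sequence read 5'->3' on its strand (default \code{"TAT"}).
#' @param spacer_len Protospacer length that must fit downstream (default 35).
#' @return A tibble with columns \code{contig_id}, \code{start}, \code{end}
#'   (genomic plus-strand span of the PAM), \code{strand}, \code{pam_seq},
#'   \code{proto_start}, \code{proto_end} (genomic span of the protospacer).
#' @export
scan_pam_sites <- function(genome, region = NULL, pam = "TAT", spacer_len = 35L) {
  seq <- genome$sequence
  n <- nchar(seq)
  plen <- nchar(pam)
  r0 <- if (is.null(region)) 0L else max(0L, region$start)
  r1 <- if (is.null(region)) n else min(n, region$end)

  plus <- exact_matches(seq, pam)
  plus <- plus[plus >= r0 & plus + plen <= r1 & plus + plen + spacer_len <= n]
  minus <- exact_matches(seq, revcomp(pam))
  minus <- minus[minus >= r0 & minus + plen <= r1 & minus - spacer_len >= 0L]

  out <- tibble::tibble(
    contig_id = genome$contig_id,
    start = c(plus, minus),
    end = c(plus, minus) + plen,
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    pam_seq = pam,
    proto_start = c(plus + plen, minus - spacer_len),
    proto_end = c(plus + plen + spacer_len, minus)
  )
  out <- out[order(out$start, out$strand), ]
  tibble::as_tibble(out)
}

#' Extract spacer candidates for a gene
#'
#' One candidate per PAM site whose protospacer lies wholly inside the search
#' window (default: gene span plus 200 bp on each side). The spacer sequence
#' is the protospacer read 5'->3' on the PAM strand, always exactly
#' \code{spacer_len} nt. \code{target_strand} is \code{"coding"} when the
#' protospacer resides on the gene's coding strand and \code{"template"}
#' otherwise; \code{offset_in_gene} is the gene-oriented signed offset of the
#' PAM-proximal protospacer base from the start codon.
#'
#' @param genome A \code{\link{genome_record}}.
#' @param gene One row of a gene table (list or one-row data frame with
#'   \code{gene_id}, \code{start}, \code{end}, \code{strand}).
#' @param window Optional \code{\link{interval}} search window.
#' @param spacer_len Spacer length in nt (default 35).
#' @param pam PAM sequence (default \code{"TAT"}).
#' @param flank Window flank around the gene when \code{window} is NULL.
#' @return A tibble of class \code{guide_candidates} with columns
#'   \code{candidate_id}, \code{gene_id}, \code{contig_id}, \code{spacer_seq},
#'   \code{pam_start}, \code{strand}, \code{proto_start}, \code{proto_end},
#'   \code{target_strand}, \code{offset_in_gene}.
#' @export
extract_candidates <- function(genome, gene, window = NULL, spacer_len = 35L,
                               pam = "TAT", flank = 200L) {
  gene <- as.list(gene)
  n <- nchar(genome$sequence)
  if (is.null(window)) {
    window <- interval(
      genome$contig_id,
      max(0L, gene$start - flank), min(n, gene$end + flank)
    )
  }
  empty <- tibble::tibble(
    candidate_id = character(), gene_id = character(), contig_id = character(),
    spacer_seq = character(), pam_start = integer(), strand = character(),
    proto_start = integer(), proto_end = integer(),
    target_strand = character(), offset_in_gene = integer()
  )
  class(empty) <- c("guide_candidates", class(empty))
  if (window$end - window$start < spacer_len + nchar(pam)) {
    tig_warning(
      "tig_empty_window",
      sprintf("window [%d, %d) too small for PAM + %d nt protospacer",
              window$start, window$end, spacer_len)
    )
    return(empty)
  }
  sites <- scan_pam_sites(genome, pam = pam, spacer_len = spacer_len)
  keep <- sites$proto_start >= window$start & sites$proto_end <= window$end
  sites <- sites[keep, ]
  if (nrow(sites) == 0L) return(empty)

  spacer_seq <- vapply(seq_len(nrow(sites)), function(i) {
    extract_interval(genome, interval(
      genome$contig_id, sites$proto_start[i], sites$proto_end[i],
      strand = sites$strand[i]
    ))
  }, character(1))
  pam_proximal <- ifelse(sites$strand == "+", sites$proto_start, sites$proto_end - 1L)
  offset <- if (gene$strand == "+") {
    pam_proximal - gene$start
  } else {
    (gene$end - 1L) - pam_proximal
  }
  out <- tibble::tibble(
    candidate_id = sprintf("%s_%d%s", gene$gene_id, sites$start, sites$strand),
    gene_id = gene$gene_id,
    contig_id = genome$contig_id,
    spacer_seq = spacer_seq,
    pam_start = sites$start,
    strand = sites$strand,
    proto_start = sites$proto_start,
    proto_end = sites$proto_end,
    target_strand = ifelse(sites$strand == gene$strand, "coding", "template"),
    offset_in_gene = as.integer(offset)
  )
  class(out) <- c("guide_candidates", class(out))
  out
}

#' Genome-wide off-target hits for one spacer
#'
#' Every window on either strand with at most \code{max_total_mismatches}
#' substitutions relative to the spacer is reported, excluding windows that
#' overlap \code{exclude} (typically the on-target protospacer). Each hit
#' carries PAM presence immediately 5' on the hit strand, 1-based PAM-proximal
#' mismatch positions, the count of mismatches inside the seed, and a
#' \code{blocking} flag (PAM present and zero seed mismatches).
#'
#' @param spacer_seq The spacer (5'->3', PAM-proximal end first).
#' @param genome A \code{\link{genome_record}}.
#' @param pam PAM sequence (default \code{"TAT"}).
#' @param seed_len Seed length in nt (default 8).
#' @param max_total_mismatches Maximum substitutions per reported hit
#'   (default 5).
#' @param exclude Optional \code{\link{interval}}; overlapping hits are
#'   dropped.
#' @return A tibble with columns \code{contig_id}, \code{start}, \code{end},
#'   \code{strand}, \code{pam_found}, \code{mismatches},
#'   \code{seed_mismatches}, \code{mismatch_positions} (list column),
#'   \code{blocking}.
#' @export
off_target_hits <- function(spacer_seq, genome, pam = "TAT", seed_len = 8L,
                            max_total_mismatches = 5L, exclude = NULL) {
  spacer_seq <- clean_dna(spacer_seq)
  hits <- genome_spacer_matches(genome, spacer_seq, max_total_mismatches, pam,
                                seed_len = seed_len)
  if (!is.null(exclude) && nrow(hits) > 0L) {
    keep <- !(hits$start < exclude$end & hits$end > exclude$start)
    hits <- hits[keep, ]
  }
  hits$blocking <- hits$pam_found & hits$seed_mismatches == 0L
  hits
}

#' Classify two spacers as functionally equivalent or distinct
#'
#' Spacers are distinct when they differ at any position inside the
#' PAM-proximal seed (1-based positions 1 to \code{seed_len}); differences
#' outside the seed leave targeting intact, so such spacers are equivalent.
#'
#' @param spacer_a,spacer_b Equal-length spacer sequences.
#' @param seed_len Seed length in nt (default 8).
#' @return \code{"equivalent"} or \code{"distinct"}.
#' @export
seed_equivalent <- function(spacer_a, spacer_b, seed_len = 8L) {
  if (nchar(spacer_a) != nchar(spacer_b)) {
    tig_error("tig_length_error", "spacers must have equal length")
  }
  mm <- mismatch_positions(toupper(spacer_a), toupper(spacer_b))
  if (any(mm <= seed_len)) "distinct" else "equivalent"
}

#' Screen candidates genome-wide for off-targets
#'
#' Runs \code{\link{off_target_hits}} for each candidate (excluding its own
#' protospacer together with its PAM) and appends summary columns.
#'
#' @param candidates A \code{guide_candidates} tibble.
#' @param genome The host \code{\link{genome_record}}.
#' @param pam,seed_len,max_total_mismatches Passed to
#'   \code{\link{off_target_hits}}.
#' @return The input tibble with added columns \code{n_off_targets},
#'   \code{n_blocking}, \code{has_blocking} and a list column
#'   \code{off_targets}.
#' @export
screen_candidates <- function(candidates, genome, pam = "TAT", seed_len = 8L,
                              max_total_mismatches = 5L) {
  plen <- nchar(pam)
  hits <- lapply(seq_len(nrow(candidates)), function(i) {
    excl_start <- if (candidates$strand[i] == "+") {
      candidates$pam_start[i]
    } else {
      candidates$proto_start[i]
    }
    excl_end <- if (candidates$strand[i] == "+") {
      candidates$proto_end[i]
    } else {
      candidates$pam_start[i] + plen
    }
    off_target_hits(
      candidates$spacer_seq[i], genome, pam = pam, seed_len = seed_len,
      max_total_mismatches = max_total_mismatches,
      exclude = interval(candidates$contig_id[i], excl_start, excl_end)
    )
  })
  candidates$off_targets <- hits
  candidates$n_off_targets <- vapply(hits, nrow, integer(1))
  candidates$n_blocking <- vapply(hits, function(h) sum(h$blocking), integer(1))
  candidates$has_blocking <- candidates$n_blocking > 0L
  candidates
}

#' Select a spacer panel
#'
#' Picks \code{k} admissible candidates maximizing pairwise genomic
#' separation: among all k-subsets, the one with the largest minimum pairwise
#' protospacer distance wins, ties broken by larger total separation, then by
#' genomic position. Selection is invariant to input order.
#'
#' @param candidates A screened \code{guide_candidates} tibble (see
#'   \code{\link{screen_candidates}}).
#' @param k Number of spacers to select (default 3).
#' @param require_no_blocking Drop candidates with blocking off-target hits
#'   (default TRUE).
#' @return A \code{guide_candidates} tibble of \code{k} rows sorted by genomic
#'   position.
#' @export
select_spacers <- function(candidates, k = 3L, require_no_blocking = TRUE) {
  if (require_no_blocking && !"has_blocking" %in% names(candidates)) {
    tig_error(
      "tig_structure_error",
      "candidates must be screened (screen_candidates) before selection"
    )
  }
  cand <- candidates[order(candidates$proto_start, candidates$strand), ]
  reasons <- rep(NA_character_, nrow(cand))
  admissible <- rep(TRUE, nrow(cand))
  if (require_no_blocking) {
    admissible <- !cand$has_blocking
    reasons[!admissible] <- "blocking off-target hit"
  }
  pool <- cand[admissible, ]
  if (nrow(pool) < k) {
    tig_error(
      "tig_insufficient_candidates_error",
      sprintf("only %d admissible candidate(s) for k = %d", nrow(pool), k),
      rejected = tibble::tibble(
        candidate_id = cand$candidate_id[!admissible],
        reason = reasons[!admissible]
      )
    )
  }
  if (nrow(pool) == k) return(pool)
  mid <- (pool$proto_start + pool$proto_end) / 2
  combos <- utils::combn(nrow(pool), k)
  best <- NULL
  for (ci in seq_len(ncol(combos))) {
    ix <- combos[, ci]
    d <- stats::dist(mid[ix])
    score <- c(min(d), sum(d))
    if (is.null(best) || score[1] > best$score[1] ||
        (score[1] == best$score[1] && score[2] > best$score[2])) {
      best <- list(ix = ix, score = score)
    }
  }
  pool[best$ix, ]
}
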