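# Knockout design: deletion window planning, homology-arm extraction, edited
# allele construction and counterselection (escape) validation.
#
# The default deletion removes 100 bp upstream of the start codon (promoter
# and proximal regulatory sequence) plus 400 bp of coding sequence - a 500 bp
# window. When PAM availability forces a chosen protospacer (plus its PAM)
# outside that window, the window is minimally extended on that side so the
# deletion removes every targeted site; that is what makes the edited allele
# escape Cascade targeting while wild-type alleles stay counterselectable.

#' Default deletion window for a gene
#'
#' The gene-oriented window \code{[start - upstream_bp, start + coding_bp)},
#' mirrored for minus-strand genes, in genomic plus-strand coordinates.
#'
#' @param gene One row of a gene table.
#' @param upstream_bp,coding_bp Window components (bp).
#' @return An \code{\link{interval}}.
#' @export
default_deletion_window <- function(gene, upstream_bp = 100L, coding_bp = 400L) {
  gene <- as.list(gene)
  if (gene$strand == "+") {
    interval(gene$contig_id, gene$start - upstream_bp, gene$start + coding_bp)
  } else {
    interval(gene$contig_id, gene$end - coding_bp, gene$end + upstream_bp)
  }
}

#' Plan a knockout deletion window
#'
#' Computes the gene-oriented default window
#' \code{[start - upstream_bp, start + coding_bp)} (mirrored for minus-strand
#' genes) and minimally extends it so every chosen protospacer together with
#' its PAM lies inside the deletion.
#'
#' @param genome A \code{\link{genome_record}} (used for bounds checking).
#' @param gene One row of a gene table (\code{gene_id}, \code{start},
#'   \code{end}, \code{strand}).
#' @param spacers A \code{guide_candidates} tibble of the spacers to cover.
#' @param upstream_bp bp removed 5' of the start codon (default 100).
#' @param coding_bp bp removed within the coding region (default 400).
#' @param pam PAM sequence (its 3 bp are covered together with each
#'   protospacer).
#' @return An object of class \code{deletion_design}: \code{gene_id},
#'   \code{contig_id}, \code{deletion} (an \code{\link{interval}}),
#'   \code{upstream_bp}, \code{coding_bp}, \code{length},
#'   \code{covered_protospacers}, \code{expanded}.
#' @export
plan_deletion <- function(genome, gene, spacers, upstream_bp = 100L,
                          coding_bp = 400L, pam = "TAT") {
  gene <- as.list(gene)
  n <- nchar(genome$sequence)
  w <- default_deletion_window(gene, upstream_bp, coding_bp)
  w0 <- w$start
  w1 <- w$end
  plen <- nchar(pam)
  if (nrow(spacers) > 0L) {
    site_start <- ifelse(spacers$strand == "+", spacers$pam_start, spacers$proto_start)
    site_end <- ifelse(spacers$strand == "+", spacers$proto_end, spacers$pam_start + plen)
    new0 <- min(w0, min(site_start))
    new1 <- max(w1, max(site_end))
  } else {
    new0 <- w0; new1 <- w1
  }
  expanded <- new0 < w0 || new1 > w1
  if (new0 < 0L || new1 > n) {
    tig_error(
      "tig_design_error",
      sprintf("deletion window [%d, %d) falls outside the contig (length %d)",
              new0, new1, n)
    )
  }
  len <- new1 - new0
  up_bp <- if (gene$strand == "+") gene$start - new0 else new1 - gene$end
  structure(
    list(
      gene_id = gene$gene_id,
      contig_id = genome$contig_id,
      deletion = interval(genome$contig_id, new0, new1),
      upstream_bp = as.integer(up_bp),
      coding_bp = as.integer(len - up_bp),
      length = as.integer(len),
      covered_protospacers = if (nrow(spacers) > 0L) spacers$candidate_id else character(0),
      expanded = expanded
    ),
    class = "deletion_design"
  )
}

#' @export
print.deletion_design <- function(x, ...) {
  cat(sprintf(
    "<deletion_design> %s: delete %s:[%d, %d) (%d bp = %d upstream + %d coding)%s\n",
    x$gene_id, x$contig_id, x$deletion$start, x$deletion$end, x$length,
    x$upstream_bp, x$coding_bp,
    if (x$expanded) " [window expanded to cover protospacers]" else ""
  ))
  invisible(x)
}

#' Extract homology arms around a deletion
#'
#' The upstream arm ends at \code{deletion$start} and the downstream arm
#' begins at \code{deletion$end}; arms abut the deletion with no gap. The
#' edited-allele junction is the 40-mer spanning the fusion point (last 20 nt
#' of the up arm plus first 20 nt of the down arm).
#'
#' @param genome A \code{\link{genome_record}}.
#' @param deletion The deletion \code{\link{interval}}.
#' @param arm_len Homology arm length in bp; presets are 600 (short, 1.2 kb
#'   total template) and 1000 (long, 2 kb total).
#' @return An object of class \code{editing_template}: \code{arm_len},
#'   \code{up_arm}, \code{down_arm}, \code{total_len}, \code{edited_junction},
#'   \code{deletion}, \code{contig_id}.
#' @export
extract_arms <- function(genome, deletion, arm_len = 600L) {
  n <- nchar(genome$sequence)
  max_up <- deletion$start
  max_down <- n - deletion$end
  if (arm_len > max_up || arm_len > max_down) {
    tig_error(
      "tig_flank_error",
      sprintf("insufficient flank for %d bp arms (max feasible %d)",
              arm_len, min(max_up, max_down)),
      max_feasible = min(max_up, max_down)
    )
  }
  up <- substr(genome$sequence, deletion$start - arm_len + 1L, deletion$start)
  down <- substr(genome$sequence, deletion$end + 1L, deletion$end + arm_len)
  structure(
    list(
      arm_len = as.integer(arm_len),
      up_arm = up,
      down_arm = down,
      total_len = 2L * as.integer(arm_len),
      edited_junction = paste0(
        substr(up, arm_len - 19L, arm_len), substr(down, 1L, 20L)
      ),
      deletion = deletion,
      contig_id = genome$contig_id
    ),
    class = "editing_template"
  )
}

#' @export
print.editing_template <- function(x, ...) {
  cat(sprintf(
    "<editing_template> %d bp arms (%d bp total) around %s:[%d, %d)\n",
    x$arm_len, x$total_len, x$contig_id, x$deletion$start, x$deletion$end
  ))
  invisible(x)
}

#' Edited allele sequence
#'
#' @param genome A \code{\link{genome_record}}.
#' @param deletion The deletion \code{\link{interval}}.
#' @return The contig sequence with the deletion excised (a DNA string whose
#'   length is the contig length minus the deletion length).
#' @export
edited_allele <- function(genome, deletion) {
  n <- nchar(genome$sequence)
  if (deletion$start < 0L || deletion$end > n) {
    tig_error("tig_out_of_bounds_error", "deletion outside contig")
  }
  paste0(
    substr(genome$sequence, 1L, deletion$start),
    substr(genome$sequence, deletion$end + 1L, n)
  )
}

#' Validate that an allele escapes CRISPR targeting
#'
#' Counterselection logic: an allele passes when none of the design's spacers
#' retains a BLOCKING site in it (PAM present and perfect seed match, within
#' the mismatch budget). The wild-type allele must FAIL for its own spacers -
#' that is what drives counterselection - and the edited allele must PASS.
#'
#' @param allele_seq Allele DNA sequence (string).
#' @param spacers A \code{guide_candidates} tibble (column \code{spacer_seq})
#'   or a character vector of spacer sequences.
#' @param pam,seed_len,max_total_mismatches Screening parameters (see
#'   \code{\link{off_target_hits}}).
#' @return An object of class \code{escape_report}: \code{pass} (logical) and
#'   \code{residual_sites} (tibble of blocking hits with a
#'   \code{spacer_index} column).
#' @export
validate_escape <- function(allele_seq, spacers, pam = "TAT", seed_len = 8L,
                            max_total_mismatches = 5L) {
  seqs <- if (is.character(spacers)) spacers else spacers$spacer_seq
  allele <- genome_record("allele", allele_seq)
  residual <- list()
  for (i in seq_along(seqs)) {
    hits <- off_target_hits(
      seqs[i], allele, pam = pam, seed_len = seed_len,
      max_total_mismatches = max_total_mismatches
    )
    hits <- hits[hits$blocking, ]
    if (nrow(hits) > 0L) {
      hits$spacer_index <- i
      residual[[length(residual) + 1L]] <- hits
    }
  }
  residual <- if (length(residual) > 0L) dplyr::bind_rows(residual) else
    tibble::tibble()
  structure(
    list(pass = nrow(residual) == 0L, residual_sites = residual),
    class = "escape_report"
  )
}

#' @export
print.escape_report <- function(x, ...) {
  if (x$pass) {
    cat("<escape_report> PASS: no spacer retains a blocking site\n")
  } else {
    cat(sprintf(
      "<escape_report> FAIL: %d residual blocking site(s)\n",
      nrow(x$residual_sites)
    ))
  }
  invisible(x)
}
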