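# In-silico vector assembly: the synthetic CRISPR cassette (leader + two
# consensus repeats flanking the spacer + terminator), scar-free insertion
# into a circular backbone at unique restriction sites, restriction-site
# census, verification primer design, and annotated GenBank export.
#
# Scar-free insertion models the final, sequence-verified assembly outcome of
# overlap-based cloning (SOE/HiFi): only the resulting sequence matters.
# Convention: inserts go immediately 3' of the plus-strand site motif.

#' Assemble a synthetic CRISPR cassette
#'
#' \code{full_seq = leader + repeat + spacer + repeat + terminator}: the
#' native leader promoter drives a minimal array of two consensus repeats
#' flanking one targeting spacer, closed by a Rho-independent terminator.
#'
#' @param leader Leader (promoter) sequence.
#' @param repeat_seq Consensus repeat (length must be within
#'   \code{repeat_len_range}).
#' @param spacer Targeting spacer (length must equal \code{spacer_len}).
#' @param terminator Terminator sequence.
#' @param spacer_len Required spacer length (default 35).
#' @param repeat_len_range Allowed repeat length range (default 20-50).
#' @return An object of class \code{crispr_cassette} with \code{full_seq} and
#'   a \code{features} tibble of part intervals (0-based half-open).
#' @export
assemble_cassette <- function(leader, repeat_seq, spacer, terminator,
                              spacer_len = 35L, repeat_len_range = c(20L, 50L)) {
  leader <- clean_dna(leader); repeat_seq <- clean_dna(repeat_seq)
  spacer <- clean_dna(spacer); terminator <- clean_dna(terminator)
  if (nchar(spacer) != spacer_len) {
    tig_error(
      "tig_length_error",
      sprintf("spacer length %d != required %d", nchar(spacer), spacer_len)
    )
  }
  if (nchar(repeat_seq) < repeat_len_range[1] || nchar(repeat_seq) > repeat_len_range[2]) {
    tig_error(
      "tig_length_error",
      sprintf("repeat length %d outside [%d, %d]", nchar(repeat_seq),
              repeat_len_range[1], repeat_len_range[2])
    )
  }
  parts <- c(leader = leader, repeat_1 = repeat_seq, spacer = spacer,
             repeat_2 = repeat_seq, terminator = terminator)
  ends <- cumsum(nchar(parts))
  starts <- c(0L, ends[-length(ends)])
  structure(
    list(
      leader = leader, repeat_seq = repeat_seq, spacer = spacer,
      terminator = terminator,
      full_seq = paste(parts, collapse = ""),
      features = tibble::tibble(
        part = names(parts),
        type = c("regulatory", "repeat_region", "misc_feature",
                 "repeat_region", "terminator"),
        start = as.integer(starts), end = as.integer(ends)
      )
    ),
    class = "crispr_cassette"
  )
}

#' @export
print.crispr_cassette <- function(x, ...) {
  cat(sprintf(
    "<crispr_cassette> %d bp (leader %d + repeat %d + spacer %d + repeat %d + terminator %d)\n",
    nchar(x$full_seq), nchar(x$leader), nchar(x$repeat_seq), nchar(x$spacer),
    nchar(x$repeat_seq), nchar(x$terminator)
  ))
  invisible(x)
}

#' Count restriction-site motif occurrences
#'
#' Scans both strands (palindromic motifs counted once) and, for circular
#' sequences, includes junction-spanning matches; counts are invariant under
#' rotation of a circular sequence.
#'
#' @param seq DNA sequence.
#' @param motif Recognition motif (length >= 4).
#' @param circular Treat the sequence as circular.
#' @return A list with \code{count} and a \code{positions} tibble
#'   (\code{start} 0-based on the plus strand, modulo length when circular;
#'   \code{strand}).
#' @export
count_restriction_sites <- function(seq, motif, circular = FALSE) {
  seq <- clean_dna(seq); motif <- clean_dna(motif)
  if (nchar(motif) < 4L) {
    tig_error("tig_length_error", "motif must be at least 4 nt")
  }
  n <- nchar(seq)
  m <- nchar(motif)
  subject <- if (circular) paste0(seq, substr(seq, 1L, m - 1L)) else seq
  rc <- revcomp(motif)
  plus <- exact_matches(subject, motif)
  pos <- tibble::tibble(start = plus, strand = rep("+", length(plus)))
  if (rc != motif) {
    minus <- exact_matches(subject, rc)
    pos <- rbind(pos, tibble::tibble(start = minus, strand = rep("-", length(minus))))
  }
  if (circular) pos$start <- pos$start %% n
  pos <- unique(pos[order(pos$start, pos$strand), ])
  list(count = nrow(pos), positions = tibble::as_tibble(pos))
}

#' Assemble a screening or editing vector
#'
#' Inserts the cassette (and, for editing vectors, the editing template) into
#' a circular backbone at named restriction-site motifs. Each motif must occur
#' exactly once in the construct at the time of its use; insertion is
#' scar-free, so the final length is the backbone length plus the summed part
#' lengths. The vector kind is \code{"editing"} exactly when a template is
#' supplied.
#'
#' @param backbone A circular \code{\link{genome_record}}.
#' @param cassette A \code{\link{assemble_cassette}} result.
#' @param template Optional \code{\link{extract_arms}} result (editing
#'   template).
#' @param array_site_motif Unique motif at which the cassette is inserted
#'   (default PciI, \code{"ACATGT"}).
#' @param template_site_motif Unique motif at which the template is inserted
#'   (default BspHI, \code{"TCATGA"}).
#' @param name Vector name.
#' @param backbone_features Optional tibble of backbone part annotations
#'   (\code{part}, \code{type}, \code{start}, \code{end}).
#' @return An object of class \code{vector_design}: \code{name}, \code{kind},
#'   \code{backbone_id}, \code{insertions} (tibble), \code{full_seq}
#'   (circular), \code{features} (tibble).
#' @export
assemble_vector <- function(backbone, cassette, template = NULL,
                            array_site_motif = "ACATGT",
                            template_site_motif = "TCATGA",
                            name = "vector",
                            backbone_features = NULL) {
  if (backbone$topology != "circular") {
    tig_error("tig_structure_error", "backbone must be circular")
  }
  features <- if (is.null(backbone_features)) {
    tibble::tibble(part = character(), type = character(),
                   start = integer(), end = integer())
  } else {
    backbone_features
  }
  construct <- backbone$sequence
  insertions <- list()

  insert_part <- function(construct, features, part_seq, part_features, motif, part_name) {
    sites <- count_restriction_sites(construct, motif, circular = TRUE)
    if (sites$count != 1L) {
      tig_error(
        "tig_site_error",
        sprintf("site motif %s occurs %d time(s) in the construct; need exactly 1",
                motif, sites$count),
        count = sites$count
      )
    }
    cut <- sites$positions$start[1] + nchar(motif)  # insert 3' of plus-strand motif
    new_seq <- paste0(
      substr(construct, 1L, cut), part_seq,
      substr(construct, cut + 1L, nchar(construct))
    )
    # shift annotations at/after the cut, then add the part's own features
    shift <- nchar(part_seq)
    features$start <- ifelse(features$start >= cut, features$start + shift, features$start)
    features$end <- ifelse(features$end > cut, features$end + shift, features$end)
    part_features$start <- part_features$start + cut
    part_features$end <- part_features$end + cut
    list(
      seq = new_seq,
      features = rbind(features, part_features),
      record = tibble::tibble(part = part_name, site = motif, position = cut)
    )
  }

  st <- insert_part(construct, features, cassette$full_seq,
                    cassette$features, array_site_motif, "crispr_cassette")
  construct <- st$seq; features <- st$features
  insertions[[1L]] <- st$record

  kind <- "screening"
  if (!is.null(template)) {
    tpl_seq <- paste0(template$up_arm, template$down_arm)
    tpl_features <- tibble::tibble(
      part = c("up_arm", "down_arm"),
      type = c("misc_feature", "misc_feature"),
      start = c(0L, template$arm_len),
      end = c(template$arm_len, 2L * template$arm_len)
    )
    st <- insert_part(construct, features, tpl_seq, tpl_features,
                      template_site_motif, "editing_template")
    construct <- st$seq; features <- st$features
    insertions[[2L]] <- st$record
    kind <- "editing"
  }
  structure(
    list(
      name = name, kind = kind, backbone_id = backbone$contig_id,
      insertions = dplyr::bind_rows(insertions),
      full_seq = construct,
      features = features[order(features$start), ],
      circular = TRUE
    ),
    class = "vector_design"
  )
}

#' @export
print.vector_design <- function(x, ...) {
  cat(sprintf(
    "<vector_design> %s (%s): %s bp circular, %d annotated part(s)\n",
    x$name, x$kind, format(nchar(x$full_seq), big.mark = ","), nrow(x$features)
  ))
  invisible(x)
}

#' Tidy a vector design into its feature table
#' @param x A \code{vector_design}.
#' @param ... Unused.
#' @return The features tibble with a \code{length} column.
#' @method tidy vector_design
#' @export
tidy.vector_design <- function(x, ...) {
  f <- tibble::as_tibble(x$features)
  f$length <- f$end - f$start
  f
}

#' Design verification primers outside the homology arms
#'
#' Screens colonies for the edited allele with primers that hybridize outside
#' the homology arms, so only chromosomal (not plasmid-borne) alleles
#' amplify. Scanning moves outward from each arm's outer boundary; the first
#' window passing the length and GC filters becomes the primer. Melting
#' temperatures use the Wallace rule, 2(A+T) + 4(G+C).
#'
#' @param genome A \code{\link{genome_record}}.
#' @param deletion The deletion \code{\link{interval}}.
#' @param arm_len Homology arm length used in the editing template.
#' @param search_span bp searched beyond each arm (default 300).
#' @param len Two-element primer length range (default 18-25).
#' @param gc Two-element GC-fraction range (default 0.40-0.60).
#' @return An object of class \code{primer_pair}: \code{fwd}, \code{rev}
#'   (5'->3'), genomic coordinates, \code{tm_fwd}, \code{tm_rev},
#'   \code{amplicon_wt}, \code{amplicon_edited}, \code{deletion_len}.
#' @export
design_screen_primers <- function(genome, deletion, arm_len, search_span = 300L,
                                  len = c(18L, 25L), gc = c(0.40, 0.60)) {
  n <- nchar(genome$sequence)
  left_bound <- deletion$start - arm_len   # primers must end at or before this
  right_bound <- deletion$end + arm_len    # primers must start at or after this
  gc_frac <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(ch %in% c("G", "C"))
  }
  find_primer <- function(side) {
    for (gap in 0:(search_span - len[1])) {
      for (L in len[1]:len[2]) {
        if (side == "left") {
          s0 <- left_bound - gap - L
          s1 <- left_bound - gap
          if (s0 < 0L || gap + L > search_span) next
        } else {
          s0 <- right_bound + gap
          s1 <- right_bound + gap + L
          if (s1 > n || gap + L > search_span) next
        }
        w <- substr(genome$sequence, s0 + 1L, s1)
        g <- gc_frac(w)
        if (g >= gc[1] && g <= gc[2]) {
          return(list(start = s0, end = s1, seq = w))
        }
      }
    }
    tig_error(
      "tig_primer_error",
      sprintf("no admissible %s primer within %d bp of the arm boundary",
              side, search_span)
    )
  }
  fw <- find_primer("left")
  rv <- find_primer("right")
  wallace <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    2L * sum(ch %in% c("A", "T")) + 4L * sum(ch %in% c("G", "C"))
  }
  amp_wt <- rv$end - fw$start
  structure(
    list(
      fwd = fw$seq, rev = revcomp(rv$seq),
      fwd_start = fw$start, fwd_end = fw$end,
      rev_start = rv$start, rev_end = rv$end,
      tm_fwd = wallace(fw$seq), tm_rev = wallace(rv$seq),
      amplicon_wt = as.integer(amp_wt),
      amplicon_edited = as.integer(amp_wt - (deletion$end - deletion$start)),
      deletion_len = deletion$end - deletion$start
    ),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf(
    "<primer_pair> fwd %s (Tm %d), rev %s (Tm %d); amplicon WT %d bp, edited %d bp\n",
    x$fwd, x$tm_fwd, x$rev, x$tm_rev, x$amplicon_wt, x$amplicon_edited
  ))
  invisible(x)
}

#' Export a vector design as an annotated GenBank file
#'
#' @param vector A \code{\link{assemble_vector}} result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_vector_genbank <- function(vector, path) {
  feats <- lapply(seq_len(nrow(vector$features)), function(i) {
    list(
      label = vector$features$part[i],
      iv = interval("v", vector$features$start[i], vector$features$end[i]),
      type = vector$features$type[i]
    )
  })
  write_genbank(vector$name, vector$full_seq, feats, path, circular = TRUE)
}
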