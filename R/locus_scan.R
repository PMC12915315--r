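# CRISPR locus analytics: de novo array detection, repeat consensus, spacer
# statistics, cross-genome spacer catalogs, repeated-spacer grouping,
# self-targeting scans and array diffing.
#
# Detection strategy: arrays of an active Type I locus carry near-identical
# repeats, so exact 20-mer anchors shared between positions 38-100 bp apart
# seed candidate repeat chains; the repeat is grown to the maximal string
# common to every unit, spacers are the gaps, and a degenerate terminal repeat
# (a few substitutions) is searched at both ends. Deterministic and fully
# oracle-testable, which is what small/synthetic genome sets need.

#' Construct a CRISPR array object
#'
#' @param contig_id Contig the array lies on.
#' @param start,end 0-based half-open span of the array on the plus strand.
#' @param repeats Ordered character vector of repeat sequences (5'->3', plus
#'   strand); length must be \code{length(spacers) + 1}.
#' @param spacers Ordered character vector of spacer sequences.
#' @param orientation One of \code{"leader-first"}, \code{"leader-last"},
#'   \code{"unknown"}.
#' @return An object of class \code{crispr_array}.
#' @export
crispr_array <- function(contig_id, start, end, repeats, spacers,
                         orientation = c("unknown", "leader-first", "leader-last")) {
  orientation <- match.arg(orientation)
  if (length(repeats) != length(spacers) + 1L) {
    tig_error("tig_structure_error", "an array needs exactly one more repeat than spacers")
  }
  structure(
    list(
      contig_id = contig_id, start = as.integer(start), end = as.integer(end),
      repeats = repeats, spacers = spacers, orientation = orientation
    ),
    class = "crispr_array"
  )
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf(
    "<crispr_array> %s:[%d, %d)  %d repeats (%d bp), %d spacers, orientation %s\n",
    x$contig_id, x$start, x$end, length(x$repeats), nchar(x$repeats[1]),
    length(x$spacers), x$orientation
  ))
  invisible(x)
}

#' Tidy a CRISPR array into a unit table
#'
#' @param x A \code{crispr_array}.
#' @param ... Unused.
#' @return A tibble with one row per repeat/spacer unit in genomic order.
#' @method tidy crispr_array
#' @export
tidy.crispr_array <- function(x, ...) {
  units <- character(0); types <- character(0)
  for (i in seq_along(x$spacers)) {
    units <- c(units, x$repeats[i], x$spacers[i])
    types <- c(types, "repeat", "spacer")
  }
  units <- c(units, x$repeats[length(x$repeats)])
  types <- c(types, "repeat")
  ends <- x$start + cumsum(nchar(units))
  tibble::tibble(
    contig_id = x$contig_id, type = types,
    start = c(x$start, ends[-length(ends)]), end = ends, sequence = units
  )
}

#' Detect CRISPR arrays in a genome
#'
#' Finds maximal non-overlapping arrays of at least \code{min_units} repeats.
#' Internal repeats must be exactly identical; one degenerate terminal repeat
#' carrying up to \code{max_terminal_repeat_mismatches} substitutions is
#' allowed at either end of the chain. Arrays are reported 5'->3' on the plus
#' strand with orientation \code{"unknown"} (leader calling is left to
#' annotation or configuration).
#'
#' @param genome A \code{\link{genome_record}}.
#' @param min_units Minimum number of repeat units per array.
#' @param repeat_len Two-element allowed repeat length range (bp).
#' @param spacer_len Two-element allowed spacer length range (bp).
#' @param max_terminal_repeat_mismatches Substitutions tolerated in a terminal
#'   repeat.
#' @return A list of \code{\link{crispr_array}} objects (empty when none found),
#'   sorted by start position.
#' @export
detect_arrays <- function(genome, min_units = 3L, repeat_len = c(20L, 50L),
                          spacer_len = c(18L, 50L),
                          max_terminal_repeat_mismatches = 2L) {
  seq <- genome$sequence
  n <- nchar(seq)
  k <- repeat_len[1]
  if (n < 2L * k) return(list())
  min_period <- repeat_len[1] + spacer_len[1]
  max_period <- repeat_len[2] + spacer_len[2]

  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  pos_by_kmer <- split(0:(n - k), kmers)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= 2L]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]

  cands <- list()
  seen_spans <- character(0)
  for (P in pos_by_kmer) {
    P <- sort(P)
    gaps <- diff(P)
    ok <- gaps >= min_period & gaps <= max_period
    # maximal runs of anchors with admissible periods
    r <- rle(ok)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (ri in which(r$values)) {
      anchors <- P[idx_start[ri]:(idx_end[ri] + 1L)]
      cand <- build_array_candidate(
        chars, n, anchors, k, repeat_len, spacer_len,
        max_terminal_repeat_mismatches
      )
      if (is.null(cand)) next
      cand$contig_id <- genome$contig_id
      key <- sprintf("%d-%d", cand$start, cand$end)
      if (key %in% seen_spans) next
      seen_spans <- c(seen_spans, key)
      if (length(cand$repeats) >= min_units) cands[[length(cands) + 1L]] <- cand
    }
  }
  if (length(cands) == 0L) return(list())

  # greedy maximal non-overlapping selection: more units first, then longer span
  ord <- order(
    -vapply(cands, function(a) length(a$repeats), integer(1)),
    -vapply(cands, function(a) a$end - a$start, integer(1)),
    vapply(cands, function(a) a$start, integer(1))
  )
  accepted <- list()
  for (a in cands[ord]) {
    clash <- any(vapply(accepted, function(b) a$start < b$end && b$start < a$end, logical(1)))
    if (!clash) accepted[[length(accepted) + 1L]] <- a
  }
  accepted[order(vapply(accepted, function(a) a$start, integer(1)))]
}

# Grow one candidate array from a run of shared k-mer anchors. `chars` is the
# genome as a character vector; anchors are 0-based starts of the shared k-mer.
build_array_candidate <- function(chars, n, anchors, k, repeat_len, spacer_len, max_term_mm) {
  m <- length(anchors)
  gaps <- diff(anchors)
  max_len <- min(repeat_len[2], min(gaps) - spacer_len[1])
  if (max_len < k) return(NULL)
  # extend left while every unit agrees
  l <- 0L
  while (k + l < max_len && anchors[1] - l - 1L >= 0L) {
    col <- chars[anchors - l]  # 0-based anchors - (l+1) -> 1-based index anchors - l
    if (length(unique(col)) != 1L) break
    l <- l + 1L
  }
  r <- 0L
  while (k + l + r < max_len && anchors[m] + k + r < n) {
    col <- chars[anchors + k + r + 1L]
    if (length(unique(col)) != 1L) break
    r <- r + 1L
  }
  L <- k + l + r
  starts <- anchors - l
  sp <- diff(starts) - L
  if (any(sp < spacer_len[1] | sp > spacer_len[2])) return(NULL)
  rep_seq <- paste(chars[(starts[1] + 1L):(starts[1] + L)], collapse = "")

  # degenerate terminal repeat at either end
  term <- find_terminal_repeat(chars, n, rep_seq, L, starts, spacer_len, max_term_mm)
  starts <- term$starts

  repeats <- vapply(starts, function(s) {
    paste(chars[(s + 1L):(s + L)], collapse = "")
  }, character(1))
  spacers <- vapply(seq_len(length(starts) - 1L), function(i) {
    paste(chars[(starts[i] + L + 1L):(starts[i + 1L])], collapse = "")
  }, character(1))
  crispr_array(
    contig_id = NA_character_, start = starts[1], end = starts[length(starts)] + L,
    repeats = repeats, spacers = spacers, orientation = "unknown"
  )
}

# Search for one mismatched terminal repeat upstream of the first and
# downstream of the last exact unit; smallest mismatch count wins, ties broken
# by shortest spacer. Returns the (possibly extended) unit start vector.
find_terminal_repeat <- function(chars, n, rep_seq, L, starts, spacer_len, max_term_mm) {
  if (max_term_mm > 0L) {
    probe <- function(t) {
      sum(utf8ToInt(rep_seq) != utf8ToInt(paste(chars[(t + 1L):(t + L)], collapse = "")))
    }
    # downstream end
    best <- NULL
    e <- starts[length(starts)] + L
    for (sp in spacer_len[1]:spacer_len[2]) {
      t <- e + sp
      if (t + L > n) break
      mm <- probe(t)
      if (mm >= 1L && mm <= max_term_mm && (is.null(best) || mm < best$mm)) best <- list(t = t, mm = mm)
    }
    if (!is.null(best)) starts <- c(starts, best$t)
    # upstream end
    best <- NULL
    for (sp in spacer_len[1]:spacer_len[2]) {
      t <- starts[1] - sp - L
      if (t < 0L) break
      mm <- probe(t)
      if (mm >= 1L && mm <= max_term_mm && (is.null(best) || mm < best$mm)) best <- list(t = t, mm = mm)
    }
    if (!is.null(best)) starts <- c(best$t, starts)
  }
  list(starts = starts)
}

#' Column-majority consensus of an array's repeats
#'
#' The terminal repeats are truncated to the internal repeat length first; all
#' internal repeats must share one length. Per-column ties are broken in fixed
#' base order A < C < G < T.
#'
#' @param array A \code{\link{crispr_array}}.
#' @return The consensus repeat as a DNA string.
#' @export
consensus_repeat <- function(array) {
  reps <- array$repeats
  if (length(reps) == 0L) tig_error("tig_structure_error", "array has no repeats")
  lens <- nchar(reps)
  internal <- if (length(reps) > 2L) lens[2:(length(reps) - 1L)] else lens
  if (length(unique(internal)) != 1L) {
    tig_error("tig_length_error", "internal repeats have unequal lengths")
  }
  L <- internal[1]
  if (any(lens < L)) {
    tig_error("tig_length_error", "terminal repeat shorter than internal repeat length")
  }
  reps <- substr(reps, 1L, L)
  mat <- do.call(rbind, strsplit(reps, "", fixed = TRUE))
  paste(apply(mat, 2L, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(counts)[which.max(counts)]  # which.max takes the first max: A<C<G<T order
  }), collapse = "")
}

#' Per-array spacer statistics
#'
#' @param arrays A list of \code{\link{crispr_array}} objects.
#' @return A tibble with one row per array (ordered by contig then start):
#'   \code{contig_id}, \code{start}, \code{end}, \code{n_spacers},
#'   \code{mean_spacer_len}, \code{repeat_len}.
#' @export
spacer_stats <- function(arrays) {
  if (length(arrays) == 0L) {
    return(tibble::tibble(
      contig_id = character(), start = integer(), end = integer(),
      n_spacers = integer(), mean_spacer_len = double(), repeat_len = integer()
    ))
  }
  out <- tibble::tibble(
    contig_id = vapply(arrays, function(a) a$contig_id, character(1)),
    start = vapply(arrays, function(a) a$start, integer(1)),
    end = vapply(arrays, function(a) a$end, integer(1)),
    n_spacers = vapply(arrays, function(a) length(a$spacers), integer(1)),
    mean_spacer_len = vapply(arrays, function(a) mean(nchar(a$spacers)), double(1)),
    repeat_len = vapply(arrays, function(a) {
      as.integer(nchar(a$repeats[min(2L, length(a$repeats))]))
    }, integer(1))
  )
  dplyr::arrange(out, .data$contig_id, .data$start)
}

# Spacers of one array in catalog orientation: leader->trailer when the
# orientation is known, else each spacer canonicalized to the
# lexicographically smaller of itself and its reverse complement.
oriented_spacers <- function(array) {
  sp <- array$spacers
  switch(array$orientation,
    "leader-first" = sp,
    "leader-last" = rev(vapply(sp, revcomp, character(1), USE.NAMES = FALSE)),
    vapply(sp, function(s) {
      rc <- revcomp(s)
      if (rc < s) rc else s
    }, character(1), USE.NAMES = FALSE)
  )
}

#' Build a cross-genome spacer catalog
#'
#' Every distinct spacer sequence (in canonical orientation) receives one
#' integer id, assigned in first-seen order across genomes, so identical
#' spacers in different genomes share an id. Per-genome array profiles are the
#' ordered id lists.
#'
#' @param genome_arrays A named list (one element per genome) of lists of
#'   \code{\link{crispr_array}} objects.
#' @return An object of class \code{spacer_catalog}: \code{ids} (tibble of
#'   \code{spacer_id}, \code{sequence}), \code{profiles} (per genome, a list of
#'   integer id vectors, one per array).
#' @export
build_spacer_catalog <- function(genome_arrays) {
  if (is.null(names(genome_arrays)) || any(!nzchar(names(genome_arrays)))) {
    tig_error("tig_structure_error", "genome_arrays must be a named list")
  }
  map <- integer(0)
  profiles <- list()
  for (g in names(genome_arrays)) {
    profs <- list()
    for (a in genome_arrays[[g]]) {
      sp <- oriented_spacers(a)
      ids <- integer(length(sp))
      for (i in seq_along(sp)) {
        hit <- map[sp[i]]
        if (is.na(hit)) {
          hit <- length(map) + 1L
          map[sp[i]] <- hit
        }
        ids[i] <- hit
      }
      profs[[length(profs) + 1L]] <- ids
    }
    profiles[[g]] <- profs
  }
  structure(
    list(
      ids = tibble::tibble(spacer_id = unname(map), sequence = names(map)),
      profiles = profiles
    ),
    class = "spacer_catalog"
  )
}

#' @export
print.spacer_catalog <- function(x, ...) {
  cat(sprintf(
    "<spacer_catalog> %d distinct spacers across %d genome(s)\n",
    nrow(x$ids), length(x$profiles)
  ))
  invisible(x)
}

# Flat view of a catalog: one row per spacer occurrence.
catalog_occurrences <- function(catalog) {
  rows <- list()
  seq_by_id <- catalog$ids$sequence[order(catalog$ids$spacer_id)]
  for (g in names(catalog$profiles)) {
    for (ai in seq_along(catalog$profiles[[g]])) {
      ids <- catalog$profiles[[g]][[ai]]
      if (length(ids) == 0L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genome = g, array = ai, position = seq_along(ids),
        spacer_id = ids, sequence = seq_by_id[ids]
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      genome = character(), array = integer(), position = integer(),
      spacer_id = integer(), sequence = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Group repeated and functionally equivalent spacers
#'
#' Two spacer occurrences fall in the same group when their sequences are
#' identical or differ only outside the PAM-proximal seed (positions 1 to
#' \code{seed_len}); a mismatch inside the seed makes them functionally
#' distinct. Grouping is the transitive closure of this relation. Only groups
#' with at least two occurrences are returned.
#'
#' @param catalog A \code{\link{build_spacer_catalog}} result.
#' @param seed_len Seed length in nt (default 8).
#' @return A list of tibbles, one per group, with columns \code{genome},
#'   \code{array}, \code{position}, \code{spacer_id}, \code{sequence}.
#' @export
find_repeated_spacers <- function(catalog, seed_len = 8L) {
  occ <- catalog_occurrences(catalog)
  n <- nrow(occ)
  if (n < 2L) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- occ$sequence[i]; b <- occ$sequence[j]
      if (nchar(a) != nchar(b)) next
      if (a == b || seed_equivalent(a, b, seed_len) == "equivalent") {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  groups <- Filter(function(ix) length(ix) >= 2L, groups)
  lapply(unname(groups), function(ix) occ[ix, ])
}

#' Scan a genome for self-targeting by its own spacers
#'
#' Each spacer of the array is searched against the full genome on both
#' strands (up to \code{max_mismatches} substitutions); matches overlapping the
#' source array span are discarded. Each hit is annotated with whether the
#' configured PAM sits immediately 5' of the protospacer on the hit strand,
#' and with the 1-based PAM-proximal mismatch positions.
#'
#' @param array The source \code{\link{crispr_array}} (detected in
#'   \code{genome}).
#' @param genome The source \code{\link{genome_record}}.
#' @param pam PAM sequence (default \code{"TAT"}).
#' @param max_mismatches Maximum substitutions per hit (default 0).
#' @return A tibble with columns \code{spacer_index}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand}, \code{pam_found},
#'   \code{mismatches}, \code{mismatch_positions} (list column).
#' @export
self_target_scan <- function(array, genome, pam = "TAT", max_mismatches = 0L) {
  seqs <- array$spacers
  out <- list()
  for (i in seq_along(seqs)) {
    hits <- genome_spacer_matches(genome, seqs[i], max_mismatches, pam)
    if (nrow(hits) == 0L) next
    keep <- !(hits$start < array$end & hits$end > array$start)
    hits <- hits[keep, ]
    if (nrow(hits) == 0L) next
    hits$spacer_index <- i
    out[[length(out) + 1L]] <- hits
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      spacer_index = integer(), contig_id = character(), start = integer(),
      end = integer(), strand = character(), pam_found = logical(),
      mismatches = integer(), mismatch_positions = list()
    ))
  }
  res <- dplyr::bind_rows(out)
  res[, c("spacer_index", "contig_id", "start", "end", "strand",
          "pam_found", "mismatches", "mismatch_positions")]
}

# Both-strand mismatch-tolerant matches of one query in a genome, annotated
# with PAM presence immediately 5' on the hit strand and 1-based PAM-proximal
# mismatch positions. Shared by self_target_scan and off_target_hits.
genome_spacer_matches <- function(genome, query, max_mm, pam, seed_len = 0L) {
  seq <- genome$sequence
  n <- nchar(seq)
  L <- nchar(query)
  plen <- nchar(pam)
  rows <- list()

  plus <- window_mismatch_scan(seq, query, max_mm, seed_len)
  if (nrow(plus) > 0L) {
    plus$strand <- "+"
    plus$gstart <- plus$start
    rows[[length(rows) + 1L]] <- plus
  }
  rc <- revcomp(seq)
  minus <- window_mismatch_scan(rc, query, max_mm, seed_len)
  if (nrow(minus) > 0L) {
    minus$strand <- "-"
    minus$gstart <- n - minus$start - L
    rows[[length(rows) + 1L]] <- minus
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      contig_id = character(), start = integer(), end = integer(),
      strand = character(), pam_found = logical(), mismatches = integer(),
      seed_mismatches = integer(), mismatch_positions = list()
    ))
  }
  hits <- dplyr::bind_rows(rows)
  hit_seq <- character(nrow(hits))
  pam_found <- logical(nrow(hits))
  mmpos <- vector("list", nrow(hits))
  for (r in seq_len(nrow(hits))) {
    gs <- hits$gstart[r]
    if (hits$strand[r] == "+") {
      hs <- substr(seq, gs + 1L, gs + L)
      pam_found[r] <- gs >= plen && substr(seq, gs - plen + 1L, gs) == pam
    } else {
      hs <- revcomp(substr(seq, gs + 1L, gs + L))
      up <- gs + L
      pam_found[r] <- up + plen <= n &&
        revcomp(substr(seq, up + 1L, up + plen)) == pam
    }
    hit_seq[r] <- hs
    mmpos[[r]] <- mismatch_positions(query, hs)
  }
  tibble::tibble(
    contig_id = genome$contig_id,
    start = as.integer(hits$gstart), end = as.integer(hits$gstart + L),
    strand = hits$strand, pam_found = pam_found,
    mismatches = as.integer(hits$mismatches),
    seed_mismatches = as.integer(hits$seed_mismatches),
    mismatch_positions = mmpos
  )
}

#' Diff two array id profiles
#'
#' Aligns two ordered spacer-id profiles by longest common subsequence (ties
#' in the traceback broken toward the leftmost match in A), classifying
#' B-only ids as insertions, A-only ids as deletions, and flagging ids that
#' occur more than once in either profile as duplications.
#'
#' @param profile_a,profile_b Nonempty vectors of spacer ids.
#' @return An object of class \code{array_diff}: \code{matches},
#'   \code{shared_blocks}, \code{insertions_in_B}, \code{deletions_from_A}
#'   (tibbles with 1-based positions), \code{duplicated_ids}, and
#'   \code{counts} (named list: \code{n_shared}, \code{n_insertions},
#'   \code{n_deletions}, \code{n_duplicated_ids}).
#' @export
diff_arrays <- function(profile_a, profile_b) {
  a <- as.vector(profile_a); b <- as.vector(profile_b)
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) tig_error("tig_structure_error", "profiles must be nonempty")

  # suffix LCS table: L[i, j] = LCS length of a[i..la], b[j..lb]
  L <- matrix(0L, la + 1L, lb + 1L)
  for (i in la:1L) {
    for (j in lb:1L) {
      L[i, j] <- if (a[i] == b[j]) L[i + 1L, j + 1L] + 1L
                 else max(L[i + 1L, j], L[i, j + 1L])
    }
  }
  # forward traceback, matching each A element at the leftmost feasible B slot
  ai <- 1L; bj <- 1L
  ma <- integer(0); mb <- integer(0)
  while (ai <= la && bj <= lb && L[ai, bj] > 0L) {
    matched <- FALSE
    jj <- bj
    while (jj <= lb && L[ai, jj] == L[ai, bj]) {
      if (a[ai] == b[jj] && L[ai + 1L, jj + 1L] + 1L == L[ai, bj]) {
        matched <- TRUE
        break
      }
      jj <- jj + 1L
    }
    if (matched) {
      ma <- c(ma, ai); mb <- c(mb, jj)
      ai <- ai + 1L; bj <- jj + 1L
    } else {
      ai <- ai + 1L
    }
  }
  matches <- tibble::tibble(a_pos = ma, b_pos = mb, id = a[ma])
  ins <- setdiff(seq_len(lb), mb)
  del <- setdiff(seq_len(la), ma)
  blocks <- if (length(ma) > 0L) {
    brk <- c(TRUE, diff(ma) != 1L | diff(mb) != 1L)
    grp <- cumsum(brk)
    dplyr::summarise(
      dplyr::group_by(matches, grp = grp),
      a_start = min(.data$a_pos), a_end = max(.data$a_pos),
      b_start = min(.data$b_pos), b_end = max(.data$b_pos), .groups = "drop"
    )[, -1L]
  } else {
    tibble::tibble(a_start = integer(), a_end = integer(),
                   b_start = integer(), b_end = integer())
  }
  dup <- unique(c(a[duplicated(a)], b[duplicated(b)]))
  structure(
    list(
      matches = matches,
      shared_blocks = blocks,
      insertions_in_B = tibble::tibble(b_pos = ins, id = b[ins]),
      deletions_from_A = tibble::tibble(a_pos = del, id = a[del]),
      duplicated_ids = dup,
      counts = list(
        n_shared = length(ma), n_insertions = length(ins),
        n_deletions = length(del), n_duplicated_ids = length(dup)
      )
    ),
    class = "array_diff"
  )
}

#' @export
print.array_diff <- function(x, ...) {
  cat(sprintf(
    "<array_diff> %d shared, %d insertion(s) in B, %d deletion(s) from A, %d duplicated id(s)\n",
    x$counts$n_shared, x$counts$n_insertions, x$counts$n_deletions,
    x$counts$n_duplicated_ids
  ))
  invisible(x)
}

#' Apply an array diff to profile A
#'
#' Reconstructs profile B from profile A and a \code{\link{diff_arrays}}
#' result: deletions are removed from A and insertions re-added at their B
#' positions. Used to verify the diff's edit-consistency invariant.
#'
#' @param profile_a The original profile A.
#' @param diff An \code{array_diff}.
#' @return The reconstructed profile B.
#' @export
apply_array_diff <- function(profile_a, diff) {
  kept <- profile_a[setdiff(seq_along(profile_a), diff$deletions_from_A$a_pos)]
  lb <- length(kept) + nrow(diff$insertions_in_B)
  out <- vector(mode = mode(profile_a), length = lb)
  out[diff$insertions_in_B$b_pos] <- diff$insertions_in_B$id
  out[setdiff(seq_len(lb), diff$insertions_in_B$b_pos)] <- kept
  out
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y","X")

#' Collapse protein sequences at 100% identity
#'
#' Exact-identity clustering (equal length, identical residues). The
#' representative is the first-seen member and clusters are numbered in
#' first-seen order.
#'
#' @param seqs Named character vector of amino-acid sequences (X permitted).
#' @return A tibble with one row per cluster: \code{cluster_id},
#'   \code{representative_id}, \code{sequence}, \code{n_members},
#'   \code{member_ids} (list column).
#' @export
dedupe_proteins <- function(seqs) {
  if (length(seqs) == 0L) {
    return(tibble::tibble(
      cluster_id = integer(), representative_id = character(),
      sequence = character(), n_members = integer(), member_ids = list()
    ))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    tig_error("tig_structure_error", "protein sequences must be named")
  }
  seqs <- toupper(seqs)
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seqs)
  if (any(bad)) {
    tig_error(
      "tig_alphabet_error",
      sprintf("non-amino-acid character in sequence(s): %s",
              paste(names(seqs)[bad], collapse = ", "))
    )
  }
  key <- factor(seqs, levels = unique(seqs))
  groups <- split(names(seqs), key)
  tibble::tibble(
    cluster_id = seq_along(groups),
    representative_id = unname(vapply(groups, `[`, character(1), 1L)),
    sequence = levels(key),
    n_members = unname(lengths(groups)),
    member_ids = unname(groups)
  )
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear gap
#' -1 (end gaps penalized). Identity is matches divided by alignment columns,
#' times 100; among equally optimal alignments the one maximizing matches is
#' used, which makes the value symmetric and well defined.
#'
#' @param seq_a,seq_b Nonempty sequences (DNA or protein).
#' @param match,mismatch,gap Scoring parameters.
#' @return Percent identity in \code{[0, 100]}.
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    tig_error("tig_structure_error", "sequences must be nonempty")
  }
  A <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)  # best score
  M <- matrix(0L, n + 1L, m + 1L) # max matches among optimal alignments
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(A[i] == B, match, mismatch)
    eqv <- as.integer(A[i] == B)
    for (j in seq_len(m)) {
      sd <- S[i, j] + sub[j]
      su <- S[i, j + 1L] + gap
      sl <- S[i + 1L, j] + gap
      best <- max(sd, su, sl)
      mm <- -1L
      if (sd == best) mm <- max(mm, M[i, j] + eqv[j])
      if (su == best) mm <- max(mm, M[i, j + 1L])
      if (sl == best) mm <- max(mm, M[i + 1L, j])
      S[i + 1L, j + 1L] <- best
      M[i + 1L, j + 1L] <- mm
    }
  }
  score <- S[n + 1L, m + 1L]
  nmatch <- M[n + 1L, m + 1L]
  # With mismatch = 0 and linear gap penalty `gap`, an alignment with D
  # diagonal steps has score = match*nmatch + gap*(n + m - 2D), so D is
  # pinned once score and nmatch are fixed; columns = n + m - D.
  d <- (score - match * nmatch - gap * (n + m)) / (-2 * gap)
  columns <- n + m - d
  100 * nmatch / columns
}

#' Pairwise identity matrix for a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param ... Passed to \code{\link{pairwise_identity}}.
#' @return A symmetric numeric matrix of percent identities (diagonal 100).
#' @export
identity_matrix <- function(seqs, ...) {
  k <- length(seqs)
  out <- matrix(100, k, k, dimnames = list(names(seqs), names(seqs)))
  if (k < 2L) return(out)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      v <- pairwise_identity(seqs[[i]], seqs[[j]], ...)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}
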