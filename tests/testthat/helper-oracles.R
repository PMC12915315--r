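# Independent oracles and small fixture builders shared across tests. These
# deliberately use different algorithms (or different libraries) than the
# package code paths they check.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# reverse complement via Biostrings (independent of the package's chartr path)
bio_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# interval extraction by slicing the doubled string
doubled_slice <- function(seq, start, end, strand = NA) {
  dd <- paste0(seq, seq)
  out <- substr(dd, start + 1L, end)
  if (!is.na(strand) && strand == "-") out <- bio_revcomp(out)
  out
}

# mismatch-tolerant matches of `query` against both strands of `subject`,
# via Biostrings::matchPattern. Returns 0-based starts per strand.
bio_spacer_matches <- function(subject, query, max_mm) {
  subj <- Biostrings::DNAString(subject)
  plus <- Biostrings::start(Biostrings::matchPattern(
    query, subj, max.mismatch = max_mm, with.indels = FALSE
  )) - 1L
  minus_rc <- Biostrings::start(Biostrings::matchPattern(
    bio_revcomp(query), subj, max.mismatch = max_mm, with.indels = FALSE
  )) - 1L
  list(plus = sort(plus), minus = sort(minus_rc))
}

# naive per-window mismatch scan (loop + substr), independent of the
# vectorized engine
naive_window_hits <- function(subject, query, max_mm) {
  L <- nchar(query)
  starts <- integer(0)
  qs <- strsplit(query, "")[[1]]
  for (s in 0:(nchar(subject) - L)) {
    w <- strsplit(substr(subject, s + 1L, s + L), "")[[1]]
    if (sum(w != qs) <= max_mm) starts <- c(starts, s)
  }
  starts
}

# exhaustive LCS by subsequence enumeration (bitmask over the shorter profile)
lcs_exhaustive <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  is_subseq <- function(x, y) {
    j <- 1L
    for (v in y) {
      if (j <= length(x) && x[j] == v) j <- j + 1L
    }
    j > length(x)
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_along(a) - 1L)) > 0L)
    if (length(idx) <= best) next
    if (is_subseq(a[idx], b)) best <- length(idx)
  }
  best
}

# exhaustive global alignment: max score, and max matches among optimal
# alignments (recursive enumeration; for sequences of length <= 6)
exhaustive_align <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    # returns list of c(score, matches, diag) over all alignments of suffixes
    if (i > length(A) && j > length(B)) return(list(c(0, 0, 0)))
    out <- list()
    if (i <= length(A) && j <= length(B)) {
      for (r in rec(i + 1L, j + 1L)) {
        s <- if (A[i] == B[j]) match else mismatch
        out[[length(out) + 1L]] <- r + c(s, A[i] == B[j], 1)
      }
    }
    if (i <= length(A)) {
      for (r in rec(i + 1L, j)) out[[length(out) + 1L]] <- r + c(gap, 0, 0)
    }
    if (j <= length(B)) {
      for (r in rec(i, j + 1L)) out[[length(out) + 1L]] <- r + c(gap, 0, 0)
    }
    out
  }
  alns <- do.call(rbind, rec(1L, 1L))
  best <- max(alns[, 1])
  opt <- alns[alns[, 1] == best, , drop = FALSE]
  nmatch <- max(opt[, 2])
  d <- max(opt[opt[, 2] == nmatch, 3])
  list(score = best, matches = nmatch,
       identity = 100 * nmatch / (length(A) + length(B) - d))
}

# transitive-closure grouping oracle: repeated floyd-style closure over an
# explicit adjacency matrix
closure_groups <- function(seqs, seed_len = 8L) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- nchar(seqs[i]) == nchar(seqs[j]) &&
        !any(which(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]]) <= seed_len)
    }
  }
  repeat {
    new <- adj | (adj %*% adj > 0)
    if (identical(new, adj)) break
    adj <- new
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(adj[i, ])] <- cid
    }
  }
  comp
}

# minimal independent GenBank flat-file parser (LOCUS length, features with
# 1-based inclusive spans, ORIGIN sequence)
parse_genbank_mini <- function(path) {
  lines <- readLines(path)
  feats <- list()
  i <- 1L
  in_origin <- FALSE
  seq_chunks <- character(0)
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^ORIGIN", ln)) {
      in_origin <- TRUE
    } else if (in_origin) {
      if (grepl("^//", ln)) break
      seq_chunks <- c(seq_chunks, gsub("[^a-zA-Z]", "", ln))
    } else if (grepl("^     \\S+\\s+(complement\\()?\\d+\\.\\.\\d+\\)?", ln)) {
      type <- sub("^\\s+(\\S+).*", "\\1", ln)
      loc <- sub("^\\s+\\S+\\s+", "", ln)
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
      label <- NA_character_
      if (i + 1L <= length(lines) && grepl("/label=", lines[i + 1L])) {
        label <- sub('.*label="([^"]*)".*', "\\1", lines[i + 1L])
        i <- i + 1L
      }
      feats[[length(feats) + 1L]] <- list(
        type = type, from = nums[1], to = nums[2], strand = strand, label = label
      )
    }
    i <- i + 1L
  }
  list(sequence = toupper(paste(seq_chunks, collapse = "")), features = feats)
}

# a small genome with a hand-planted array: returns list(genome, truth)
plant_toy_array <- function(bg_len = 6000L, at = 2000L, repeat_seq, spacers,
                            seed = 99L) {
  withr::local_seed(seed)
  bg <- rand_dna(bg_len)
  units <- character(0)
  for (s in spacers) units <- c(units, repeat_seq, s)
  units <- c(units, repeat_seq)
  arr <- paste(units, collapse = "")
  seq <- paste0(substr(bg, 1, at), arr, substr(bg, at + nchar(arr) + 1L, bg_len))
  list(
    genome = genome_record("toy", seq),
    start = at, end = at + nchar(arr)
  )
}
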