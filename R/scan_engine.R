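# Shared windowed mismatch scan. Core primitive behind PAM scanning,
# off-target screening and self-targeting scans: slides a pattern over a
# subject and returns, per window, total and seed-region mismatch counts.
# Vectorized over windows (one pass per pattern position), so 100 kb subjects
# are cheap.

# subject, pattern: plain uppercase DNA strings. Returns a data.frame with
# 0-based window starts, mismatch totals and seed-region mismatch counts for
# windows with <= max_mm mismatches. Position 1 of the pattern is its 5' end.
window_mismatch_scan <- function(subject, pattern, max_mm = 0L, seed_len = 0L) {
  L <- nchar(pattern)
  n <- nchar(subject)
  nw <- n - L + 1L
  if (nw < 1L) {
    return(data.frame(start = integer(), mismatches = integer(), seed_mismatches = integer()))
  }
  g <- utf8ToInt(subject)
  p <- utf8ToInt(pattern)
  mm <- integer(nw)
  seed <- integer(nw)
  for (j in seq_len(L)) {
    neq <- g[j:(j + nw - 1L)] != p[j]
    mm <- mm + neq
    if (j <= seed_len) seed <- seed + neq
  }
  keep <- which(mm <= max_mm)
  data.frame(
    start = keep - 1L,
    mismatches = mm[keep],
    seed_mismatches = seed[keep]
  )
}

# 1-based positions at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  which(utf8ToInt(a) != utf8ToInt(b))
}

# All 0-based start positions of exact occurrences of `motif` in `subject`,
# including overlapping ones.
exact_matches <- function(subject, motif) {
  window_mismatch_scan(subject, motif, max_mm = 0L)$start
}
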