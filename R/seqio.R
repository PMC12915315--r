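# Sequence and coordinate primitives: FASTA and gene-table readers, GenBank
# emission, reverse complement, interval extraction. All internal coordinates
# are 0-based half-open; GenBank output converts to 1-based inclusive.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genome record
#'
#' A genome record holds one contig: an identifier, an uppercase DNA sequence
#' over \code{A,C,G,T,N}, and a topology flag. Plasmids are circular; genome
#' contigs default to linear.
#'
#' @param contig_id Contig identifier (single string).
#' @param sequence DNA sequence; lowercase is folded to uppercase and U to T.
#' @param topology Either \code{"linear"} or \code{"circular"}.
#' @return An object of class \code{genome_record} with fields
#'   \code{contig_id}, \code{sequence}, \code{topology}.
#' @examples
#' genome_record("chr", "acgtACGT")
#' @export
genome_record <- function(contig_id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(contig_id), length(contig_id) == 1L, nzchar(contig_id))
  sequence <- clean_dna(sequence)
  if (!nzchar(sequence)) {
    tig_error("tig_alphabet_error", "sequence must be nonempty")
  }
  structure(
    list(contig_id = contig_id, sequence = sequence, topology = topology),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf(
    "<genome_record> %s: %s bp (%s)\n", x$contig_id,
    format(nchar(x$sequence), big.mark = ","), x$topology
  ))
  invisible(x)
}

# Uppercase, fold U->T, reject anything outside {A,C,G,T,N}.
clean_dna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "t", sequence)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  bad <- regmatches(s, regexpr("[^ACGTN]", s))
  if (length(bad) > 0L) {
    tig_error(
      "tig_alphabet_error",
      sprintf("sequence contains character outside {A,C,G,T,N}: '%s'", bad),
      character = bad
    )
  }
  s
}

#' Genomic interval (0-based, half-open)
#'
#' @param contig_id Contig the interval lies on.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy \code{start < end}.
#' @param strand Optional strand, \code{"+"}, \code{"-"} or \code{NA}.
#' @return An object of class \code{tig_interval}.
#' @export
interval <- function(contig_id, start, end, strand = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end) {
    tig_error("tig_bounds_error", sprintf("invalid interval [%s, %s)", start, end))
  }
  if (!is.na(strand) && !strand %in% c("+", "-")) {
    tig_error("tig_bounds_error", sprintf("invalid strand '%s'", strand))
  }
  structure(
    list(contig_id = contig_id, start = start, end = end, strand = strand),
    class = "tig_interval"
  )
}

#' @export
print.tig_interval <- function(x, ...) {
  cat(sprintf(
    "<interval> %s:[%d, %d)%s\n", x$contig_id, x$start, x$end,
    if (is.na(x$strand)) "" else paste0(" ", x$strand)
  ))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Sequences are uppercased, U is folded to T, and any character outside
#' \code{A,C,G,T,N} raises an alphabet error. Record identifiers are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (default linear).
#' @return A named list of \code{\link{genome_record}} objects.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) {
    tig_error("tig_io_error", sprintf("file not found: %s", path))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    tig_error(
      "tig_duplicate_id_error",
      sprintf("duplicate FASTA header(s): %s", paste(unique(dup), collapse = ", ")),
      ids = unique(dup)
    )
  }
  recs <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), topology = topology)
  })
  names(recs) <- ids
  recs
}

#' Write genome records to a FASTA file
#'
#' @param records A list of \code{\link{genome_record}} objects (or a single one).
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) r$contig_id, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq DNA string over \code{A,C,G,T,N} (case-insensitive); N maps to N.
#' @return The reverse complement, uppercase.
#' @examples
#' revcomp("TAT") # "ATA"
#' @export
revcomp <- function(seq) {
  s <- clean_dna(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]), collapse = "")
}

#' Extract an interval from a genome
#'
#' Returns the subsequence in plus orientation, reverse complemented when the
#' interval's strand is \code{"-"}. On circular records an interval whose end
#' exceeds the contig length wraps around the origin; on linear records that is
#' an out-of-bounds error. Spans longer than the contig are always rejected.
#'
#' @param genome A \code{\link{genome_record}}.
#' @param iv A \code{\link{interval}} (its \code{contig_id} is not checked
#'   against the record; callers pair them).
#' @return A DNA string of length \code{iv$end - iv$start}.
#' @export
extract_interval <- function(genome, iv) {
  n <- nchar(genome$sequence)
  span <- iv$end - iv$start
  if (span > n) {
    tig_error("tig_out_of_bounds_error", sprintf("span %d exceeds contig length %d", span, n))
  }
  if (iv$start < 0L || (genome$topology == "linear" && iv$end > n)) {
    tig_error(
      "tig_out_of_bounds_error",
      sprintf("interval [%d, %d) outside linear contig of length %d", iv$start, iv$end, n)
    )
  }
  s <- if (iv$end <= n) {
    substr(genome$sequence, iv$start + 1L, iv$end)
  } else {
    # circular wrap: equivalent to slicing the doubled sequence
    paste0(
      substr(genome$sequence, iv$start + 1L, n),
      substr(genome$sequence, 1L, iv$end - n)
    )
  }
  if (!is.na(iv$strand) && iv$strand == "-") revcomp(s) else s
}

#' Read gene annotations from GFF3 or a minimal TSV
#'
#' GFF3 input keeps rows of type \code{gene} and takes the identifier from the
#' \code{ID=} attribute. TSV input needs columns \code{gene_id}, \code{contig_id},
#' \code{start}, \code{end}, \code{strand} (header row required); coordinates in
#' the TSV are already 0-based half-open, while GFF3 coordinates are converted
#' from 1-based inclusive.
#'
#' @param path Path to a \code{.gff}/\code{.gff3} or \code{.tsv} file.
#' @return A tibble with columns \code{gene_id}, \code{contig_id}, \code{start},
#'   \code{end}, \code{strand} (0-based half-open coordinates).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) {
    tig_error("tig_io_error", sprintf("file not found: %s", path))
  }
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    fields <- fields[vapply(fields, length, 1L) >= 9L]
    rows <- Filter(function(f) f[3] == "gene", fields)
    genes <- tibble::tibble(
      gene_id = vapply(rows, function(f) {
        m <- regmatches(f[9], regexpr("ID=[^;]+", f[9]))
        if (length(m) == 0L) tig_error("tig_format_error", "gene row without ID= attribute")
        sub("^ID=", "", m)
      }, character(1)),
      contig_id = vapply(rows, `[`, character(1), 1L),
      start = vapply(rows, function(f) as.integer(f[4]) - 1L, integer(1)),
      end = vapply(rows, function(f) as.integer(f[5]), integer(1)),
      strand = vapply(rows, `[`, character(1), 7L)
    )
  } else {
    genes <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
    need <- c("gene_id", "contig_id", "start", "end", "strand")
    if (!all(need %in% names(genes))) {
      tig_error(
        "tig_format_error",
        sprintf("gene TSV must have columns: %s", paste(need, collapse = ", "))
      )
    }
    genes <- genes[, need]
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  }
  if (anyDuplicated(genes$gene_id)) {
    tig_error("tig_duplicate_id_error", "duplicate gene_id in gene table")
  }
  if (any(genes$start < 0L | genes$start >= genes$end)) {
    tig_error("tig_bounds_error", "gene table contains invalid coordinates")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    tig_error("tig_format_error", "gene strand must be '+' or '-'")
  }
  genes
}

#' Write a tibble of genes as a minimal TSV
#' @param genes Tibble as returned by \code{\link{read_gene_table}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal GenBank flat file
#'
#' Emits LOCUS, FEATURES and ORIGIN sections. Internal 0-based half-open
#' feature intervals are converted to 1-based inclusive GenBank locations;
#' minus-strand features use \code{complement()} notation. The emitted file is
#' deterministic (no timestamps).
#'
#' @param record_name LOCUS name.
#' @param sequence DNA sequence.
#' @param features A list of features, each a list with elements \code{label},
#'   \code{iv} (a \code{\link{interval}}) and \code{type} (feature key, e.g.
#'   \code{"misc_feature"}); may be empty.
#' @param path Output path.
#' @param circular Mark the LOCUS as circular.
#' @return The path, invisibly.
#' @export
write_genbank <- function(record_name, sequence, features = list(), path, circular = FALSE) {
  sequence <- clean_dna(sequence)
  n <- nchar(sequence)
  for (f in features) {
    if (f$iv$start < 0L || f$iv$end > n) {
      tig_error(
        "tig_bounds_error",
        sprintf("feature '%s' [%d, %d) outside sequence of length %d",
                f$label, f$iv$start, f$iv$end, n)
      )
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     %s   UNA",
    record_name, n, if (circular) "circular" else "linear"
  ), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (f in features) {
    loc <- sprintf("%d..%d", f$iv$start + 1L, f$iv$end)
    if (!is.na(f$iv$strand) && f$iv$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", f$type, loc), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label), con)
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(sequence, off, min(off + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tolower(groups), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
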