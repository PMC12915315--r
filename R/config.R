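# Run configuration: the design constants of the endogenous Type I-G editing
# workflow, with YAML/JSON loading and validation. Precedence is
# CLI flag > config file > built-in default.

#' Default run configuration
#'
#' Holds the design constants: PAM \code{5'-TAT-3'}, 35 nt spacers, 8 nt
#' PAM-proximal seed, 600/1000 bp homology-arm presets, 100 bp upstream +
#' 400 bp coding default deletion, off-target thresholds, and the enzyme
#' motif table (PciI \code{ACATGT} for the cassette site, BspHI \code{TCATGA}
#' for the template site).
#'
#' @param pam PAM sequence.
#' @param spacer_len Spacer/protospacer length (nt).
#' @param seed_len Seed length (nt).
#' @param arm_presets Homology-arm length presets (bp).
#' @param upstream_bp,coding_bp Default deletion window components (bp).
#' @param max_total_mismatches Off-target mismatch budget.
#' @param enzymes Named motif table.
#' @param fixture_seed Seed for synthetic fixtures.
#' @return A validated list of class \code{tig_config}.
#' @export
tig_config <- function(pam = "TAT", spacer_len = 35L, seed_len = 8L,
                       arm_presets = c(600L, 1000L), upstream_bp = 100L,
                       coding_bp = 400L, max_total_mismatches = 5L,
                       enzymes = c(PciI = "ACATGT", BspHI = "TCATGA"),
                       fixture_seed = 42L) {
  cfg <- structure(
    list(pam = pam, spacer_len = as.integer(spacer_len),
         seed_len = as.integer(seed_len), arm_presets = as.integer(arm_presets),
         upstream_bp = as.integer(upstream_bp), coding_bp = as.integer(coding_bp),
         max_total_mismatches = as.integer(max_total_mismatches),
         enzymes = enzymes, fixture_seed = as.integer(fixture_seed)),
    class = "tig_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  check <- function(ok, field, why) {
    if (!ok) {
      tig_error(
        "tig_config_error",
        sprintf("invalid config field '%s': %s", field, why), field = field
      )
    }
  }
  check(grepl("^[ACGT]+$", cfg$pam), "pam", "must be a DNA string over ACGT")
  check(cfg$spacer_len >= 18L && cfg$spacer_len <= 50L, "spacer_len",
        "must be within [18, 50]")
  check(cfg$seed_len >= 1L && cfg$seed_len <= cfg$spacer_len, "seed_len",
        "must be within [1, spacer_len]")
  check(all(cfg$arm_presets > 0L), "arm_presets", "must be positive")
  check(cfg$upstream_bp >= 0L, "upstream_bp", "must be non-negative")
  check(cfg$coding_bp > 0L, "coding_bp", "must be positive")
  check(cfg$max_total_mismatches >= 0L, "max_total_mismatches", "must be non-negative")
  check(length(cfg$enzymes) > 0L && !is.null(names(cfg$enzymes)) &&
          all(grepl("^[ACGT]{4,}$", cfg$enzymes)),
        "enzymes", "must be a named table of DNA motifs (>= 4 nt)")
  invisible(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' Fields present in the file override the built-in defaults; everything else
#' keeps its default. The merged configuration is validated.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{tig_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    tig_error("tig_io_error", sprintf("config file not found: %s", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$enzymes)) raw$enzymes <- unlist(raw$enzymes)
  defaults <- tig_config()
  for (field in names(raw)) {
    if (!field %in% names(defaults)) {
      tig_error("tig_config_error", sprintf("unknown config field '%s'", field),
                field = field)
    }
    defaults[[field]] <- raw[[field]]
  }
  for (f in c("spacer_len", "seed_len", "arm_presets", "upstream_bp",
              "coding_bp", "max_total_mismatches", "fixture_seed")) {
    defaults[[f]] <- as.integer(defaults[[f]])
  }
  validate_config(defaults)
  defaults
}

#' @export
print.tig_config <- function(x, ...) {
  cat(sprintf(
    "<tig_config> PAM %s, spacer %d nt, seed 1-%d, arms {%s} bp, deletion %d+%d bp\n",
    x$pam, x$spacer_len, x$seed_len, paste(x$arm_presets, collapse = ", "),
    x$upstream_bp, x$coding_bp
  ))
  invisible(x)
}

# stable digest of the effective config, echoed into output headers
config_digest <- function(cfg) {
  rlang::hash(cfg[order(names(cfg))])
}

# commented header line for TSV outputs; deterministic (no timestamps)
tsv_header <- function(cfg) {
  sprintf("# tigdesign %s config_digest=%s",
          as.character(utils::packageVersion("tigdesign")), config_digest(cfg))
}

write_tsv_with_header <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
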