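# End-to-end editing-design workflow: from a host genome and target gene to
# the full panel of editing vectors (three spacers x two homology-arm
# presets = six vectors per gene, plus the template-free screening vectors).

#' Design the full editing-vector panel for one gene
#'
#' Runs guide extraction, genome-wide off-target screening, spacer selection,
#' deletion planning, template extraction for each arm preset, cassette
#' assembly and vector assembly. With the default three selected spacers and
#' two arm presets this yields six editing vectors per target gene, plus one
#' screening vector (no template) per spacer.
#'
#' @param genome Host \code{\link{genome_record}}.
#' @param gene One row of a gene table.
#' @param backbone A backbone as returned by \code{\link{make_backbone}} (or a
#'   list with \code{record}, \code{features}, \code{sites}).
#' @param leader,terminator Cassette leader and terminator sequences.
#' @param repeat_seq Consensus repeat used in the cassette.
#' @param config A \code{\link{tig_config}}.
#' @param k Number of spacers to select (default 3).
#' @return A list: \code{candidates} (screened), \code{selected},
#'   \code{deletion} (\code{deletion_design}), \code{templates} (one
#'   \code{editing_template} per arm preset), \code{screening_vectors},
#'   \code{editing_vectors} (named list, one per spacer x arm preset),
#'   \code{primers} (one \code{primer_pair} per arm preset).
#' @export
design_editing_vectors <- function(genome, gene, backbone, leader, terminator,
                                   repeat_seq, config = tig_config(), k = 3L) {
  # candidates are drawn from the intended deletion window (shrunk by the PAM
  # length so each protospacer's PAM is covered too), so the deletion only
  # expands beyond upstream_bp + coding_bp when PAM availability forces it
  w <- default_deletion_window(gene, config$upstream_bp, config$coding_bp)
  plen <- nchar(config$pam)
  cands <- extract_candidates(
    genome, gene,
    window = interval(w$contig_id, w$start + plen, w$end - plen),
    spacer_len = config$spacer_len, pam = config$pam
  )
  cands <- screen_candidates(
    cands, genome, pam = config$pam, seed_len = config$seed_len,
    max_total_mismatches = config$max_total_mismatches
  )
  sel <- select_spacers(cands, k = k)
  del <- plan_deletion(
    genome, gene, sel, upstream_bp = config$upstream_bp,
    coding_bp = config$coding_bp, pam = config$pam
  )
  templates <- lapply(config$arm_presets, function(al) {
    extract_arms(genome, del$deletion, arm_len = al)
  })
  names(templates) <- paste0("arm", config$arm_presets)
  primers <- lapply(config$arm_presets, function(al) {
    design_screen_primers(genome, del$deletion, arm_len = al)
  })
  names(primers) <- names(templates)

  screening <- list()
  editing <- list()
  for (si in seq_len(nrow(sel))) {
    cas <- assemble_cassette(
      leader, repeat_seq, sel$spacer_seq[si], terminator,
      spacer_len = config$spacer_len
    )
    sv_name <- sprintf("%s_screen_sp%d", gene$gene_id, si)
    screening[[sv_name]] <- assemble_vector(
      backbone$record, cas,
      array_site_motif = backbone$sites[["array_site"]],
      template_site_motif = backbone$sites[["template_site"]],
      name = sv_name, backbone_features = backbone$features
    )
    for (tn in names(templates)) {
      ev_name <- sprintf("%s_edit_sp%d_%s", gene$gene_id, si, tn)
      editing[[ev_name]] <- assemble_vector(
        backbone$record, cas, template = templates[[tn]],
        array_site_motif = backbone$sites[["array_site"]],
        template_site_motif = backbone$sites[["template_site"]],
        name = ev_name, backbone_features = backbone$features
      )
    }
  }
  list(
    candidates = cands, selected = sel, deletion = del,
    templates = templates, screening_vectors = screening,
    editing_vectors = editing, primers = primers
  )
}
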