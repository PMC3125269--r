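# End-to-end orchestration: mask -> eligibility -> SSR mining -> hit
# filtration -> pairing -> synteny calls -> summary tables.

#' Run the BES characterization pipeline
#'
#' Chains the survey stages on a read set: repeat masking with the supplied
#' library, the non-repetitive eligibility filter (longest unmasked run
#' longer than `min_run` bp), SSR mining with mask-aware flank eligibility,
#' then — for whichever hit tables are supplied — the three-step filtration
#' to unique assignments restricted to eligible reads, clone pairing,
#' synteny calling, and the per-mode summary tables.
#'
#' @param reads Read table (see [read_bes_fasta()]).
#' @param repeat_library Repeat library (see [read_repeat_library()]); `NULL`
#'   skips masking.
#' @param hits_nuc,hits_prot Optional BLAST hit tables (nucleotide /
#'   translated) in the schema of [parse_blast_tab()].
#' @param protein_to_gene Protein-to-gene map (required with `hits_prot`).
#' @param gene_loci Gene location table placing protein-mode assignments on
#'   the reference (required with `hits_prot`).
#' @param params [mask_params()].
#' @param evalue_cutoff Global e-value cutoff for filtration.
#' @param min_run Non-repetitive eligibility bound, bp (exclusive).
#' @param min_flank SSR flank eligibility bound, bp per side.
#' @param min_span,max_span Microsynteny span window, bp.
#' @param species Species label stamped onto calls and summaries.
#' @return List with `reads` (masked, with eligibility columns), `ssr_loci`,
#'   `ssr_report`, `sequencing`, and per-mode `nucleotide` / `protein`
#'   sublists (`assignments`, `pairings`, `calls`, `summary`).
#' @export
bes_pipeline <- function(reads, repeat_library = NULL,
                         hits_nuc = NULL, hits_prot = NULL,
                         protein_to_gene = NULL, gene_loci = NULL,
                         params = mask_params(), evalue_cutoff = 1e-5,
                         min_run = 100L, min_flank = 50L,
                         min_span = 10000, max_span = 300000,
                         species = "reference") {
  if (!is.null(repeat_library)) {
    reads <- mask_with_library(reads, repeat_library, params)
  }
  reads <- nonrepetitive_eligible(reads, min_run)
  loci <- find_tandem_repeats(reads)
  loci <- flank_eligible(reads, loci, min_flank)
  report <- summarize_ssrs(loci)
  eligible_reads <- reads[reads$eligible, , drop = FALSE]

  run_mode <- function(hits, mode) {
    hits <- semi_join(hits, eligible_reads, by = c(query_id = "read_id"))
    assignments <- assign_unique(
      hits, mode, cutoff = evalue_cutoff,
      protein_to_gene = protein_to_gene, reads = eligible_reads
    )
    pairings <- pair_ends(assignments, reads,
                          gene_loci = if (mode == "protein") gene_loci else NULL)
    calls <- call_synteny(pairings, min_span, max_span,
                          species = species, mode = mode)
    list(assignments = assignments, pairings = pairings, calls = calls)
  }

  nuc <- if (!is.null(hits_nuc)) run_mode(hits_nuc, "nucleotide")
  prot <- if (!is.null(hits_prot)) {
    if (is.null(protein_to_gene) || is.null(gene_loci)) {
      stop("protein hits need protein_to_gene and gene_loci")
    }
    run_mode(hits_prot, "protein")
  }
  if (!is.null(nuc)) {
    nuc$summary <- synteny_summary(
      nuc$calls, nuc$pairings, nuc$assignments, reads,
      other_mode_calls = prot$calls, species = species, mode = "nucleotide"
    )
  }
  if (!is.null(prot)) {
    prot$summary <- synteny_summary(
      prot$calls, prot$pairings, prot$assignments, reads,
      other_mode_calls = nuc$calls, species = species, mode = "protein"
    )
  }
  list(
    reads = reads,
    ssr_loci = loci,
    ssr_report = report,
    sequencing = sequencing_accounting(reads),
    nucleotide = nuc,
    protein = prot
  )
}
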