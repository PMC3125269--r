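# Three-step filtration of BLAST hits down to at most one unique
# assignment per read: global e-value cutoff, per-read minimal e-value,
# HSP-product tie-break, and the uniqueness rule (with protein-to-gene
# collapsing in translated mode).

#' Global e-value cutoff
#'
#' Keeps hits with `evalue <= cutoff`; row order is preserved.
#'
#' @param hits Hit table (see [parse_blast_tab()]).
#' @param cutoff Significance cutoff.
#' @return Subset of `hits`.
#' @export
apply_evalue_cutoff <- function(hits, cutoff = 1e-5) {
  hits[hits$evalue <= cutoff, , drop = FALSE]
}

#' Filtration step 1: keep only minimal e-value hits per read
#'
#' @param hits Hit table; grouping is by `query_id`, so tables holding many
#'   reads are handled per read.
#' @return Subset of `hits` attaining each read's minimum e-value (possibly
#'   more than one hit; ties pass to step 2).
#' @export
filter_min_evalue <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits %>%
    group_by(.data$query_id) %>%
    filter(.data$evalue == min(.data$evalue)) %>%
    ungroup()
}

#' Filtration step 2: HSP-product tie-break
#'
#' Among hits tied at the minimal e-value, keeps those with the highest HSP
#' score, the product of percent identity and alignment length.
#'
#' @param hits Hit table (per read, hits share the minimal e-value).
#' @return Subset of `hits` attaining each read's maximal `hsp_score`.
#' @export
tiebreak_hsp <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits %>%
    group_by(.data$query_id) %>%
    filter(.data$hsp_score == max(.data$hsp_score)) %>%
    ungroup()
}

#' Collapse protein subjects to their genes
#'
#' Renames protein (peptide) subject identifiers to gene identifiers, since
#' one gene may encode several peptides through alternative splicing;
#' uniqueness in translated mode is then judged at the gene level.
#'
#' @param hits Hit table with protein `subject_id`s.
#' @param protein_to_gene Mapping table with columns `protein_id`, `gene_id`.
#' @param unmapped What to do with hits whose subject is absent from the
#'   mapping: `"drop"` them with a warning (default) or raise an `"error"`.
#' @return `hits` with a `gene_id` column added.
#' @export
collapse_protein_to_gene <- function(hits, protein_to_gene,
                                     unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  stopifnot(all(c("protein_id", "gene_id") %in% names(protein_to_gene)))
  hits$gene_id <- protein_to_gene$gene_id[
    match(hits$subject_id, protein_to_gene$protein_id)]
  miss <- is.na(hits$gene_id)
  if (any(miss)) {
    ids <- unique(hits$subject_id[miss])
    msg <- paste0(length(ids), " protein id(s) missing from the mapping: ",
                  paste(head(ids, 5), collapse = ", "),
                  if (length(ids) > 5) ", ...")
    if (unmapped == "error") stop(msg)
    warning(msg, "; dropping those hits")
    hits <- hits[!miss, , drop = FALSE]
  }
  hits
}

#' Assign at most one unique hit per read
#'
#' Runs the full filtration pipeline per read: global e-value cutoff, then
#' the minimal-e-value filter, then the HSP tie-break; a read receives an
#' assignment if and only if exactly one subject remains (gene-level subjects
#' in `"protein"` mode after [collapse_protein_to_gene()]). Reads whose
#' surviving hits name several subjects are `ambiguous` and excluded from
#' unique-hit counts; residual ties within one subject are resolved to a
#' deterministic representative row, so the output is independent of input
#' hit order.
#'
#' @param hits Hit table for any number of reads.
#' @param mode `"nucleotide"` or `"protein"`.
#' @param cutoff Global e-value cutoff.
#' @param protein_to_gene Protein-to-gene mapping (protein mode).
#' @param unmapped Passed to [collapse_protein_to_gene()].
#' @param reads Optional read table; reads present there but absent from
#'   `hits` gain `no_hit` rows so the output accounts for every read.
#' @return Tibble with one row per read: `read_id`, `mode`, `status`
#'   (`unique` / `ambiguous` / `no_hit`) and, for unique reads, the surviving
#'   hit's columns (`subject_id`, `gene_id`, coordinates, `strand`, `evalue`,
#'   `hsp_score`).
#' @export
assign_unique <- function(hits, mode = c("nucleotide", "protein"),
                          cutoff = 1e-5, protein_to_gene = NULL,
                          unmapped = "drop", reads = NULL) {
  mode <- match.arg(mode)
  h <- apply_evalue_cutoff(hits, cutoff)
  if (mode == "protein") {
    if (is.null(protein_to_gene)) stop("protein mode requires protein_to_gene")
    h <- collapse_protein_to_gene(h, protein_to_gene, unmapped)
  } else {
    h$gene_id <- NA_character_
  }
  h <- tiebreak_hsp(filter_min_evalue(h))
  if (nrow(h)) {
    h$subject_key <- if (mode == "protein") h$gene_id else h$subject_id
    n_subj <- h %>%
      group_by(.data$query_id) %>%
      summarise(n_subjects = n_distinct(.data$subject_key), .groups = "drop")
    rep_rows <- h %>%
      arrange(.data$query_id, .data$evalue, desc(.data$hsp_score),
              .data$subject_key, .data$s_start, .data$q_start) %>%
      group_by(.data$query_id) %>%
      slice_head(n = 1) %>%
      ungroup()
    per_read <- inner_join(n_subj, rep_rows, by = "query_id") %>%
      arrange(.data$query_id)
    uniq <- per_read$n_subjects == 1
    rep_rows <- per_read
    assigned <- tibble(
      read_id = per_read$query_id,
      mode = mode,
      status = ifelse(uniq, "unique", "ambiguous"),
      subject_id = ifelse(uniq, rep_rows$subject_id, NA_character_),
      gene_id = ifelse(uniq, rep_rows$gene_id, NA_character_),
      pct_identity = ifelse(uniq, rep_rows$pct_identity, NA_real_),
      aln_length = ifelse(uniq, rep_rows$aln_length, NA_real_),
      q_start = ifelse(uniq, rep_rows$q_start, NA_real_),
      q_end = ifelse(uniq, rep_rows$q_end, NA_real_),
      s_start = ifelse(uniq, rep_rows$s_start, NA_real_),
      s_end = ifelse(uniq, rep_rows$s_end, NA_real_),
      strand = ifelse(uniq, rep_rows$strand, NA_character_),
      evalue = ifelse(uniq, rep_rows$evalue, NA_real_),
      hsp_score = ifelse(uniq, rep_rows$hsp_score, NA_real_)
    )
  } else {
    assigned <- tibble(
      read_id = character(0), mode = character(0), status = character(0),
      subject_id = character(0), gene_id = character(0),
      pct_identity = numeric(0), aln_length = numeric(0),
      q_start = numeric(0), q_end = numeric(0),
      s_start = numeric(0), s_end = numeric(0), strand = character(0),
      evalue = numeric(0), hsp_score = numeric(0)
    )
  }
  if (!is.null(reads)) {
    missing_ids <- setdiff(reads$read_id, assigned$read_id)
    if (length(missing_ids)) {
      assigned <- bind_rows(assigned, tibble(
        read_id = missing_ids, mode = mode, status = "no_hit"
      ))
    }
  }
  assigned <- assigned[order(assigned$read_id), , drop = FALSE]
  assigned
}
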