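# Paired-end synteny calling: pair unique assignments by clone, test
# same-chromosome placement (macro-synteny), inner-gap span and tail-to-tail
# orientation (microsynteny), and intersect nucleotide/protein support.

normalize_hit_interval <- function(s_start, s_end) {
  list(lo = pmin(s_start, s_end), hi = pmax(s_start, s_end))
}

#' Pair unique assignments by clone
#'
#' Joins unique per-read assignments back to their clones, producing one row
#' per clone with at least one assigned end. In protein (translated) mode a
#' gene location table maps each assignment onto the reference genome: the
#' hit interval becomes the gene extent and the genomic strand is the
#' product of the alignment frame sign and the gene strand.
#'
#' @param assignments Output of [assign_unique()] (one mode, one species).
#' @param reads Read table supplying `read_id`, `clone_id`, `end`.
#' @param gene_loci Optional gene location table (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`) required to place protein-mode assignments.
#' @return Tibble with one row per clone: `clone_id`, `n_ends`, and for each
#'   end (`f_`/`r_` prefix) the subject chromosome, normalised interval
#'   (`lo`, `hi`, 1-based inclusive) and strand, `NA` when that end is not
#'   assigned.
#' @export
pair_ends <- function(assignments, reads, gene_loci = NULL) {
  a <- assignments[assignments$status == "unique", , drop = FALSE]
  if (!nrow(a)) {
    return(tibble(clone_id = character(0), n_ends = integer(0),
                  f_chrom = character(0), f_lo = numeric(0), f_hi = numeric(0),
                  f_strand = character(0), r_chrom = character(0),
                  r_lo = numeric(0), r_hi = numeric(0), r_strand = character(0)))
  }
  meta <- reads[, c("read_id", "clone_id", "end")]
  a <- inner_join(a, meta, by = "read_id")
  if (nrow(a) < sum(assignments$status == "unique")) {
    stop("assignments reference reads absent from the read table")
  }
  if (any(duplicated(a[, c("clone_id", "end")]))) {
    stop("more than one unique assignment for the same (clone, end)")
  }
  if (!is.null(gene_loci)) {
    g <- gene_loci[match(a$gene_id, gene_loci$gene_id), , drop = FALSE]
    placed <- !is.na(g$gene_id)
    a$chrom <- ifelse(placed, g$chrom, NA_character_)
    a$lo <- ifelse(placed, pmin(g$start, g$end), NA_real_)
    a$hi <- ifelse(placed, pmax(g$start, g$end), NA_real_)
    a$g_strand <- ifelse(placed, g$strand, NA_character_)
    a$hit_strand <- ifelse(a$strand == a$g_strand, "+", "-")
    a <- a[placed, , drop = FALSE]
  } else {
    iv <- normalize_hit_interval(a$s_start, a$s_end)
    a$chrom <- a$subject_id
    a$lo <- iv$lo
    a$hi <- iv$hi
    a$hit_strand <- a$strand
  }
  f <- a[a$end == "forward", c("clone_id", "chrom", "lo", "hi", "hit_strand")]
  r <- a[a$end == "reverse", c("clone_id", "chrom", "lo", "hi", "hit_strand")]
  names(f)[-1] <- paste0("f_", c("chrom", "lo", "hi", "strand"))
  names(r)[-1] <- paste0("r_", c("chrom", "lo", "hi", "strand"))
  out <- dplyr::full_join(f, r, by = "clone_id")
  out$n_ends <- (!is.na(out$f_chrom)) + (!is.na(out$r_chrom))
  out %>%
    select("clone_id", "n_ends", dplyr::starts_with("f_"),
           dplyr::starts_with("r_")) %>%
    arrange(.data$clone_id)
}

#' Are both ends on the same chromosome?
#'
#' Exact string comparison of the two ends' chromosome names (unplaced
#' scaffolds count as chromosomes).
#'
#' @param pairing One or more rows from [pair_ends()].
#' @return Logical vector.
#' @export
same_chromosome <- function(pairing) {
  if (any(pairing$n_ends < 2)) stop("same_chromosome needs both ends assigned")
  pairing$f_chrom == pairing$r_chrom
}

#' Inner gap between two paired-end hits
#'
#' The span between both ends is the inner gap: the number of reference
#' bases strictly between the two aligned intervals (1-based inclusive
#' coordinates). Overlapping or abutting hits span 0.
#'
#' @param lo_f,hi_f Normalised interval of the forward-end hit.
#' @param lo_r,hi_r Normalised interval of the reverse-end hit.
#' @return Integer span in bp (vectorised).
#' @export
compute_span <- function(lo_f, hi_f, lo_r, hi_r) {
  left_hi <- ifelse(lo_f <= lo_r, hi_f, hi_r)
  right_lo <- pmax(lo_f, lo_r)
  pmax(0, right_lo - left_hi - 1)
}

#' Tail-to-tail orientation test
#'
#' Both ends of a clone read inward from the insert boundaries, so on a
#' conserved reference region the two hits must lie on opposite strands with
#' their 3' ends internal: the left-hand hit on the plus strand and the
#' right-hand hit on the minus strand. Which end label (forward/reverse)
#' sits left is arbitrary, so both mirror configurations pass; head-to-head
#' (3' ends external) and same-strand configurations fail.
#'
#' @param lo_f,hi_f,strand_f Interval and strand (`"+"`/`"-"`) of the
#'   forward-end hit.
#' @param lo_r,hi_r,strand_r Interval and strand of the reverse-end hit.
#' @return Logical vector.
#' @export
tail_to_tail <- function(lo_f, hi_f, strand_f, lo_r, hi_r, strand_r) {
  f_left <- lo_f < lo_r | (lo_f == lo_r & hi_f <= hi_r)
  left_strand <- ifelse(f_left, strand_f, strand_r)
  right_strand <- ifelse(f_left, strand_r, strand_f)
  strand_f != strand_r & left_strand == "+" & right_strand == "-"
}

#' Classify paired-end synteny per clone
#'
#' Classification per clone: `SINGLE_END` when only one end is assigned;
#' `DISCORDANT` when the ends map to different chromosomes; otherwise
#' `MACRO_ONLY` (macro-synteny: same chromosome), upgraded to `MICRO` when
#' the inner gap lies within `[min_span, max_span]` (bounds inclusive) and
#' the hits are tail-to-tail.
#'
#' @param pairings Output of [pair_ends()].
#' @param min_span,max_span Microsynteny span window in bp.
#' @param species,mode Optional labels copied onto the output.
#' @return Tibble of synteny calls: `clone_id`, `species`, `mode`,
#'   `classification`, `chrom`, `span_bp`, `orientation_ok`, and the outer
#'   reference extent `ref_start`, `ref_end` for same-chromosome calls.
#' @export
call_synteny <- function(pairings, min_span = 10000, max_span = 300000,
                         species = NA_character_, mode = NA_character_) {
  n <- nrow(pairings)
  if (!n) {
    return(tibble(clone_id = character(0), species = character(0),
                  mode = character(0), classification = synteny_levels(),
                  chrom = character(0), span_bp = numeric(0),
                  orientation_ok = logical(0), ref_start = numeric(0),
                  ref_end = numeric(0))[0, ])
  }
  both <- pairings$n_ends == 2
  same <- both & pairings$f_chrom == pairings$r_chrom
  span <- ifelse(same,
                 compute_span(pairings$f_lo, pairings$f_hi,
                              pairings$r_lo, pairings$r_hi), NA_real_)
  orient <- ifelse(same,
                   tail_to_tail(pairings$f_lo, pairings$f_hi, pairings$f_strand,
                                pairings$r_lo, pairings$r_hi, pairings$r_strand),
                   NA)
  cls <- case_when(
    !both ~ "SINGLE_END",
    !same ~ "DISCORDANT",
    span >= min_span & span <= max_span & orient ~ "MICRO",
    TRUE ~ "MACRO_ONLY"
  )
  tibble(
    clone_id = pairings$clone_id,
    species = species,
    mode = mode,
    classification = factor(cls, levels = levels(synteny_levels())),
    chrom = ifelse(same, pairings$f_chrom, NA_character_),
    span_bp = span,
    orientation_ok = orient,
    ref_start = ifelse(same, pmin(pairings$f_lo, pairings$r_lo), NA_real_),
    ref_end = ifelse(same, pmax(pairings$f_hi, pairings$r_hi), NA_real_)
  )
}

synteny_levels <- function() {
  factor(character(0), levels = c("SINGLE_END", "DISCORDANT", "MACRO_ONLY",
                                  "MICRO"))
}

#' Clones with same-chromosome support in both search modes
#'
#' Returns the clones whose paired ends reached same-chromosome
#' (macro-synteny or better) status in both the nucleotide and the protein
#' search mode. Symmetric in its arguments.
#'
#' @param calls_a,calls_b Synteny call tables from [call_synteny()] for the
#'   same species in two modes.
#' @return `list(n = <count>, clones = <character vector>)`.
#' @export
intersect_modes <- function(calls_a, calls_b) {
  macro <- function(calls) {
    calls$clone_id[calls$classification %in% c("MACRO_ONLY", "MICRO")]
  }
  clones <- sort(intersect(macro(calls_a), macro(calls_b)))
  list(n = length(clones), clones = clones)
}
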