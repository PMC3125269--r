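# Survey summary statistics: printed percentages and ratios (half-up
# rounding), sequencing accounting, GC and Q20 metrics, the per-species
# synteny summary table, and the marker polymorphism summary. Every derived
# percentage in an emitted table is recomputable from its two count rows;
# an audit enforcing that runs on each construction.

#' Printed percentage
#'
#' `100 * numerator / denominator`, rounded half away from zero at the
#' requested precision, as the survey tables print it.
#'
#' @param numerator,denominator Counts (denominator > 0).
#' @param decimals Decimal places.
#' @return Numeric percentage.
#' @examples
#' percent(418, 792, 0)
#' percent(126, 193, 1)
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator == 0)) stop("zero denominator")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Printed ratio
#'
#' `numerator / denominator` rounded half away from zero.
#'
#' @param numerator,denominator Counts (denominator > 0).
#' @param decimals Decimal places.
#' @return Numeric ratio.
#' @examples
#' ratio(632, 355, 2)
#' @export
ratio <- function(numerator, denominator, decimals = 2) {
  if (any(denominator == 0)) stop("zero denominator")
  round_half_up(numerator / denominator, decimals)
}

new_summary_table <- function(rows, derived, title = "summary") {
  stopifnot(all(c("label", "count") %in% names(rows)))
  if (nrow(derived)) {
    stopifnot(all(derived$numerator %in% rows$label),
              all(derived$denominator %in% rows$label))
  }
  x <- structure(list(rows = rows, derived = derived, title = title),
                 class = "summary_table")
  audit_summary_table(x)
  x
}

summary_table_value <- function(x, label) {
  i <- match(label, x$rows$label)
  if (is.na(i)) stop("no summary row labelled '", label, "'")
  x$rows$count[i]
}

derived_values <- function(x) {
  if (!nrow(x$derived)) {
    return(tibble(label = character(0), value = numeric(0)))
  }
  num <- x$rows$count[match(x$derived$numerator, x$rows$label)]
  den <- x$rows$count[match(x$derived$denominator, x$rows$label)]
  tibble(
    label = x$derived$label,
    value = ifelse(den > 0, percent(num, pmax(den, 1), x$derived$decimals),
                   NA_real_)
  )
}

#' Audit a summary table
#'
#' Recomputes every derived percentage from its two count rows and errors on
#' any mismatch; runs automatically whenever a summary table is built.
#'
#' @param x A `summary_table`.
#' @return `TRUE`, invisibly.
#' @export
audit_summary_table <- function(x) {
  dv <- derived_values(x)
  for (i in seq_len(nrow(dv))) {
    num <- summary_table_value(x, x$derived$numerator[i])
    den <- summary_table_value(x, x$derived$denominator[i])
    if (den > 0) {
      expected <- percent(num, den, x$derived$decimals[i])
      if (!isTRUE(all.equal(dv$value[i], expected))) {
        stop("summary audit failed for '", dv$label[i], "'")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.summary_table <- function(x, ...) {
  cat(x$title, "\n")
  w <- max(nchar(x$rows$label))
  for (i in seq_len(nrow(x$rows))) {
    cat(sprintf("  %-*s %s\n", w, x$rows$label[i],
                format(x$rows$count[i], big.mark = ",")))
  }
  dv <- derived_values(x)
  for (i in seq_len(nrow(dv))) {
    cat(sprintf("  %-*s %s%%\n", w, dv$label[i], dv$value[i]))
  }
  invisible(x)
}

#' Tidy a summary table
#'
#' @param x A `summary_table`.
#' @param ... Unused.
#' @return Tibble of count rows followed by derived percentage rows
#'   (`type` column distinguishes them).
#' @export
tidy.summary_table <- function(x, ...) {
  bind_rows(
    tibble(label = x$rows$label, value = as.numeric(x$rows$count),
           type = "count"),
    mutate(derived_values(x), type = "percent")
  )
}

#' One-row view of a summary table
#'
#' @param x A `summary_table`.
#' @param ... Unused.
#' @return One-row tibble, one column per row label.
#' @export
glance.summary_table <- function(x, ...) {
  t <- tidy(x)
  as_tibble(setNames(as.list(t$value), t$label))
}

#' Sequencing accounting for a read set
#'
#' Counts clones, clones with both ends sequenced, single-end clones, total
#' reads and total base pairs, with the both-end percentage as a derived
#' row.
#'
#' @param reads Read table.
#' @return A `summary_table`.
#' @export
sequencing_accounting <- function(reads) {
  ends_per_clone <- if (nrow(reads)) {
    reads %>%
      distinct(.data$clone_id, .data$end) %>%
      count(.data$clone_id)
  } else {
    tibble(clone_id = character(0), n = integer(0))
  }
  rows <- tibble(
    label = c("BAC clones", "Clones with both ends", "Clones with one end",
              "Total reads", "Total bp"),
    count = c(nrow(ends_per_clone), sum(ends_per_clone$n == 2),
              sum(ends_per_clone$n == 1), nrow(reads),
              sum(nchar(reads$bases)))
  )
  derived <- tibble(label = "Both ends (%)",
                    numerator = "Clones with both ends",
                    denominator = "BAC clones", decimals = 1)
  if (rows$count[1] == 0) derived <- derived[0, ]
  new_summary_table(rows, derived, title = "BAC-end sequencing accounting")
}

#' GC content of a read set
#'
#' Percentage of G+C bases over A+C+G+T; IUPAC ambiguity codes are excluded
#' from both numerator and denominator.
#'
#' @param reads Read table or character vector of sequences.
#' @return Unrounded percentage.
#' @export
gc_content <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  s <- toupper(paste(seqs, collapse = ""))
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(s) - nchar(gsub(b, "", s, fixed = TRUE))
  }, numeric(1))
  denom <- sum(counts)
  if (denom == 0) stop("no unambiguous bases")
  100 * (counts[["G"]] + counts[["C"]]) / denom
}

#' Q20 read length
#'
#' Number of bases with phred quality at least 20 in each read.
#'
#' @param reads Read table with the `quals` list column populated.
#' @return Integer vector, one value per read.
#' @export
q20_length <- function(reads) {
  if (any(vapply(reads$quals, is.null, logical(1)))) {
    stop("Q20 length requires per-base qualities for every read")
  }
  vapply(reads$quals, function(q) sum(q >= 20L), integer(1))
}

#' Mean Q20 length of a read set
#'
#' @param reads Read table with qualities.
#' @return Mean Q20 length in bp.
#' @export
mean_q20 <- function(reads) mean(q20_length(reads))

#' Per-species synteny summary table
#'
#' Emits the eight-row per-species summary: total reads with hits, reads with
#' unique hits, clones with one hit-bearing end, clones with both ends
#' hit-bearing, clones with both ends uniquely assigned, unique pairs on the
#' same chromosome, pairs also supported in the other search mode, and
#' microsynteny calls; plus the two derived percentages (same-chromosome
#' share of unique pairs, microsynteny share of same-chromosome pairs).
#'
#' @param calls Synteny calls from [call_synteny()].
#' @param pairings Pairings from [pair_ends()].
#' @param assignments Per-read assignment table from [assign_unique()]
#'   (statuses `unique` / `ambiguous` / `no_hit`).
#' @param reads Read table (for clone/end structure).
#' @param other_mode_calls Optional synteny calls for the same species in the
#'   other search mode, filling the "also identified" row.
#' @param species,mode Labels for the table title.
#' @return A `summary_table`.
#' @export
synteny_summary <- function(calls, pairings, assignments, reads,
                            other_mode_calls = NULL,
                            species = "reference", mode = "nucleotide") {
  if (nrow(calls) && !all(is.na(calls$mode)) &&
      length(unique(stats::na.omit(calls$mode))) > 1) {
    stop("calls mix search modes")
  }
  if (nrow(calls) && !all(is.na(calls$species)) &&
      length(unique(stats::na.omit(calls$species))) > 1) {
    stop("calls mix species")
  }
  with_hits <- assignments[assignments$status != "no_hit", , drop = FALSE]
  meta <- reads[, c("read_id", "clone_id")]
  hit_clones <- inner_join(with_hits, meta, by = "read_id") %>%
    distinct(.data$clone_id, .data$read_id) %>%
    count(.data$clone_id)
  same_chrom <- calls$classification %in% c("MACRO_ONLY", "MICRO")
  also <- if (!is.null(other_mode_calls)) {
    intersect_modes(calls, other_mode_calls)$n
  } else NA_integer_
  rows <- tibble(
    label = c("Total BES with hits", "BES with unique hits",
              "BAC with one end", "Paired BAC-ends",
              "Paired BAC-ends with unique hits",
              "Unique hits paired BAC-ends matched on the same chromosome",
              "Also identified in the other mode", "Microsynteny identified"),
    count = c(nrow(with_hits),
              sum(assignments$status == "unique"),
              sum(hit_clones$n == 1),
              sum(hit_clones$n == 2),
              sum(pairings$n_ends == 2),
              sum(same_chrom),
              also,
              sum(calls$classification == "MICRO"))
  )
  derived <- tibble(
    label = c("Same chromosome (% of unique pairs)",
              "Microsynteny (% of same chromosome)"),
    numerator = c("Unique hits paired BAC-ends matched on the same chromosome",
                  "Microsynteny identified"),
    denominator = c("Paired BAC-ends with unique hits",
                    "Unique hits paired BAC-ends matched on the same chromosome"),
    decimals = c(0, 0)
  )
  keep <- rows$count[match(derived$denominator, rows$label)] > 0
  derived <- derived[keep, , drop = FALSE]
  new_summary_table(rows, derived,
                    title = sprintf("Synteny summary (%s, %s)", species, mode))
}

#' Marker polymorphism summary
#'
#' Classifies each genotyped marker: `failed` when every parent gave no PCR
#' product, `monomorphic` when exactly one allele size was observed across
#' parents, `polymorphic` otherwise. A marker is additionally counted as
#' `duplicated` when any single (diploid) parent shows more than two
#' alleles, the signature of a duplicated locus; duplicated loci may still
#' be polymorphic, so the duplication count sits outside the three-way
#' partition. The allele-number range is reported over polymorphic loci.
#'
#' @param genotypes Genotype tibble from [read_genotype_table()].
#' @return An object of class `polymorphism_summary`.
#' @export
polymorphism_summary <- function(genotypes) {
  if (!nrow(genotypes)) stop("no genotype records")
  per_marker <- genotypes %>%
    group_by(.data$marker_id) %>%
    summarise(
      n_alleles = n_distinct(unlist(.data$alleles)),
      all_np = all(.data$no_product),
      dup = any(lengths(.data$alleles) > 2),
      .groups = "drop"
    ) %>%
    mutate(class = case_when(
      .data$all_np ~ "failed",
      .data$n_alleles == 1 ~ "monomorphic",
      TRUE ~ "polymorphic"
    ))
  poly <- per_marker[per_marker$class == "polymorphic", , drop = FALSE]
  structure(list(
    n_tested = nrow(per_marker),
    n_polymorphic = sum(per_marker$class == "polymorphic"),
    n_failed = sum(per_marker$class == "failed"),
    n_monomorphic = sum(per_marker$class == "monomorphic"),
    n_duplicated = sum(per_marker$dup),
    allele_range = if (nrow(poly)) range(poly$n_alleles) else c(NA_integer_, NA_integer_),
    per_marker = per_marker
  ), class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat("Marker polymorphism summary\n")
  cat(sprintf("  tested: %d\n", x$n_tested))
  cat(sprintf("  polymorphic: %d (%.1f%%), alleles %d-%d\n", x$n_polymorphic,
              percent(x$n_polymorphic, x$n_tested, 1),
              x$allele_range[1], x$allele_range[2]))
  cat(sprintf("  failed: %d (%.1f%%)\n", x$n_failed,
              percent(x$n_failed, x$n_tested, 1)))
  cat(sprintf("  monomorphic: %d (%.1f%%)\n", x$n_monomorphic,
              percent(x$n_monomorphic, x$n_tested, 1)))
  cat(sprintf("  duplicated loci: %d\n", x$n_duplicated))
  invisible(x)
}

#' Tidy a polymorphism summary
#'
#' @param x A `polymorphism_summary`.
#' @param ... Unused.
#' @return Per-marker classification tibble.
#' @export
tidy.polymorphism_summary <- function(x, ...) x$per_marker

#' One-row polymorphism summary
#'
#' @param x A `polymorphism_summary`.
#' @param ... Unused.
#' @return One-row tibble with counts and the printed percentages.
#' @export
glance.polymorphism_summary <- function(x, ...) {
  tibble(
    n_tested = x$n_tested,
    n_polymorphic = x$n_polymorphic,
    n_failed = x$n_failed,
    n_monomorphic = x$n_monomorphic,
    n_duplicated = x$n_duplicated,
    pct_polymorphic = percent(x$n_polymorphic, x$n_tested, 1),
    pct_failed = percent(x$n_failed, x$n_tested, 1),
    pct_monomorphic = percent(x$n_monomorphic, x$n_tested, 1),
    allele_min = x$allele_range[1],
    allele_max = x$allele_range[2]
  )
}
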