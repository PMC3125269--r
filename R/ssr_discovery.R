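# Microsatellite (SSR) mining: tandem arrays of period 1-10, canonical
# motif classes merged across reverse complement (not across rotations),
# mask-aware flank eligibility, and the class-distribution report.

default_min_copies <- function(period) ifelse(period <= 2, 4, 3)

#' Canonical motif class of an SSR
#'
#' SSR motifs are reported as a class `"X/Y"` pairing a motif with its
#' reverse complement, so e.g. `GA` and `TC` fall in one class `"GA/TC"`.
#' Classes are merged across reverse complement only, never across rotations
#' or phases: `TG` and `AC` are rotations of one another but remain distinct
#' classes. The class label puts the lexicographically smaller member first,
#' which makes the function an involution:
#' `canonical_class(revcomp_dna(m)) == canonical_class(m)`.
#'
#' @param motif Character vector of SSR motifs (ACGT only, length 1-10).
#' @return Character vector of `"X/Y"` class labels.
#' @examples
#' canonical_class(c("GA", "TC", "AAC"))
#' @export
canonical_class <- function(motif) {
  motif <- toupper(motif)
  if (any(!grepl("^[ACGT]+$", motif))) {
    stop("motifs must contain only A, C, G, T")
  }
  if (any(nchar(motif) < 1 | nchar(motif) > 10)) {
    stop("motif length must be 1-10")
  }
  rc <- revcomp_dna(motif)
  first <- ifelse(motif <= rc, motif, rc)
  second <- ifelse(motif <= rc, rc, motif)
  paste0(first, "/", second)
}

# Consensus motif of an array [a, b] (1-based inclusive) at period p:
# per-phase majority base, anchored at the array start (phase-preserving).
consensus_motif <- function(chars, a, b, p) {
  vapply(0:(p - 1), function(j) {
    pos <- seq(a + j, b, by = p)
    bases <- chars[pos]
    tab <- sort(table(bases), decreasing = TRUE)
    top <- tab[tab == tab[1]]
    sort(names(top))[1]
  }, character(1)) |> paste(collapse = "")
}

array_purity <- function(chars, a, b, p, motif) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  expected <- m[((seq(a, b) - a) %% p) + 1L]
  mean(chars[a:b] == expected)
}

# Candidate tandem arrays at one period for one sequence.
period_candidates <- function(chars, eq, p, min_copies, min_length,
                              max_mismatch_frac) {
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx_true <- which(r$values)
  if (!length(idx_true)) return(NULL)
  cands <- list()
  used_until <- 0L
  for (t in idx_true) {
    if (starts[t] <= used_until) next
    u <- starts[t]
    v <- ends[t]
    n_true <- r$lengths[t]
    n_false <- 0L
    if (max_mismatch_frac > 0) {
      j <- t
      while (j + 2L <= length(r$lengths)) {
        gap <- r$lengths[j + 1L]
        nxt <- r$lengths[j + 2L]
        if (gap > p) break
        if ((n_false + gap) / (n_true + nxt + n_false + gap) > max_mismatch_frac) break
        n_false <- n_false + gap
        n_true <- n_true + nxt
        v <- ends[j + 2L]
        j <- j + 2L
      }
    }
    used_until <- v
    len <- v - u + 1L + p           # array positions u .. v + p
    if (len < min_length || len / p < min_copies) next
    cands[[length(cands) + 1L]] <- c(a = u, b = v + p)
  }
  if (!length(cands)) return(NULL)
  do.call(rbind, cands)
}

detect_ssrs_seq <- function(seq, max_period, min_copies, min_length,
                            max_mismatch_frac) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_length) {
    return(tibble(start = integer(0), end = integer(0), period = integer(0),
                  motif = character(0), copies = numeric(0),
                  purity = numeric(0)))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  out <- list()
  for (p in seq_len(min(max_period, n - 1L))) {
    eq <- chars[1:(n - p)] == chars[(1 + p):n] & acgt[1:(n - p)] & acgt[(1 + p):n]
    mc <- if (is.function(min_copies)) min_copies(p) else min_copies
    cand <- period_candidates(chars, eq, p, mc, min_length, max_mismatch_frac)
    if (is.null(cand)) next
    for (i in seq_len(nrow(cand))) {
      a <- unname(cand[i, "a"])
      b <- unname(cand[i, "b"])
      motif <- consensus_motif(chars, a, b, p)
      if (!grepl("^[ACGT]+$", motif)) next
      purity <- array_purity(chars, a, b, p, motif)
      if (purity < 1 - max_mismatch_frac) next
      len <- b - a + 1L
      out[[length(out) + 1L]] <- tibble(
        start = a - 1L, end = b, period = p, motif = motif,
        copies = len / p, purity = purity
      )
    }
  }
  cand <- bind_rows(out)
  if (!nrow(cand)) return(cand)
  resolve_overlaps(cand)
}

# Overlapping candidate arrays of different periods resolve to the
# higher-purity, then longer, then shorter-period call (any overlap rejects).
resolve_overlaps <- function(cand) {
  len <- cand$end - cand$start
  ord <- order(-cand$purity, -len, cand$period, cand$start)
  cand <- cand[ord, , drop = FALSE]
  acc_s <- integer(0)
  acc_e <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!length(acc_s) ||
        all(cand$end[i] <= acc_s | cand$start[i] >= acc_e)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, cand$start[i])
      acc_e <- c(acc_e, cand$end[i])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Find tandem repeats (SSR loci) of period 1-10
#'
#' Scans each read for maximal tandem arrays of motif length (period) up to
#' `max_period`. Arrays must span at least `min_length` bp and
#' `min_copies` motif copies (by default 4 copies for mono/dinucleotides and
#' 3 for longer motifs) at purity at least `1 - max_mismatch_frac`, where
#' purity is the fraction of array positions matching a perfect repeat of
#' the phase-anchored consensus motif. Overlapping calls of different
#' periods are resolved to the higher-purity, longer call (shorter period on
#' ties), so a perfect `(AC)n` array is reported once at period 2 and not
#' again at its harmonics.
#'
#' @param x A read table (see [read_bes_fasta()]) or a character vector of
#'   sequences (names used as `read_id`).
#' @param max_period Maximum motif length.
#' @param min_copies Minimum copy number; a single number or a function of
#'   the period (default: 4 for period <= 2, 3 otherwise).
#' @param min_length Minimum array length in bp.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction.
#' @return Tibble of SSR loci: `read_id`, `start`, `end` (0-based half-open),
#'   `period`, `motif`, `copies`, `purity`, `canonical_class`.
#' @export
find_tandem_repeats <- function(x, max_period = 10L,
                                min_copies = default_min_copies,
                                min_length = 12L, max_mismatch_frac = 0.2) {
  if (is.data.frame(x)) {
    ids <- x$read_id
    seqs <- x$bases
  } else {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    seqs <- unname(as.character(x))
  }
  res <- lapply(seq_along(seqs), function(i) {
    loci <- detect_ssrs_seq(seqs[i], max_period, min_copies, min_length,
                            max_mismatch_frac)
    if (nrow(loci)) loci$read_id <- ids[i]
    loci
  })
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(read_id = character(0), start = integer(0), end = integer(0),
                  period = integer(0), motif = character(0),
                  copies = numeric(0), purity = numeric(0),
                  canonical_class = character(0)))
  }
  out$canonical_class <- canonical_class(out$motif)
  out[, c("read_id", "start", "end", "period", "motif", "copies", "purity",
          "canonical_class")]
}

#' Flank eligibility of SSR loci for primer design
#'
#' A locus is eligible when at least `min_flank` unmasked, non-SSR bases lie
#' on each side of it within the read. Masking must run before this filter
#' so repeat-derived flanks do not count as usable primer sequence; bases
#' belonging to any other SSR locus on the same read are excluded too.
#'
#' @param reads Read table with populated `mask`.
#' @param loci SSR locus table from [find_tandem_repeats()].
#' @param min_flank Minimum clean flank length per side, bp.
#' @return `loci` with `left_clean`, `right_clean` and `eligible` columns.
#' @export
flank_eligible <- function(reads, loci, min_flank = 50L) {
  if (!nrow(loci)) {
    loci$left_clean <- integer(0)
    loci$right_clean <- integer(0)
    loci$eligible <- logical(0)
    return(loci)
  }
  read_idx <- match(loci$read_id, reads$read_id)
  if (anyNA(read_idx)) stop("loci reference reads absent from the read table")
  read_len <- nchar(reads$bases)[read_idx]
  if (any(loci$start < 0 | loci$end > read_len)) {
    stop("locus outside read bounds")
  }
  res <- vapply(seq_len(nrow(loci)), function(i) {
    ri <- read_idx[i]
    dirty <- reads$mask[[ri]]
    others <- loci[loci$read_id == loci$read_id[i], , drop = FALSE]
    dirty <- rbind(dirty, as_mask(others$start, others$end))
    dirty <- merge_intervals(dirty)
    left <- loci$start[i] - overlap_with_intervals(0L, loci$start[i], dirty)
    right <- (read_len[i] - loci$end[i]) -
      overlap_with_intervals(loci$end[i], read_len[i], dirty)
    c(left, right)
  }, numeric(2))
  loci$left_clean <- as.integer(res[1, ])
  loci$right_clean <- as.integer(res[2, ])
  loci$eligible <- loci$left_clean >= min_flank & loci$right_clean >= min_flank
  loci
}

PERIOD_GROUPS <- c("Monomer", "Dimer", "Trimer", "Tetramer", "Pentamer",
                   "Hexamer", "Heptamer", "Octomer", "Nanomer", "Decamer")

#' Summarise SSR loci by period group and canonical class
#'
#' Groups loci by period (Monomer ... Decamer) and canonical class; classes
#' with fewer than `other_threshold` loci roll into an `"Other"` row within
#' their period group. Each class is displayed with the motif variant most
#' often observed in the data first (e.g. `TG/CA` when `TG` arrays outnumber
#' `CA` arrays). Because detectors can report the same array more than once
#' across input subsets, the report carries both a raw locus count and a
#' count of distinct `(read, interval)` loci.
#'
#' @param loci SSR locus table, optionally carrying the `eligible` column
#'   from [flank_eligible()].
#' @param other_threshold Minimum per-class count to be named in the report.
#' @return An object of class `ssr_report`; see [tidy.ssr_report()].
#' @export
summarize_ssrs <- function(loci, other_threshold = 15L) {
  if (nrow(loci)) {
    stopifnot(all(loci$period >= 1 & loci$period <= length(PERIOD_GROUPS)))
    key <- canonical_class(loci$motif)
    disp <- vapply(split(loci$motif, key), function(ms) {
      tab <- sort(table(ms), decreasing = TRUE)
      top <- names(tab)[tab == tab[1]]
      m <- sort(top)[1]
      paste0(m, "/", revcomp_dna(m))
    }, character(1))
    tab <- tibble(
      period_group = factor(PERIOD_GROUPS[loci$period], levels = PERIOD_GROUPS),
      class_label = unname(disp[key])
    ) %>%
      count(.data$period_group, .data$class_label, name = "n") %>%
      mutate(class_label = if_else(.data$n < other_threshold, "Other",
                                   .data$class_label)) %>%
      count(.data$period_group, .data$class_label, wt = .data$n, name = "n") %>%
      arrange(.data$period_group, .data$class_label == "Other", desc(.data$n))
    by_period <- count(tab, .data$period_group, wt = .data$n, name = "n")
    dedup <- distinct(loci, .data$read_id, .data$start, .data$end)
  } else {
    tab <- tibble(period_group = factor(character(0), levels = PERIOD_GROUPS),
                  class_label = character(0), n = integer(0))
    by_period <- tibble(period_group = tab$period_group, n = integer(0))
    dedup <- loci
  }
  structure(list(
    by_class = tab,
    by_period = by_period,
    total_loci = nrow(loci),
    total_distinct = nrow(dedup),
    n_reads = if (nrow(loci)) n_distinct(loci$read_id) else 0L,
    eligible_count = if ("eligible" %in% names(loci)) sum(loci$eligible) else NA_integer_,
    primer_candidate_count = if ("eligible" %in% names(loci)) sum(loci$eligible) else NA_integer_
  ), class = "ssr_report")
}

#' @export
print.ssr_report <- function(x, ...) {
  cat("SSR report:", x$total_loci, "loci (", x$total_distinct,
      "distinct ) in", x$n_reads, "reads\n")
  if (!is.na(x$eligible_count)) {
    cat("  flank-eligible (primer candidates):", x$eligible_count, "\n")
  }
  print(as.data.frame(x$by_class), row.names = FALSE)
  invisible(x)
}

#' Tidy an SSR report
#'
#' @param x An `ssr_report`.
#' @param ... Unused.
#' @return Tibble with `period_group`, `class_label`, `n`.
#' @export
tidy.ssr_report <- function(x, ...) x$by_class

#' One-row summary of an SSR report
#'
#' @param x An `ssr_report`.
#' @param ... Unused.
#' @return One-row tibble with totals.
#' @export
glance.ssr_report <- function(x, ...) {
  tibble(total_loci = x$total_loci, total_distinct = x$total_distinct,
         n_reads = x$n_reads, eligible_count = x$eligible_count,
         primer_candidate_count = x$primer_candidate_count)
}
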