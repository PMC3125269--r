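# Library-based repeat masking with a seed-and-extend local aligner,
# contaminant screening, the self-alignment hit census, and masking stats.

#' Parameters for the seed-and-extend masker
#'
#' The masker seeds on exact `seed_k`-mers shared between a read and a
#' library consensus (either strand) and extends each seed without gaps in
#' both directions under an x-drop rule (+1 match, -1 mismatch; extension
#' stops when the score falls `xdrop` below its running maximum). A hit is
#' kept when its alignment is at least `min_hit_len` columns at identity
#' `>= min_identity`; hit intervals on the read are merged into the mask.
#'
#' @param seed_k Seed word length (>= 8).
#' @param min_identity Minimum alignment identity, fraction in (0, 1].
#' @param min_hit_len Minimum alignment length in bp.
#' @param xdrop Extension drop-off in score units.
#' @return An object of class `mask_params`.
#' @export
mask_params <- function(seed_k = 11L, min_identity = 0.80, min_hit_len = 30L,
                        xdrop = 20) {
  stopifnot(seed_k >= 8, min_identity > 0, min_identity <= 1,
            min_hit_len >= 1, xdrop > 0)
  structure(list(seed_k = as.integer(seed_k), min_identity = min_identity,
                 min_hit_len = as.integer(min_hit_len), xdrop = xdrop),
            class = "mask_params")
}

#' @export
print.mask_params <- function(x, ...) {
  cat("seed-and-extend masker parameters\n")
  cat(sprintf("  seed_k = %d, min_identity = %.2f, min_hit_len = %d, xdrop = %g\n",
              x$seed_k, x$min_identity, x$min_hit_len, x$xdrop))
  invisible(x)
}

# Low-level scan: queries x subjects -> tidy hit table (0-based half-open).
scan_local_hits <- function(queries, subjects, params, both_strands = TRUE) {
  if (!length(queries) || !length(subjects)) {
    return(tibble(query = integer(0), subject = integer(0), strand = integer(0),
                  q_start = numeric(0), q_end = numeric(0),
                  s_start = numeric(0), s_end = numeric(0),
                  length = numeric(0), matches = numeric(0),
                  identity = numeric(0), score = numeric(0)))
  }
  as_tibble(.seed_extend_scan(
    as.character(queries), as.character(subjects),
    params$seed_k, params$min_identity, params$min_hit_len, params$xdrop,
    both_strands
  ))
}

#' Read a repeat library FASTA
#'
#' Headers may carry a repeat class tag after `#`, e.g.
#' `>RT_rep_0001 #DNA/TcMar-Tc1`; untagged elements are classed `Unknown`.
#'
#' @param path FASTA path.
#' @return Tibble with `name`, `repeat_class`, `consensus`.
#' @export
read_repeat_library <- function(path) {
  rec <- read_fasta_records(path)
  cls <- ifelse(grepl("#", rec$name),
                trimws(sub("^[^#]*#", "", rec$name)), "Unknown")
  name <- trimws(sub("#.*$", "", rec$name))
  name <- sub("\\s.*$", "", name)
  bad <- !is_iupac_dna(rec$seq) | !nzchar(rec$seq)
  if (any(bad)) stop("invalid consensus sequence for: ",
                     paste(name[bad], collapse = ", "))
  tibble(name = name, repeat_class = cls, consensus = toupper(rec$seq))
}

#' Write a repeat library FASTA
#'
#' @param library Tibble with `name`, `repeat_class`, `consensus`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_repeat_library <- function(library, path) {
  write_fasta_records(paste0(library$name, " #", library$repeat_class),
                      library$consensus, path)
}

as_library_tbl <- function(library) {
  if (is.character(library)) {
    return(tibble(name = names(library) %||% paste0("lib", seq_along(library)),
                  repeat_class = "Unknown", consensus = toupper(library)))
  }
  stopifnot(is.data.frame(library), "consensus" %in% names(library))
  library
}

#' Mask reads with a repeat library
#'
#' Every local alignment between a read and any library consensus (either
#' strand) passing the `params` thresholds contributes its read interval to
#' the read's mask; intervals are merged with any pre-existing mask and the
#' bases themselves are never rewritten, so downstream operations choose a
#' hard- or soft-masked view. Masking is idempotent.
#'
#' @param reads Read table (see [read_bes_fasta()]).
#' @param library Repeat library tibble (see [read_repeat_library()]) or a
#'   character vector of consensus sequences.
#' @param params [mask_params()].
#' @return `reads` with the `mask` list column updated.
#' @export
mask_with_library <- function(reads, library, params = mask_params()) {
  library <- as_library_tbl(library)
  if (!nrow(library)) stop("repeat library is empty")
  if (!nrow(reads)) return(reads)
  hits <- scan_local_hits(reads$bases, library$consensus, params)
  if (nrow(hits)) {
    by_read <- split(hits[, c("q_start", "q_end")], hits$query)
    for (qs in names(by_read)) {
      i <- as.integer(qs)
      add <- as_mask(by_read[[qs]]$q_start, by_read[[qs]]$q_end)
      reads$mask[[i]] <- merge_intervals(rbind(reads$mask[[i]], add))
    }
  }
  reads$mask <- lapply(reads$mask, merge_intervals)
  reads
}

#' Percentage of base pairs masked
#'
#' @param reads Read table with populated `mask`.
#' @return `100 * masked bp / total bp` (unrounded).
#' @export
masked_fraction <- function(reads) {
  if (!nrow(reads)) stop("no reads")
  total <- sum(nchar(reads$bases))
  if (total == 0) stop("zero total sequence length")
  masked <- sum(vapply(reads$mask, interval_total, 1L))
  100 * masked / total
}

#' Cross-mask one repeat library with another
#'
#' Treats the consensus sequences of `library_a` as a read set, masks them
#' with `library_b`, and returns the masked percentage. Asymmetric by
#' construction: it measures how much of `a` is representable by `b`.
#'
#' @param library_a,library_b Repeat libraries.
#' @param params [mask_params()].
#' @return Masked percentage of `library_a` in base pairs.
#' @export
cross_mask_fraction <- function(library_a, library_b, params = mask_params()) {
  a <- as_library_tbl(library_a)
  if (!nrow(a)) stop("library_a is empty")
  reads <- tibble(
    read_id = a$name, clone_id = a$name, end = "forward",
    bases = a$consensus, quals = rep(list(NULL), nrow(a)),
    mask = rep(list(empty_mask()), nrow(a))
  )
  masked_fraction(mask_with_library(reads, library_b, params))
}

#' Screen reads against a contaminant library
#'
#' A read is removed when some single local alignment to a contaminant
#' (vector or host sequence) has identity `>= min_identity` and covers at
#' least `min_cov` of the read length.
#'
#' @param reads Read table.
#' @param contaminants Contaminant library (tibble with `consensus` or a
#'   character vector).
#' @param min_identity Minimum alignment identity.
#' @param min_cov Minimum fraction of the read covered by one alignment.
#' @param params [mask_params()] controlling seeding/extension.
#' @return `list(kept = ..., removed = ...)`, a disjoint partition of `reads`.
#' @export
screen_contaminants <- function(reads, contaminants, min_identity = 0.90,
                                min_cov = 0.50, params = mask_params()) {
  contaminants <- as_library_tbl(contaminants)
  if (!nrow(contaminants)) stop("contaminant library is empty")
  if (!nrow(reads)) return(list(kept = reads, removed = reads))
  scan_p <- mask_params(params$seed_k, min(params$min_identity, min_identity),
                        params$min_hit_len, params$xdrop)
  hits <- scan_local_hits(reads$bases, contaminants$consensus, scan_p)
  removed_idx <- logical(nrow(reads))
  if (nrow(hits)) {
    hits$read_len <- nchar(reads$bases)[hits$query]
    flag <- hits$identity >= min_identity &
      (hits$q_end - hits$q_start) >= min_cov * hits$read_len
    removed_idx[unique(hits$query[flag])] <- TRUE
  }
  list(kept = reads[!removed_idx, , drop = FALSE],
       removed = reads[removed_idx, , drop = FALSE])
}

#' Longest non-repetitive run and survey eligibility
#'
#' A read is eligible for homology searches when its longest unmasked run is
#' strictly longer than `min_run` bp ("more than" `min_run` contiguous
#' non-repetitive bases).
#'
#' @param reads Read table with populated `mask`.
#' @param min_run Minimum contiguous unmasked length (exclusive bound).
#' @return `reads` with `eligible`, `run_start`, `run_end`, `run_length`
#'   columns describing the longest unmasked run (0-based half-open).
#' @export
nonrepetitive_eligible <- function(reads, min_run = 100L) {
  runs <- lapply(seq_len(nrow(reads)), function(i) {
    comp <- complement_intervals(reads$mask[[i]], nchar(reads$bases[i]))
    if (nrow(comp) == 0) return(c(NA_integer_, NA_integer_, 0L))
    len <- comp[, 2] - comp[, 1]
    j <- which.max(len)
    c(comp[j, 1], comp[j, 2], len[j])
  })
  m <- do.call(rbind, runs)
  reads$run_start <- m[, 1]
  reads$run_end <- m[, 2]
  reads$run_length <- m[, 3]
  reads$eligible <- m[, 3] > min_run
  reads
}

#' Census of residual repeats by all-vs-all self-alignment
#'
#' Aligns the masked reads to each other (only unmasked sequence
#' participates), counts for each read the number of *other* reads with a
#' significant alignment, and bins the counts: `LOW` up to 10 hits,
#' `MODERATE` more than 10 and at most 50, `HIGH` more than 50. Reads still
#' producing many self-hits after library masking point at repeat families
#' missing from the library. Significance uses the ungapped Karlin-Altschul
#' e-value `K * m * n * exp(-lambda * S)` for the +1/-1 scoring of the
#' seed-and-extend aligner (`lambda = ln 3`, `K = 0.33` under a uniform base
#' model), with `m` the read's unmasked length and `n` the total unmasked
#' database length.
#'
#' @param reads Masked read table.
#' @param evalue_cutoff Significance cutoff for counting a hit.
#' @param params [mask_params()].
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters for the +1/-1
#'   ungapped scores.
#' @return Tibble `read_id`, `hit_count`, `census_class` (factor
#'   LOW/MODERATE/HIGH).
#' @export
self_hit_census <- function(reads, evalue_cutoff = 1e-5,
                            params = mask_params(),
                            karlin_lambda = log(3), karlin_k = 0.33) {
  n_reads <- nrow(reads)
  runs <- lapply(seq_len(n_reads), function(i) {
    comp <- complement_intervals(reads$mask[[i]], nchar(reads$bases[i]))
    comp <- comp[comp[, 2] - comp[, 1] >= params$seed_k, , drop = FALSE]
    if (nrow(comp) == 0) return(NULL)
    tibble(read = i,
           seq = substring(reads$bases[i], comp[, 1] + 1L, comp[, 2]))
  })
  runs <- bind_rows(runs)
  hit_count <- integer(n_reads)
  if (!is.null(runs) && nrow(runs)) {
    seqs <- toupper(runs$seq)
    hits <- scan_local_hits(seqs, seqs, params)
    if (nrow(hits)) {
      hits$read_q <- runs$read[hits$query]
      hits$read_s <- runs$read[hits$subject]
      hits <- hits[hits$read_q != hits$read_s, , drop = FALSE]
      if (nrow(hits)) {
        m_len <- vapply(seq_len(n_reads), function(i) {
          sum(nchar(seqs[runs$read == i]))
        }, 1L)
        n_db <- sum(nchar(seqs))
        hits$evalue <- karlin_k * m_len[hits$read_q] * n_db *
          exp(-karlin_lambda * hits$score)
        sig <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
        if (nrow(sig)) {
          tab <- table(unique(sig[, c("read_q", "read_s")])$read_q)
          hit_count[as.integer(names(tab))] <- as.integer(tab)
        }
      }
    }
  }
  tibble(
    read_id = reads$read_id,
    hit_count = hit_count,
    census_class = census_class(hit_count)
  )
}

#' Bin a self-alignment hit count
#'
#' `LOW` for counts up to 10, `MODERATE` for counts in (10, 50], `HIGH`
#' above 50. The boundary counts 10 and 50 fall in the lower bin.
#'
#' @param hit_count Integer vector of hit counts.
#' @return Factor with levels LOW, MODERATE, HIGH.
#' @export
census_class <- function(hit_count) {
  factor(
    ifelse(hit_count > 50, "HIGH", ifelse(hit_count > 10, "MODERATE", "LOW")),
    levels = c("LOW", "MODERATE", "HIGH")
  )
}
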