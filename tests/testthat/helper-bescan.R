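# Shared fixtures and independent oracles, built in code.

# Build a read table from named sequences.
make_reads <- function(seqs, clone = NULL, end = NULL, quals = NULL) {
  ids <- names(seqs) %||% paste0("r", seq_along(seqs))
  tibble::tibble(
    read_id = ids,
    clone_id = clone %||% ids,
    end = end %||% rep("forward", length(seqs)),
    bases = unname(unlist(seqs)),
    quals = quals %||% rep(list(NULL), length(seqs)),
    mask = rep(list(bescan:::empty_mask()), length(seqs))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rc <- function(x) bescan::revcomp_dna(x)

# ---------------------------------------------------------------------------
# Brute-force SSR oracle: enumerate every (start, period) window, extend
# perfect runs maximally, dedupe harmonics and overlaps with the same
# resolution contract as the detector (purity desc, length desc, period asc).
# Only meaningful for perfect arrays (max_mismatch_frac = 0).
brute_force_ssrs <- function(seq, max_period = 3, min_length = 12,
                             min_copies = function(p) ifelse(p <= 2, 4, 3)) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  cand <- list()
  for (p in seq_len(min(max_period, n - 1))) {
    i <- 1
    while (i + p <= n) {
      if (chars[i] == chars[i + p] && chars[i] %in% c("A", "C", "G", "T")) {
        j <- i
        while (j + p <= n && chars[j] == chars[j + p] &&
               chars[j + p] %in% c("A", "C", "G", "T")) {
          j <- j + 1
        }
        # maximal perfect array covering positions i .. j + p - 1 (1-based)
        len <- j + p - i
        mc <- if (is.function(min_copies)) min_copies(p) else min_copies
        if (len >= min_length && len / p >= mc) {
          cand[[length(cand) + 1]] <- data.frame(
            start = i - 1L, end = i - 1L + len, period = p,
            motif = paste(chars[i:(i + p - 1)], collapse = ""),
            purity = 1
          )
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      period = integer(0), motif = character(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[, c("start", "end", "period")]), , drop = FALSE]
  len <- cand$end - cand$start
  cand <- cand[order(-cand$purity, -len, cand$period, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  acc_s <- integer(0)
  acc_e <- integer(0)
  for (k in seq_len(nrow(cand))) {
    if (!length(acc_s) ||
        all(cand$end[k] <= acc_s | cand$start[k] >= acc_e)) {
      keep[k] <- TRUE
      acc_s <- c(acc_s, cand$start[k])
      acc_e <- c(acc_e, cand$end[k])
    }
  }
  out <- cand[keep, c("start", "end", "period", "motif")]
  out[order(out$start), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Exhaustive filtration oracle: direct evaluation of the three rules on one
# read's hits, independent of the dplyr pipeline.
oracle_assign <- function(hits, cutoff = 1e-5, gene_map = NULL) {
  h <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (!nrow(h)) return(list(status = "no_hit", subject = NA_character_))
  if (!is.null(gene_map)) {
    h$key <- unname(gene_map[h$subject_id])
    h <- h[!is.na(h$key), , drop = FALSE]
    if (!nrow(h)) return(list(status = "no_hit", subject = NA_character_))
  } else {
    h$key <- h$subject_id
  }
  h <- h[h$evalue == min(h$evalue), , drop = FALSE]
  h <- h[h$hsp_score == max(h$hsp_score), , drop = FALSE]
  subjects <- unique(h$key)
  if (length(subjects) == 1) {
    list(status = "unique", subject = subjects)
  } else {
    list(status = "ambiguous", subject = NA_character_)
  }
}

# Random hit table for one read.
random_hits <- function(read_id, n, subjects = paste0("chr", 1:4)) {
  ev_pool <- c(1e-20, 1e-10, 1e-8, 1e-4)
  pct <- sample(c(80, 90, 95, 100), n, replace = TRUE)
  len <- sample(c(50, 100, 150), n, replace = TRUE)
  tibble::tibble(
    query_id = read_id,
    subject_id = sample(subjects, n, replace = TRUE),
    pct_identity = pct, aln_length = len,
    mismatches = 0, gap_opens = 0,
    q_start = 1, q_end = len,
    s_start = sample(1e5, n), s_end = sample(1e5, n) + len,
    evalue = sample(ev_pool, n, replace = TRUE),
    bit_score = 100, strand = "+",
    hsp_score = pct * len
  )
}
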