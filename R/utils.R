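# Shared low-level helpers: DNA string ops, interval arithmetic, rounding.

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; handles the full IUPAC alphabet and preserves case.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp_dna(c("ACGT", "TG"))
#' @export
revcomp_dna <- function(x) {
  comp <- chartr(
    "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
    x
  )
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

is_iupac_dna <- function(x) {
  grepl(sprintf("^[%s%s]*$", IUPAC_CHARS, tolower(IUPAC_CHARS)), x)
}

# Empty mask: 0-row integer matrix with start/end columns (0-based half-open).
empty_mask <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

as_mask <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

# Sort and merge possibly overlapping half-open intervals.
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(empty_mask())
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out_s <- m[1, 1]
  out_e <- m[1, 2]
  k <- 1L
  starts <- integer(nrow(m))
  ends <- integer(nrow(m))
  starts[1] <- out_s
  ends[1] <- out_e
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= ends[k]) {
        ends[k] <- max(ends[k], m[i, 2])
      } else {
        k <- k + 1L
        starts[k] <- m[i, 1]
        ends[k] <- m[i, 2]
      }
    }
  }
  as_mask(starts[1:k], ends[1:k])
}

interval_total <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(0L)
  sum(m[, 2] - m[, 1])
}

# Complement of intervals within [0, len): the unmasked runs.
complement_intervals <- function(m, len) {
  m <- merge_intervals(m)
  if (nrow(m) == 0) {
    if (len == 0) return(empty_mask())
    return(as_mask(0L, len))
  }
  starts <- c(0L, m[, 2])
  ends <- c(m[, 1], as.integer(len))
  keep <- ends > starts
  as_mask(starts[keep], ends[keep])
}

# Total overlap (bp) between one half-open interval and an interval matrix.
overlap_with_intervals <- function(start, end, m) {
  if (is.null(m) || nrow(m) == 0 || end <= start) return(0L)
  lo <- pmax(m[, 1], start)
  hi <- pmin(m[, 2], end)
  sum(pmax(0L, hi - lo))
}

#' Round half away from zero
#'
#' Deterministic half-up rounding at a fixed number of decimals, as used for
#' every printed percentage and ratio in the survey tables (base R `round()`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run bounds of lowercase letters in a sequence -> mask matrix.
lowercase_intervals <- function(seq) {
  if (nchar(seq) == 0) return(empty_mask())
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  low <- chars %in% strsplit(tolower(IUPAC_CHARS), "")[[1]]
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(empty_mask())
  as_mask(starts[keep], ends[keep])
}

apply_softmask <- function(seq, mask) {
  if (nrow(mask) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(mask))) {
    idx <- (mask[i, 1] + 1L):mask[i, 2]
    chars[idx] <- tolower(chars[idx])
  }
  paste(chars, collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Substitution-diverge a sequence at the given per-base rate.
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    chars[hit] <- vapply(chars[hit], function(b) {
      choices <- alt[[b]]
      if (is.null(choices)) b else sample(choices, 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
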