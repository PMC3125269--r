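# External formats: FASTA end-reads, BLAST tabular (-m9 dialect, 12 columns),
# BED6 synteny export, genotype TSV.

read_fasta_records <- function(path, collapse = "") {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1] && any(nzchar(lines))) {
    stop("not a FASTA file (first line is not a header): ", path)
  }
  idx <- which(hdr)
  if (!length(idx)) {
    return(tibble(name = character(0), seq = character(0), line = integer(0)))
  }
  starts <- idx + 1L
  ends <- c(idx[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(idx), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = collapse)
  }, character(1))
  if (collapse == "") seqs <- gsub("[ \t]", "", seqs)
  tibble(
    name = sub("^>\\s*", "", lines[idx]),
    seq = seqs,
    line = idx
  )
}

write_fasta_records <- function(names, seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(names)) {
    writeLines(paste0(">", names[i]), con)
    s <- seqs[i]
    if (nchar(s) == 0) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read BAC-end reads from FASTA
#'
#' Parses a FASTA file of BAC-end sequences into a tidy table of reads. The
#' clone identity and end label are decoded from the record name with a
#' configurable regular expression whose two capture groups are the clone id
#' and the end token; the default convention is `<clone>_T7` (forward /
#' T7-primer end) and `<clone>_SP6` (reverse / Sp6-primer end). Lowercase
#' bases are imported as soft-mask intervals so externally masked FASTA
#' interoperates with [mask_with_library()].
#'
#' Records with a malformed header or non-IUPAC characters are dropped with a
#' warning naming the offending line (or rejected with an error when
#' `strict = TRUE`).
#'
#' @param path FASTA file of end reads.
#' @param qual_path Optional FASTA-like `.qual` file with space-separated
#'   phred scores per record, in the same order as `path`.
#' @param header_pattern Regex with two capture groups, clone id then end
#'   token, applied to the first whitespace-delimited word of each header.
#' @param forward_token,reverse_token End tokens mapped to the forward and
#'   reverse read of a clone.
#' @param strict Error (rather than warn and drop) on malformed records.
#' @return A tibble with columns `read_id`, `clone_id`,
#'   `end` (`"forward"`/`"reverse"`), `bases`, `quals` (list column of
#'   integer vectors or `NULL`), and `mask` (list column of two-column
#'   integer matrices of 0-based half-open intervals).
#' @seealso [write_bes_fasta()] for the exact inverse.
#' @export
read_bes_fasta <- function(path, qual_path = NULL,
                           header_pattern = "^(.+)_(T7|SP6)$",
                           forward_token = "T7", reverse_token = "SP6",
                           strict = FALSE) {
  rec <- read_fasta_records(path)
  if (nrow(rec) == 0) {
    return(tibble(
      read_id = character(0), clone_id = character(0), end = character(0),
      bases = character(0), quals = list(), mask = list()
    ))
  }
  word <- sub("\\s.*$", "", rec$name)
  m <- regmatches(word, regexec(header_pattern, word))
  ok_hdr <- lengths(m) == 3
  ok_seq <- is_iupac_dna(rec$seq)
  bad <- !ok_hdr | !ok_seq
  if (any(bad)) {
    msgs <- paste0(
      "line ", rec$line[bad], " ('", word[bad], "'): ",
      ifelse(!ok_hdr[bad], "header does not match naming convention",
             "non-IUPAC character in sequence")
    )
    if (strict) stop(paste(msgs, collapse = "\n"))
    warning("dropped ", sum(bad), " record(s):\n", paste(msgs, collapse = "\n"))
  }
  keep <- which(!bad)
  clone <- vapply(m[keep], `[`, character(1), 2)
  token <- vapply(m[keep], `[`, character(1), 3)
  end <- ifelse(token == forward_token, "forward",
                ifelse(token == reverse_token, "reverse", NA_character_))
  if (anyNA(end)) stop("end token not among forward/reverse tokens")

  quals <- rep(list(NULL), length(keep))
  if (!is.null(qual_path)) {
    q <- read_fasta_records(qual_path, collapse = " ")
    qmap <- setNames(q$seq, sub("\\s.*$", "", q$name))
    quals <- lapply(seq_along(keep), function(i) {
      s <- qmap[[word[keep[i]]]]
      if (is.null(s)) return(NULL)
      as.integer(strsplit(trimws(gsub("\\s+", " ", s)), " ")[[1]])
    })
    lens <- vapply(quals, function(q) if (is.null(q)) -1L else length(q), 1L)
    mismatch <- lens >= 0 & lens != nchar(rec$seq[keep])
    if (any(mismatch)) stop("quality length differs from sequence length for: ",
                            paste(word[keep][mismatch], collapse = ", "))
  }
  out <- tibble(
    read_id = word[keep],
    clone_id = clone,
    end = end,
    bases = rec$seq[keep],
    quals = quals,
    mask = lapply(rec$seq[keep], lowercase_intervals)
  )
  dup <- duplicated(out[, c("clone_id", "end")])
  if (any(dup)) stop("duplicate (clone_id, end) records: ",
                     paste(out$read_id[dup], collapse = ", "))
  out
}

#' Write BAC-end reads to FASTA
#'
#' Inverse of [read_bes_fasta()]: mask intervals are written as lowercase
#' (soft masking) and qualities, when present, to a FASTA-like `.qual` file.
#'
#' @param reads Read table as returned by [read_bes_fasta()].
#' @param path Output FASTA path.
#' @param qual_path Optional output path for per-base qualities.
#' @param width Line width for wrapped sequence.
#' @return `path`, invisibly.
#' @export
write_bes_fasta <- function(reads, path, qual_path = NULL, width = 70L) {
  seqs <- vapply(seq_len(nrow(reads)), function(i) {
    apply_softmask(toupper(reads$bases[i]), reads$mask[[i]])
  }, character(1))
  write_fasta_records(reads$read_id, seqs, path, width)
  if (!is.null(qual_path)) {
    con <- file(qual_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(reads))) {
      q <- reads$quals[[i]]
      if (is.null(q)) next
      writeLines(paste0(">", reads$read_id[i]), con)
      writeLines(paste(q, collapse = " "), con)
    }
  }
  invisible(path)
}

#' Parse BLAST tabular output (12-column `-m9` dialect)
#'
#' Reads tab-separated BLAST output with optional `#` comment lines and
#' exactly 12 fields per hit line. Query coordinates are normalised to
#' `q_start <= q_end`; the alignment strand is recorded in a `strand` column
#' and is minus when exactly one of the coordinate pairs was descending in
#' the file (subject order for nucleotide searches, query order for
#' translated searches). Subject coordinates are kept as printed, so for
#' nucleotide hits `s_start > s_end` still encodes the minus strand. The
#' tie-break score `hsp_score = pct_identity * aln_length` is computed on
#' load.
#'
#' @param path Path to a BLAST tabular file.
#' @return A tibble with the 12 standard columns plus `strand` and
#'   `hsp_score`.
#' @export
parse_blast_tab <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end",
            "s_start", "s_end", "evalue", "bit_score")
  if (!length(lines)) {
    out <- as_tibble(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)), cols))
    out$strand <- character(0)
    out$hsp_score <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    i <- which(nf != 12)[1]
    stop("line ", lineno[i], ": expected 12 tab-separated fields, found ", nf[i])
  }
  mat <- do.call(rbind, parts)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(v) & !is.na(mat[, j]))
    if (length(bad)) {
      stop("line ", lineno[bad[1]], ": field ", j, " (", cols[j],
           ") is not a number: '", mat[bad[1], j], "'")
    }
    v
  }
  out <- tibble(
    query_id = mat[, 1], subject_id = mat[, 2],
    pct_identity = num(3), aln_length = num(4),
    mismatches = num(5), gap_opens = num(6),
    q_start = num(7), q_end = num(8),
    s_start = num(9), s_end = num(10),
    evalue = num(11), bit_score = num(12)
  )
  if (any(out$evalue < 0)) stop("negative e-value encountered")
  q_rev <- out$q_start > out$q_end
  s_rev <- out$s_start > out$s_end
  out$strand <- ifelse(xor(q_rev, s_rev), "-", "+")
  qs <- pmin(out$q_start, out$q_end)
  qe <- pmax(out$q_start, out$q_end)
  out$q_start <- qs
  out$q_end <- qe
  out$hsp_score <- out$pct_identity * out$aln_length
  out
}

#' Write hits in BLAST 12-column tabular format
#'
#' @param hits Hit table in the schema of [parse_blast_tab()]. The `strand`
#'   column is re-encoded in coordinate order: minus-strand nucleotide hits
#'   get descending subject coordinates as emitted, and rows flagged
#'   `translated = TRUE` (if present) carry strand in the query order.
#' @param path Output path.
#' @param comment Optional comment line written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  if (nrow(hits)) {
    translated <- if ("translated" %in% names(hits)) hits$translated else
      rep(FALSE, nrow(hits))
    qs <- hits$q_start
    qe <- hits$q_end
    ss <- hits$s_start
    se <- hits$s_end
    flipq <- hits$strand == "-" & translated
    qs[flipq] <- hits$q_end[flipq]
    qe[flipq] <- hits$q_start[flipq]
    need_flip_s <- hits$strand == "-" & !translated & ss <= se
    ss[need_flip_s] <- hits$s_end[need_flip_s]
    se[need_flip_s] <- hits$s_start[need_flip_s]
    lines <- paste(hits$query_id, hits$subject_id,
                   formatC(hits$pct_identity, format = "fg"),
                   hits$aln_length, hits$mismatches, hits$gap_opens,
                   qs, qe, ss, se,
                   formatC(hits$evalue, format = "g", digits = 6),
                   formatC(hits$bit_score, format = "fg"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Export microsynteny calls as BED6
#'
#' Writes same-chromosome synteny calls as BED6 intervals on the reference
#' genome (0-based half-open), named by clone, sorted by `(chrom, start)`.
#' Calls without reference coordinates are skipped with a warning.
#'
#' @param calls Synteny call table from [call_synteny()] (needs `chrom`,
#'   `ref_start`, `ref_end`, `clone_id`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_synteny_bed <- function(calls, path) {
  has_coord <- !is.na(calls$chrom) & !is.na(calls$ref_start) &
    !is.na(calls$ref_end)
  if (any(!has_coord)) {
    warning("skipping ", sum(!has_coord), " call(s) without reference coordinates")
  }
  b <- calls[has_coord, , drop = FALSE]
  b <- b[order(b$chrom, b$ref_start), , drop = FALSE]
  lines <- if (nrow(b)) {
    paste(b$chrom, format(b$ref_start - 1L, scientific = FALSE, trim = TRUE),
          format(b$ref_end, scientific = FALSE, trim = TRUE),
          b$clone_id, 0L, "+", sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype table
#'
#' Tab-separated with a header `marker` and `parent` followed by allele size
#' columns (`allele1`, `allele2`, ... as many as the data need; two for a
#' plain diploid table). A blank cell is a missing allele; the token `NP`
#' marks a failed, product-less amplification for that parent. Allele sizes
#' are fragment lengths in base pairs.
#'
#' @param path Input TSV path.
#' @return Tibble with `marker_id`, `parent_id`, `alleles` (list column of
#'   integer vectors) and `no_product` (logical).
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  need <- c("marker", "parent")
  if (!all(need %in% names(df))) stop("genotype table needs columns marker, parent")
  allele_cols <- grep("^allele", names(df), value = TRUE)
  if (!length(allele_cols)) stop("genotype table needs at least one allele column")
  dup <- duplicated(df[, need])
  if (any(dup)) {
    stop("duplicate (marker, parent) rows: ",
         paste(unique(paste(df$marker[dup], df$parent[dup])), collapse = ", "))
  }
  amat <- as.matrix(df[, allele_cols, drop = FALSE])
  rows <- lapply(seq_len(nrow(df)), function(i) {
    vals <- trimws(amat[i, ])
    vals <- vals[nzchar(vals)]
    if (any(vals == "NP")) {
      if (!all(vals == "NP")) stop("row ", i, ": NP mixed with allele sizes")
      return(list(alleles = integer(0), no_product = TRUE))
    }
    sizes <- suppressWarnings(as.integer(vals))
    if (anyNA(sizes)) stop("row ", i, ": unparsable allele size")
    if (any(sizes < 0)) stop("row ", i, ": negative allele size")
    list(alleles = sizes, no_product = FALSE)
  })
  tibble(
    marker_id = df$marker,
    parent_id = df$parent,
    alleles = lapply(rows, `[[`, "alleles"),
    no_product = vapply(rows, `[[`, logical(1), "no_product")
  )
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; emits as many `allele<k>` columns as
#' the widest genotype needs (minimum two).
#'
#' @param genotypes Genotype tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  k <- max(2L, if (nrow(genotypes)) max(lengths(genotypes$alleles)) else 2L)
  header <- c("marker", "parent", paste0("allele", seq_len(k)))
  lines <- vapply(seq_len(nrow(genotypes)), function(i) {
    a <- genotypes$alleles[[i]]
    cells <- if (genotypes$no_product[i]) {
      c("NP", rep("", k - 1L))
    } else {
      c(as.character(a), rep("", k - length(a)))
    }
    paste(c(genotypes$marker_id[i], genotypes$parent_id[i], cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}
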