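# Seeded synthetic-data generator: a source genome with implanted repeat
# families and SSR loci, a rearranged multi-chromosome reference sharing its
# blocks, paired BAC-end reads with qualities, emulated BLAST tabular hits
# (nucleotide and translated) with configurable noise, genotype tables, and
# a ground-truth registry tying every artefact back to its origin.

default_repeat_families <- function() {
  tibble(
    name = sprintf("RT_rep_%02d", 1:12),
    repeat_class = c("DNA/TcMar-Tc1", "DNA/Tc1", "LINE/L2", "LINE/Rex1",
                     "LINE/L1", "SINE", "SINE/Deu", "LTR/Gypsy", "Unknown",
                     "Unknown", "Unknown", "Unknown"),
    consensus_len = c(1500L, 1300L, 1100L, 1000L, 900L, 350L, 300L, 1200L,
                      800L, 600L, 500L, 400L),
    weight = c(10, 3, 2, 2, 1.5, 1, 1, 1.5, 4, 3, 2, 2),
    divergence = rep(0.12, 12)
  )
}

# Default SSR class mix: dinucleotide-dominated with the TG/CA class on top,
# a tail of tetra- to decanucleotide motifs (all primitive motifs).
default_ssr_motifs <- function() {
  c(TG = 0.195, AC = 0.179, GA = 0.088, TA = 0.073, AG = 0.072, AT = 0.045,
    A = 0.010, C = 0.002,
    AAT = 0.006, ATA = 0.006, CAT = 0.003, TTA = 0.004, AAC = 0.002,
    TGTA = 0.010, CACA = 0.006, TCTG = 0.006, AGAC = 0.006, TATG = 0.005,
    CTCA = 0.004, ACAC = 0.004, ATAC = 0.004, AGAA = 0.003, ACAT = 0.003,
    TCAAA = 0.003, ATTTG = 0.003, TTCGA = 0.010,
    ATCGGA = 0.025, TTGACG = 0.025,
    ATCGGAC = 0.012,
    TTACGGAC = 0.040,
    TTACGGACA = 0.021,
    TTACGGACAT = 0.069)
}

#' Configuration for the synthetic BES study
#'
#' Defaults emulate the sequencing regime of a large-insert BAC-end survey:
#' ~92% of clones with both ends sequenced, read lengths 101-832 bp with
#' mean 546 bp, inserts 100-200 kb (so intact paired ends span the
#' microsynteny window), GC 42%, and a repeat landscape covering 59.5% of
#' the genome dominated by a Tc1-transposon-like family. Problem sizes
#' (genome length, clone count) are desk-scale stand-ins for a genome-scale
#' survey.
#'
#' @param seed Mandatory RNG seed; every generator is fully deterministic
#'   given the config.
#' @param genome_len Source genome length, bp.
#' @param n_chrom Number of reference chromosomes.
#' @param gc GC fraction of background sequence.
#' @param repeat_families Tibble with `name`, `repeat_class`,
#'   `consensus_len`, `weight`, `divergence` describing implanted families.
#' @param repeat_target_fraction Fraction of the genome covered by implanted
#'   repeat copies (<= 0.95).
#' @param ssr_rate Implanted SSR loci per kb of non-repeat sequence.
#' @param ssr_motifs Named probability vector over SSR motifs.
#' @param n_genes Gene annotations implanted (for translated searches).
#' @param gene_len_range Gene length range, bp.
#' @param n_clones Number of BAC clones.
#' @param insert_range Clone insert size range, bp.
#' @param both_end_rate Probability a clone has both ends sequenced.
#' @param read_len_range,read_len_mean Read length range and mean, bp.
#' @param rearrangement_rate Rearrangement breakpoints per Mb between source
#'   and reference.
#' @param hit_noise Named vector `miss_rate`, `paralog_rate`, `tie_rate`
#'   controlling emulated hit noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_len = 5e6,
                       n_chrom = 5L,
                       gc = 0.42,
                       repeat_families = default_repeat_families(),
                       repeat_target_fraction = 0.595,
                       ssr_rate = 0.07,
                       ssr_motifs = default_ssr_motifs(),
                       n_genes = 300L,
                       gene_len_range = c(2000L, 10000L),
                       n_clones = 2000L,
                       insert_range = c(1e5, 2e5),
                       both_end_rate = 0.92,
                       read_len_range = c(101L, 832L),
                       read_len_mean = 546,
                       rearrangement_rate = 2,
                       hit_noise = c(miss_rate = 0.1, paralog_rate = 0.1,
                                     tie_rate = 0.05)) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(
    seed == as.integer(seed), genome_len > 0, n_chrom >= 2,
    gc > 0, gc < 1,
    repeat_target_fraction >= 0, repeat_target_fraction <= 0.95,
    ssr_rate >= 0, n_clones >= 1,
    insert_range[1] > 0, insert_range[2] >= insert_range[1],
    insert_range[2] < genome_len,
    both_end_rate >= 0, both_end_rate <= 1,
    read_len_range[1] > 0, read_len_range[2] > read_len_range[1],
    read_len_mean > read_len_range[1], read_len_mean < read_len_range[2],
    rearrangement_rate >= 0,
    all(c("miss_rate", "paralog_rate", "tie_rate") %in% names(hit_noise)),
    all(hit_noise >= 0 & hit_noise <= 1)
  )
  structure(list(
    seed = as.integer(seed), genome_len = as.integer(genome_len),
    n_chrom = as.integer(n_chrom), gc = gc,
    repeat_families = repeat_families,
    repeat_target_fraction = repeat_target_fraction,
    ssr_rate = ssr_rate, ssr_motifs = ssr_motifs,
    n_genes = as.integer(n_genes), gene_len_range = as.integer(gene_len_range),
    n_clones = as.integer(n_clones), insert_range = as.integer(insert_range),
    both_end_rate = both_end_rate,
    read_len_range = as.integer(read_len_range), read_len_mean = read_len_mean,
    rearrangement_rate = rearrangement_rate, hit_noise = hit_noise
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic BES study configuration\n")
  cat(sprintf("  seed %d; genome %s bp on %d chromosomes; GC %.2f\n",
              x$seed, format(x$genome_len, big.mark = ","), x$n_chrom, x$gc))
  cat(sprintf("  repeats: %d families, target fraction %.3f\n",
              nrow(x$repeat_families), x$repeat_target_fraction))
  cat(sprintf("  clones: %d, inserts %s-%s bp, both-end rate %.2f\n",
              x$n_clones, format(x$insert_range[1], big.mark = ","),
              format(x$insert_range[2], big.mark = ","), x$both_end_rate))
  cat(sprintf("  reads: %d-%d bp, mean %g\n", x$read_len_range[1],
              x$read_len_range[2], x$read_len_mean))
  cat(sprintf("  rearrangements: %g / Mb; noise miss %.2f, paralog %.2f, tie %.2f\n",
              x$rearrangement_rate, x$hit_noise[["miss_rate"]],
              x$hit_noise[["paralog_rate"]], x$hit_noise[["tie_rate"]]))
  invisible(x)
}

# Map source positions (1-based) through the block table to reference
# coordinates. Returns NA chrom for positions outside a single block.
map_interval_to_ref <- function(blocks, src_lo, src_hi) {
  bi <- findInterval(src_lo, blocks$src_start)
  ok <- bi >= 1 & src_hi <= blocks$src_end[pmax(bi, 1)]
  b <- blocks[pmax(bi, 1), , drop = FALSE]
  plus <- b$strand == "+"
  lo <- ifelse(plus, b$ref_start + (src_lo - b$src_start),
               b$ref_start + (b$src_end - src_hi))
  hi <- ifelse(plus, b$ref_start + (src_hi - b$src_start),
               b$ref_start + (b$src_end - src_lo))
  tibble(
    chrom = ifelse(ok, b$chrom, NA_character_),
    lo = ifelse(ok, lo, NA_real_),
    hi = ifelse(ok, hi, NA_real_),
    block_strand = ifelse(ok, b$strand, NA_character_),
    block = ifelse(ok, bi, NA_integer_)
  )
}

#' Simulate the source genome and a rearranged reference
#'
#' Builds a random source genome with repeat copies implanted by an
#' alternating background-gap / repeat-copy walk until the target repeat
#' fraction is met, perfect SSR arrays implanted in background gaps (flanking
#' bases adjusted so implanted array boundaries are exact), and gene
#' annotations for translated searches. The reference genome is the source
#' cut at rearrangement breakpoints into blocks that are dealt round-robin
#' onto chromosomes, each block inverted with probability 1/2; adjacent
#' source blocks therefore always land on different chromosomes, so a clone
#' insert straddling a breakpoint is discordant by construction. Repeats,
#' SSRs and genes are implanted before rearrangement, so both genomes share
#' them. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return `list(source, reference, library, registry)`: the source sequence,
#'   a tibble of reference chromosomes, the repeat library (true family
#'   consensi), and the truth registry (blocks, implanted repeats, SSRs,
#'   genes, gene reference locations).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  glen <- config$genome_len
  fams <- config$repeat_families
  if (config$repeat_target_fraction > 0 && nrow(fams) == 0) {
    stop("repeat_target_fraction > 0 requires repeat families")
  }
  fams$consensus <- vapply(fams$consensus_len, random_dna, character(1),
                           gc = config$gc)
  f <- config$repeat_target_fraction
  mean_copy <- sum(fams$consensus_len * fams$weight) / sum(fams$weight)
  if (f > 0 && mean_copy * (1 - f) / f < 1) {
    stop("repeat_target_fraction too high for these family lengths")
  }

  # background / repeat-copy walk
  pieces <- character(0)
  rep_start <- integer(0)
  rep_end <- integer(0)
  rep_family <- character(0)
  pos <- 0L
  gap_mean <- if (f > 0) mean_copy * (1 - f) / f else Inf
  while (pos < glen) {
    gap <- if (is.finite(gap_mean)) {
      min(glen - pos, max(20L, as.integer(rexp(1, 1 / gap_mean))))
    } else {
      glen - pos
    }
    pieces <- c(pieces, random_dna(gap, config$gc))
    pos <- pos + gap
    if (pos >= glen || !is.finite(gap_mean)) break
    fi <- sample.int(nrow(fams), 1, prob = fams$weight)
    copy_len <- min(fams$consensus_len[fi], glen - pos)
    copy <- substr(fams$consensus[fi], 1, copy_len)
    copy <- mutate_dna(copy, fams$divergence[fi])
    if (runif(1) < 0.5) copy <- revcomp_dna(copy)
    pieces <- c(pieces, copy)
    rep_start <- c(rep_start, pos)             # 0-based
    rep_end <- c(rep_end, pos + copy_len)
    rep_family <- c(rep_family, fams$name[fi])
    pos <- pos + copy_len
  }
  source <- paste(pieces, collapse = "")
  source <- substr(source, 1, glen)
  repeats <- tibble(start = rep_start, end = pmin(rep_end, glen),
                    family = rep_family)
  repeats <- repeats[repeats$end > repeats$start, , drop = FALSE]

  # SSR implants inside background gaps
  gaps <- complement_intervals(as_mask(repeats$start, repeats$end), glen)
  ssrs <- implant_ssrs(gaps, config)
  if (nrow(ssrs)) {
    chars <- strsplit(source, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(ssrs))) {
      a <- ssrs$start[i]
      b <- ssrs$end[i]
      motif <- strsplit(ssrs$motif[i], "", fixed = TRUE)[[1]]
      p <- length(motif)
      idx <- (a + 1L):b
      chars[idx] <- motif[((idx - a - 1L) %% p) + 1L]
      # break period-p agreement across both seams so implanted array
      # boundaries are exact even under mismatch-tolerant chaining:
      # no position pairing across a boundary may match at lag p
      for (j in a:(max(1L, a - p))) {          # left flank, descending
        if (j >= 1L && j + p <= glen && chars[j] == chars[j + p]) {
          chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j + p]), 1)
        }
      }
      for (j in (b - p + 1L):(b + 1L)) {       # right flank, ascending
        if (j >= 1L && j + p <= glen && chars[j + p] == chars[j]) {
          chars[j + p] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
        }
      }
    }
    source <- paste(chars, collapse = "")
  }

  # gene annotations (may overlap anything; used by translated searches)
  genes <- implant_genes(config)

  # rearrangement into reference chromosomes
  n_bkpt <- rpois(1, config$rearrangement_rate * glen / 1e6)
  bkpt <- sort(unique(sample.int(glen - 1L, min(n_bkpt, glen - 1L))))
  seg_start <- c(1L, bkpt + 1L)
  seg_end <- c(bkpt, glen)
  n_seg <- length(seg_start)
  chrom_of <- ((seq_len(n_seg) - 1L) %% config$n_chrom) + 1L
  strand_of <- ifelse(runif(n_seg) < 0.5, "+", "-")
  blocks <- tibble(
    src_start = seg_start, src_end = seg_end,
    chrom = paste0("chr", chrom_of), strand = strand_of
  )
  blocks <- blocks %>%
    group_by(.data$chrom) %>%
    mutate(ref_start = cumsum(dplyr::lag(.data$src_end - .data$src_start + 1L,
                                         default = 0L)) + 1L) %>%
    ungroup()
  ref_seqs <- vapply(split(blocks, blocks$chrom), function(b) {
    b <- b[order(b$ref_start), , drop = FALSE]
    paste(vapply(seq_len(nrow(b)), function(i) {
      s <- substr(source, b$src_start[i], b$src_end[i])
      if (b$strand[i] == "-") revcomp_dna(s) else s
    }, character(1)), collapse = "")
  }, character(1))
  reference <- tibble(chrom = names(ref_seqs), seq = unname(ref_seqs))

  gene_loci <- gene_ref_loci(genes, blocks)
  library <- tibble(name = fams$name, repeat_class = fams$repeat_class,
                    consensus = fams$consensus)
  registry <- list(
    config = config, blocks = blocks, repeats = repeats, ssrs = ssrs,
    genes = genes, gene_loci = gene_loci
  )
  list(source = source, reference = reference, library = library,
       registry = registry)
}

implant_ssrs <- function(gaps, config) {
  motifs <- config$ssr_motifs
  gap_len <- gaps[, 2] - gaps[, 1]
  usable <- gaps[gap_len >= 80, , drop = FALSE]
  total_kb <- sum(usable[, 2] - usable[, 1]) / 1000
  n_ssr <- rpois(1, config$ssr_rate * total_kb)
  if (n_ssr == 0 || nrow(usable) == 0) {
    return(tibble(start = integer(0), end = integer(0), motif = character(0),
                  period = integer(0), copies = integer(0)))
  }
  out <- vector("list", n_ssr)
  placed <- empty_mask()
  for (i in seq_len(n_ssr)) {
    g <- sample.int(nrow(usable), 1,
                    prob = usable[, 2] - usable[, 1])
    motif <- sample(names(motifs), 1, prob = motifs)
    p <- nchar(motif)
    min_cp <- max(ifelse(p <= 2, 4, 3), ceiling(12 / p))
    max_cp <- max(min_cp, floor(60 / p))
    copies <- sample(min_cp:max_cp, 1)
    len <- copies * p
    lo <- usable[g, 1] + 16L
    hi <- usable[g, 2] - 16L - len
    if (hi <= lo) next
    start <- lo + sample.int(hi - lo, 1)
    if (overlap_with_intervals(start - 30L, start + len + 30L, placed) > 0) next
    placed <- merge_intervals(rbind(placed, as_mask(start, start + len)))
    out[[i]] <- tibble(start = start, end = start + len, motif = motif,
                       period = p, copies = copies)
  }
  res <- bind_rows(out)
  if (nrow(res)) res <- res[order(res$start), , drop = FALSE]
  res
}

implant_genes <- function(config) {
  if (config$n_genes == 0) {
    return(tibble(gene_id = character(0), src_start = integer(0),
                  src_end = integer(0), strand = character(0),
                  n_peptides = integer(0)))
  }
  placed <- empty_mask()
  out <- vector("list", config$n_genes)
  attempts <- 0L
  i <- 0L
  while (i < config$n_genes && attempts < config$n_genes * 20L) {
    attempts <- attempts + 1L
    len <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1)
    if (len >= config$genome_len) next
    start <- sample.int(config$genome_len - len, 1)
    if (overlap_with_intervals(start, start + len, placed) > 0) next
    placed <- merge_intervals(rbind(placed, as_mask(start, start + len)))
    i <- i + 1L
    out[[i]] <- tibble(
      gene_id = sprintf("GENE%04d", i),
      src_start = start + 1L, src_end = start + len,     # 1-based inclusive
      strand = sample(c("+", "-"), 1),
      n_peptides = sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
    )
  }
  bind_rows(out)
}

gene_ref_loci <- function(genes, blocks) {
  if (!nrow(genes)) {
    return(tibble(gene_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), strand = character(0)))
  }
  m <- map_interval_to_ref(blocks, genes$src_start, genes$src_end)
  placed <- !is.na(m$chrom)
  tibble(
    gene_id = genes$gene_id[placed],
    chrom = m$chrom[placed],
    start = m$lo[placed],
    end = m$hi[placed],
    strand = ifelse(m$block_strand[placed] == "+", genes$strand[placed],
                    ifelse(genes$strand[placed] == "+", "-", "+"))
  )
}

# Read length sampler: scaled beta with the configured mean, clipped to the
# configured range by construction.
sample_read_len <- function(n, config, concentration = 5) {
  lo <- config$read_len_range[1]
  hi <- config$read_len_range[2]
  m <- (config$read_len_mean - lo) / (hi - lo)
  as.integer(round(lo + (hi - lo) * rbeta(n, m * concentration,
                                          (1 - m) * concentration)))
}

# Plateau-with-degraded-tails quality model: only the >= 20 threshold
# behaviour matters downstream.
make_quals <- function(len) {
  q <- pmin(60L, pmax(21L, as.integer(round(rnorm(len, 38, 4)))))
  head_len <- min(5L, len)
  q[seq_len(head_len)] <- c(8L, 12L, 16L, 18L, 19L)[seq_len(head_len)]
  tail_len <- min(max(3L, round(0.05 * len)), len)
  if (tail_len > 0) {
    ramp <- as.integer(round(seq(19, 4, length.out = tail_len)))
    q[(len - tail_len + 1L):len] <- ramp
  }
  q
}

#' Simulate paired BAC-end reads
#'
#' Each clone receives an insert placed uniformly on the source genome with
#' length uniform in `insert_range`; with probability `both_end_rate` both
#' ends are sequenced, otherwise one random end. The forward read starts at
#' the left insert boundary on the top strand and the reverse read at the
#' right boundary on the bottom strand, so the two reads of a clone face
#' inward (this is what makes tail-to-tail geometry recoverable on the
#' reference). Read lengths follow the configured range and mean; qualities
#' are high on a central plateau and degrade at both tails.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genomes()].
#' @return `list(reads, clones)`: the read table (schema of
#'   [read_bes_fasta()]) and the per-clone truth table (insert coordinates,
#'   per-end read lengths and source intervals, expected reference placement:
#'   chromosome per end, inner gap, intactness and expected classification
#'   assuming unique true hits).
#' @export
simulate_bes <- function(config, sim) {
  set.seed(config$seed + 1L)
  glen <- config$genome_len
  n <- config$n_clones
  ins_len <- sample(config$insert_range[1]:config$insert_range[2], n,
                    replace = TRUE)
  ins_start <- vapply(ins_len, function(L) sample.int(glen - L + 1L, 1), 1L)
  both <- runif(n) < config$both_end_rate
  only_end <- ifelse(both, NA_character_,
                     sample(c("forward", "reverse"), n, replace = TRUE))
  len_f <- sample_read_len(n, config)
  len_r <- sample_read_len(n, config)
  clone_id <- sprintf("BAC%05d", seq_len(n))

  has_f <- both | only_end == "forward"
  has_r <- both | only_end == "reverse"
  f_lo <- ins_start                      # 1-based inclusive source coords
  f_hi <- ins_start + len_f - 1L
  r_hi <- ins_start + ins_len - 1L
  r_lo <- r_hi - len_r + 1L

  reads_f <- tibble(
    read_id = paste0(clone_id[has_f], "_T7"),
    clone_id = clone_id[has_f], end = "forward",
    src_lo = f_lo[has_f], src_hi = f_hi[has_f], src_strand = "+"
  )
  reads_r <- tibble(
    read_id = paste0(clone_id[has_r], "_SP6"),
    clone_id = clone_id[has_r], end = "reverse",
    src_lo = r_lo[has_r], src_hi = r_hi[has_r], src_strand = "-"
  )
  reads <- bind_rows(reads_f, reads_r) %>% arrange(.data$clone_id, .data$end)
  seqs <- substring(sim$source, reads$src_lo, reads$src_hi)
  seqs[reads$src_strand == "-"] <- revcomp_dna(seqs[reads$src_strand == "-"])
  reads$bases <- seqs
  reads$quals <- lapply(nchar(seqs), make_quals)
  reads$mask <- rep(list(empty_mask()), nrow(reads))

  blocks <- sim$registry$blocks
  mf <- map_interval_to_ref(blocks, f_lo, f_hi)
  mr <- map_interval_to_ref(blocks, r_lo, r_hi)
  same_block <- !is.na(mf$block) & !is.na(mr$block) & mf$block == mr$block
  same_chrom <- !is.na(mf$chrom) & !is.na(mr$chrom) & mf$chrom == mr$chrom
  gap <- ifelse(same_chrom,
                compute_span(mf$lo, mf$hi, mr$lo, mr$hi), NA_real_)
  # orientation on the reference: strands flip together under inversion, so
  # intact (same-block) clones are always tail-to-tail; across blocks the
  # left-hand hit must be plus.
  strand_f_ref <- ifelse(mf$block_strand == "+", "+", "-")
  strand_r_ref <- ifelse(mr$block_strand == "+", "-", "+")
  t2t <- ifelse(same_chrom,
                tail_to_tail(mf$lo, mf$hi, strand_f_ref,
                             mr$lo, mr$hi, strand_r_ref), NA)
  expected_class <- case_when(
    !(has_f & has_r) ~ "SINGLE_END",
    is.na(mf$chrom) | is.na(mr$chrom) ~ "UNPLACED",
    !same_chrom ~ "DISCORDANT",
    same_chrom & gap >= 10000 & gap <= 300000 & t2t ~ "MICRO",
    TRUE ~ "MACRO_ONLY"
  )
  n_bkpt_inside <- vapply(seq_len(n), function(i) {
    sum(blocks$src_start > ins_start[i] &
          blocks$src_start <= ins_start[i] + ins_len[i] - 1L)
  }, 1L)
  clones <- tibble(
    clone_id = clone_id,
    src_start = ins_start, insert_len = ins_len,
    has_forward = has_f, has_reverse = has_r,
    len_f = len_f, len_r = len_r,
    f_src_lo = f_lo, f_src_hi = f_hi, r_src_lo = r_lo, r_src_hi = r_hi,
    intact = same_block, breakpoint = n_bkpt_inside > 0,
    expected_chrom_f = mf$chrom, expected_chrom_r = mr$chrom,
    expected_strand_f = strand_f_ref, expected_strand_r = strand_r_ref,
    expected_gap = gap, expected_t2t = t2t,
    expected_class = expected_class
  )
  list(reads = reads, clones = clones)
}

read_repeat_fraction <- function(registry, src_lo, src_hi) {
  rep_iv <- as_mask(registry$repeats$start, registry$repeats$end)
  vapply(seq_along(src_lo), function(i) {
    overlap_with_intervals(src_lo[i] - 1L, src_hi[i], rep_iv) /
      (src_hi[i] - src_lo[i] + 1L)
  }, numeric(1))
}

empty_hits <- function() {
  tibble(query_id = character(0), subject_id = character(0),
         pct_identity = numeric(0), aln_length = numeric(0),
         mismatches = numeric(0), gap_opens = numeric(0),
         q_start = numeric(0), q_end = numeric(0),
         s_start = numeric(0), s_end = numeric(0),
         evalue = numeric(0), bit_score = numeric(0),
         strand = character(0), hsp_score = numeric(0),
         translated = logical(0))
}

scatter_hits <- function(read_id, n_hits, config, blocks) {
  chrom_len <- blocks %>%
    group_by(.data$chrom) %>%
    summarise(len = sum(.data$src_end - .data$src_start + 1L),
              .groups = "drop")
  ci <- sample.int(nrow(chrom_len), n_hits, replace = TRUE)
  len <- sample(50:200, n_hits, replace = TRUE)
  lo <- vapply(seq_len(n_hits), function(i) {
    sample.int(max(1L, chrom_len$len[ci[i]] - len[i]), 1)
  }, 1L)
  strand <- sample(c("+", "-"), n_hits, replace = TRUE)
  pct <- round(runif(n_hits, 75, 95), 2)
  tibble(
    query_id = read_id, subject_id = chrom_len$chrom[ci],
    pct_identity = pct, aln_length = len,
    mismatches = round((1 - pct / 100) * len), gap_opens = 0,
    q_start = 1, q_end = len,
    s_start = ifelse(strand == "+", lo, lo + len - 1),
    s_end = ifelse(strand == "+", lo + len - 1, lo),
    evalue = 10^runif(n_hits, -40, -6), bit_score = round(len * 1.2, 1),
    strand = strand, hsp_score = pct * len, translated = FALSE
  )
}

#' Emulate BLAST tabular hits for simulated reads
#'
#' Stands in for running nucleotide or translated searches against the
#' rearranged reference. For each read mapping inside a conserved block a
#' true hit is emitted at the mapped reference location (coordinates and
#' strand follow the block's rearrangement history) with an e-value far
#' below the filtration cutoff. Noise is configurable: with `miss_rate` the
#' true hit is withheld; with `paralog_rate` a weaker decoy on another
#' chromosome accompanies it (removed by the minimal-e-value step); with
#' `tie_rate` the best hit is duplicated on a second chromosome at equal
#' e-value and HSP product (forcing non-uniqueness). Reads dominated by
#' implanted repeats receive many scattered hits instead. Translated mode
#' emits peptide subjects (sometimes several peptides of one gene, at equal
#' score, to exercise gene collapsing) together with the protein-to-gene
#' map; the frame sign is encoded in query coordinate order as in real
#' translated tabular output.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genomes()].
#' @param bes Output of [simulate_bes()].
#' @param mode `"nucleotide"` or `"protein"`.
#' @param reads Optional subset of `bes$reads` to emulate hits for (default
#'   all reads).
#' @return `list(hits, per_read, protein_to_gene, gene_loci)`; `per_read`
#'   records each read's emitted-truth status (`unique_true`, `tied`,
#'   `missing`, `repetitive_multi`, `no_hit`).
#' @export
emulate_blast_hits <- function(config, sim, bes,
                               mode = c("nucleotide", "protein"),
                               reads = NULL) {
  mode <- match.arg(mode)
  set.seed(config$seed + if (mode == "nucleotide") 2L else 3L)
  reads <- reads %||% bes$reads
  registry <- sim$registry
  blocks <- registry$blocks
  noise <- config$hit_noise
  rep_frac <- read_repeat_fraction(registry, reads$src_lo, reads$src_hi)

  out <- vector("list", nrow(reads))
  status <- character(nrow(reads))
  p2g <- NULL
  if (mode == "protein") {
    genes <- registry$genes
    gid <- rep(genes$gene_id, genes$n_peptides)
    p2g <- tibble(
      protein_id = paste0(gid, "_P", unlist(lapply(genes$n_peptides, seq_len))),
      gene_id = gid
    )
  }

  for (i in seq_len(nrow(reads))) {
    rid <- reads$read_id[i]
    L <- reads$src_hi[i] - reads$src_lo[i] + 1L
    if (rep_frac[i] > 0.5) {
      sc <- scatter_hits(rid, sample(8:30, 1), config, blocks)
      if (mode == "protein") {
        # repeat-derived translated hits land on scattered peptides
        sc$subject_id <- p2g$protein_id[
          sample.int(nrow(p2g), nrow(sc), replace = TRUE)]
        sc$s_start <- 1
        sc$s_end <- floor(sc$aln_length / 3)
        sc$translated <- TRUE
      }
      out[[i]] <- sc
      status[i] <- "repetitive_multi"
      next
    }
    if (mode == "nucleotide") {
      m <- map_interval_to_ref(blocks, reads$src_lo[i], reads$src_hi[i])
      if (is.na(m$chrom[1])) {
        # read straddles a block boundary: map the larger piece
        piece <- straddle_major_piece(blocks, reads$src_lo[i], reads$src_hi[i])
        if (is.null(piece) || piece$len < 50) { status[i] <- "no_hit"; next }
        m <- map_interval_to_ref(blocks, piece$lo, piece$hi)
        q_off <- piece$q_off
        alen <- piece$len
      } else {
        q_off <- 0L
        alen <- L
      }
      if (runif(1) < noise[["miss_rate"]]) { status[i] <- "missing"; next }
      strand <- if (reads$src_strand[i] == m$block_strand[1]) "+" else "-"
      pct <- round(runif(1, 95, 99.9), 2)
      ev <- 10^(-runif(1, 60, 120))
      true_hit <- tibble(
        query_id = rid, subject_id = m$chrom[1],
        pct_identity = pct, aln_length = alen,
        mismatches = round((1 - pct / 100) * alen), gap_opens = 0,
        q_start = 1 + q_off, q_end = q_off + alen,
        s_start = ifelse(strand == "+", m$lo[1], m$hi[1]),
        s_end = ifelse(strand == "+", m$hi[1], m$lo[1]),
        evalue = ev, bit_score = round(alen * 1.8, 1),
        strand = strand, hsp_score = pct * alen, translated = FALSE
      )
      hits <- true_hit
      if (runif(1) < noise[["paralog_rate"]]) {
        decoy <- scatter_hits(rid, 1L, config, blocks)
        decoy$evalue <- min(ev * 1e15, 9e-6)
        hits <- bind_rows(hits, decoy)
      }
      other <- setdiff(unique(blocks$chrom), m$chrom[1])
      if (runif(1) < noise[["tie_rate"]] && length(other)) {
        tie <- true_hit
        tie$subject_id <- other[sample.int(length(other), 1)]
        shift <- sample.int(1e5, 1)
        tie$s_start <- true_hit$s_start + shift
        tie$s_end <- true_hit$s_end + shift
        hits <- bind_rows(hits, tie)
        status[i] <- "tied"
      } else {
        status[i] <- "unique_true"
      }
      out[[i]] <- hits
    } else {
      genes <- registry$genes
      ov_lo <- pmax(genes$src_start, reads$src_lo[i])
      ov_hi <- pmin(genes$src_end, reads$src_hi[i])
      ov <- pmax(0L, ov_hi - ov_lo + 1L)
      gi <- which.max(ov)
      if (!length(gi) || ov[gi] < 60) { status[i] <- "no_hit"; next }
      if (runif(1) < noise[["miss_rate"]]) { status[i] <- "missing"; next }
      g <- genes[gi, ]
      frame <- if (reads$src_strand[i] == g$strand) "+" else "-"
      aa_len <- floor(ov[gi] / 3)
      pct <- round(runif(1, 60, 95), 2)
      ev <- 10^(-runif(1, 20, 80))
      # read-local coordinates of the overlapping stretch
      if (reads$src_strand[i] == "+") {
        qs <- ov_lo[gi] - reads$src_lo[i] + 1L
      } else {
        qs <- reads$src_hi[i] - ov_hi[gi] + 1L
      }
      qe <- qs + ov[gi] - 1L
      n_pep <- if (g$n_peptides >= 2 && runif(1) < 0.4) 2L else 1L
      hits <- lapply(seq_len(n_pep), function(k) {
        tibble(
          query_id = rid,
          subject_id = paste0(g$gene_id, "_P", k),
          pct_identity = pct, aln_length = aa_len,
          mismatches = round((1 - pct / 100) * aa_len), gap_opens = 0,
          q_start = if (frame == "+") qs else qe,
          q_end = if (frame == "+") qe else qs,
          s_start = 1, s_end = aa_len,
          evalue = ev, bit_score = round(aa_len * 1.5, 1),
          strand = frame, hsp_score = pct * aa_len, translated = TRUE
        )
      })
      hits <- bind_rows(hits)
      if (runif(1) < noise[["paralog_rate"]] && nrow(genes) > 1) {
        og <- genes[sample(setdiff(seq_len(nrow(genes)), gi), 1), ]
        decoy <- hits[1, ]
        decoy$subject_id <- paste0(og$gene_id, "_P1")
        decoy$pct_identity <- max(30, pct - 20)
        decoy$evalue <- min(ev * 1e10, 9e-6)
        decoy$hsp_score <- decoy$pct_identity * decoy$aln_length
        hits <- bind_rows(hits, decoy)
      }
      if (runif(1) < noise[["tie_rate"]] && nrow(genes) > 1) {
        og <- genes[sample(setdiff(seq_len(nrow(genes)), gi), 1), ]
        tie <- hits[1, ]
        tie$subject_id <- paste0(og$gene_id, "_P1")
        hits <- bind_rows(hits, tie)
        status[i] <- "tied"
      } else {
        status[i] <- "unique_true"
      }
      out[[i]] <- hits
    }
  }
  hits <- bind_rows(out)
  if (!nrow(hits)) hits <- empty_hits()
  # q coordinates follow the parser's normalised convention; strand column
  # carries orientation. write_blast_tab() re-encodes for round trips.
  qs <- pmin(hits$q_start, hits$q_end)
  qe <- pmax(hits$q_start, hits$q_end)
  hits$q_start <- qs
  hits$q_end <- qe
  list(
    hits = hits,
    per_read = tibble(read_id = reads$read_id, status = status),
    protein_to_gene = p2g,
    gene_loci = if (mode == "protein") registry$gene_loci else NULL
  )
}

straddle_major_piece <- function(blocks, lo, hi) {
  inside <- blocks[blocks$src_end >= lo & blocks$src_start <= hi, , drop = FALSE]
  if (!nrow(inside)) return(NULL)
  p_lo <- pmax(inside$src_start, lo)
  p_hi <- pmin(inside$src_end, hi)
  j <- which.max(p_hi - p_lo)
  list(lo = p_lo[j], hi = p_hi[j], len = p_hi[j] - p_lo[j] + 1L,
       q_off = p_lo[j] - lo)
}

#' Simulate a marker genotyping panel
#'
#' Draws markers into polymorphic / failed / monomorphic classes at the given
#' fractions and genotypes `n_parents` diploid parents. Polymorphic markers
#' carry 2-12 alleles on a dinucleotide size ladder, distributed so every
#' allele is observed; duplicated markers (a configurable subset of the
#' polymorphic ones) give one parent 3-4 alleles. Failed markers yield no
#' product for any parent; monomorphic markers a single homozygous allele.
#'
#' @param seed RNG seed.
#' @param n_markers Number of markers.
#' @param n_parents Number of diploid parents genotyped.
#' @param polymorphic_frac,failed_frac Expected class fractions (the
#'   remainder is monomorphic).
#' @param duplicated_frac Expected overall fraction of duplicated markers.
#' @param allele_range Range of distinct allele counts for polymorphic loci.
#' @return `list(genotypes, truth)` with the genotype table (schema of
#'   [read_genotype_table()]) and the per-marker truth.
#' @export
simulate_genotypes <- function(seed, n_markers = 193L, n_parents = 10L,
                               polymorphic_frac = 0.653, failed_frac = 0.295,
                               duplicated_frac = 15 / 193,
                               allele_range = c(2L, 12L)) {
  stopifnot(polymorphic_frac + failed_frac <= 1, duplicated_frac <= polymorphic_frac)
  set.seed(seed)
  mono_frac <- 1 - polymorphic_frac - failed_frac
  classes <- sample(c("polymorphic", "failed", "monomorphic"), n_markers,
                    replace = TRUE,
                    prob = c(polymorphic_frac, failed_frac, mono_frac))
  dup <- classes == "polymorphic" &
    runif(n_markers) < duplicated_frac / polymorphic_frac
  marker_id <- sprintf("SSR%04d", seq_len(n_markers))
  parent_id <- sprintf("P%02d", seq_len(n_parents))
  rows <- vector("list", n_markers)
  truth_alleles <- integer(n_markers)
  for (i in seq_len(n_markers)) {
    base <- sample(80:380, 1)
    if (classes[i] == "failed") {
      rows[[i]] <- tibble(marker_id = marker_id[i], parent_id = parent_id,
                          alleles = rep(list(integer(0)), n_parents),
                          no_product = TRUE)
      truth_alleles[i] <- 0L
      next
    }
    if (classes[i] == "monomorphic") {
      rows[[i]] <- tibble(marker_id = marker_id[i], parent_id = parent_id,
                          alleles = rep(list(c(base, base)), n_parents),
                          no_product = FALSE)
      truth_alleles[i] <- 1L
      next
    }
    k_min <- if (dup[i]) max(3L, allele_range[1]) else allele_range[1]
    ks <- k_min:allele_range[2]
    k <- sample(ks, 1, prob = 1 / seq_along(ks))
    alleles <- base + 2L * (0:(k - 1L))
    slots <- sample(rep(alleles, length.out = 2L * n_parents))
    geno <- lapply(seq_len(n_parents), function(p) {
      sort(slots[c(2 * p - 1, 2 * p)])
    })
    if (dup[i]) {
      p <- sample.int(n_parents, 1)
      extra_n <- sample(1:2, 1)
      geno[[p]] <- sort(unique(c(geno[[p]],
                                 sample(alleles, extra_n, replace = FALSE))))
      while (length(geno[[p]]) < 3) {
        geno[[p]] <- sort(unique(c(geno[[p]], sample(alleles, 1))))
      }
    }
    rows[[i]] <- tibble(marker_id = marker_id[i], parent_id = parent_id,
                        alleles = geno, no_product = FALSE)
    truth_alleles[i] <- k
  }
  list(
    genotypes = bind_rows(rows),
    truth = tibble(marker_id = marker_id, class = classes, duplicated = dup,
                   n_alleles = truth_alleles)
  )
}

#' Run the full synthetic study
#'
#' Convenience wrapper generating genomes, reads, nucleotide and translated
#' hits, and the genotyping panel from one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `genomes`, `reads`, `clones`, `nuc` and `prot` hit
#'   bundles (see [emulate_blast_hits()]) and `genotyping`.
#' @export
simulate_bes_study <- function(config) {
  genomes <- simulate_genomes(config)
  bes <- simulate_bes(config, genomes)
  nuc <- emulate_blast_hits(config, genomes, bes, "nucleotide")
  prot <- emulate_blast_hits(config, genomes, bes, "protein")
  genotyping <- simulate_genotypes(config$seed + 4L)
  list(genomes = genomes, reads = bes$reads, clones = bes$clones,
       nuc = nuc, prot = prot, genotyping = genotyping)
}
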