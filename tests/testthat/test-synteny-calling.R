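mk_pairing <- function(f = list("chr1", 100000, 100500, "+"),
                       r = list("chr1", 249500, 250000, "-"),
                       clone = "c1") {
  tibble::tibble(
    clone_id = clone,
    n_ends = sum(!is.null(f), !is.null(r)),
    f_chrom = if (is.null(f)) NA_character_ else f[[1]],
    f_lo = if (is.null(f)) NA_real_ else f[[2]],
    f_hi = if (is.null(f)) NA_real_ else f[[3]],
    f_strand = if (is.null(f)) NA_character_ else f[[4]],
    r_chrom = if (is.null(r)) NA_character_ else r[[1]],
    r_lo = if (is.null(r)) NA_real_ else r[[2]],
    r_hi = if (is.null(r)) NA_real_ else r[[3]],
    r_strand = if (is.null(r)) NA_character_ else r[[4]]
  )
}

test_that("span is the inner gap between normalised hit intervals", {
  # bases strictly between [100000,100500] and [249500,250000]
  expect_equal(compute_span(100000, 100500, 249500, 250000), 148999)
  # order of the two ends does not matter
  expect_equal(compute_span(249500, 250000, 100000, 100500), 148999)
  # overlapping hits clamp to zero
  expect_equal(compute_span(100, 500, 300, 700), 0)
  # adjacent hits have no bases between them
  expect_equal(compute_span(1, 500, 501, 1000), 0)
  # nested hits clamp to zero
  expect_equal(compute_span(100, 900, 300, 400), 0)
})

test_that("tail-to-tail requires opposite strands with 3' ends internal", {
  # enumerate strand pairs x left/right order: exactly left=+, right=- passes
  configs <- expand.grid(sf = c("+", "-"), sr = c("+", "-"),
                         f_left = c(TRUE, FALSE), stringsAsFactors = FALSE)
  got <- vapply(seq_len(nrow(configs)), function(i) {
    cfgr <- configs[i, ]
    f <- if (cfgr$f_left) c(1000, 1500) else c(9000, 9500)
    r <- if (cfgr$f_left) c(9000, 9500) else c(1000, 1500)
    tail_to_tail(f[1], f[2], cfgr$sf, r[1], r[2], cfgr$sr)
  }, logical(1))
  want <- (configs$f_left & configs$sf == "+" & configs$sr == "-") |
    (!configs$f_left & configs$sf == "-" & configs$sr == "+")
  expect_equal(got, want)
  expect_equal(sum(got), 2)
})

test_that("synteny classification follows the span window and orientation", {
  # 149 kb apart, tail-to-tail: microsynteny
  p <- mk_pairing()
  call <- call_synteny(p)
  expect_equal(as.character(call$classification), "MICRO")
  expect_equal(call$span_bp, 148999)
  expect_true(call$orientation_ok)
  expect_equal(call$chrom, "chr1")
  expect_equal(call$ref_start, 100000)
  expect_equal(call$ref_end, 250000)

  # 5 kb gap: below the lower span bound
  p2 <- mk_pairing(r = list("chr1", 105501, 106000, "-"))
  expect_equal(as.character(call_synteny(p2)$classification), "MACRO_ONLY")

  # head-to-head orientation fails
  p3 <- mk_pairing(f = list("chr1", 100000, 100500, "-"),
                   r = list("chr1", 249500, 250000, "+"))
  c3 <- call_synteny(p3)
  expect_equal(as.character(c3$classification), "MACRO_ONLY")
  expect_false(c3$orientation_ok)

  # different chromosome: discordant
  p4 <- mk_pairing(r = list("chr2", 249500, 250000, "-"))
  expect_equal(as.character(call_synteny(p4)$classification), "DISCORDANT")
  # scaffold names compare exactly
  p5 <- mk_pairing(r = list("scaffold_221", 249500, 250000, "-"))
  expect_equal(as.character(call_synteny(p5)$classification), "DISCORDANT")

  # one end only
  p6 <- mk_pairing(r = NULL)
  p6$n_ends <- 1L
  expect_equal(as.character(call_synteny(p6)$classification), "SINGLE_END")
})

test_that("span bounds are inclusive at 10 kb and 300 kb", {
  at <- function(gap) {
    mk_pairing(r = list("chr1", 100500 + gap + 1, 100500 + gap + 500, "-"))
  }
  expect_equal(as.character(call_synteny(at(10000))$classification), "MICRO")
  expect_equal(as.character(call_synteny(at(9999))$classification), "MACRO_ONLY")
  expect_equal(as.character(call_synteny(at(300000))$classification), "MICRO")
  expect_equal(as.character(call_synteny(at(300001))$classification), "MACRO_ONLY")
})

test_that("pair_ends joins unique assignments to clones and flags singles", {
  reads <- make_reads(
    c(c1_T7 = "ACGT", c1_SP6 = "ACGT", c2_T7 = "ACGT"),
    clone = c("c1", "c1", "c2"),
    end = c("forward", "reverse", "forward")
  )
  a <- tibble::tibble(
    read_id = c("c1_T7", "c1_SP6", "c2_T7"), mode = "nucleotide",
    status = "unique", subject_id = c("chr1", "chr1", "chr2"),
    gene_id = NA_character_, pct_identity = 99, aln_length = 100,
    q_start = 1, q_end = 100,
    s_start = c(1000, 60099, 500), s_end = c(1099, 60000, 599),
    strand = c("+", "-", "+"), evalue = 1e-50, hsp_score = 9900
  )
  p <- pair_ends(a, reads)
  expect_equal(nrow(p), 2)
  expect_equal(p$n_ends[p$clone_id == "c1"], 2L)
  expect_equal(p$n_ends[p$clone_id == "c2"], 1L)
  expect_equal(p$f_lo[p$clone_id == "c1"], 1000)
  expect_equal(p$r_lo[p$clone_id == "c1"], 60000)
  expect_equal(p$r_strand[p$clone_id == "c1"], "-")

  expect_equal(nrow(pair_ends(a[0, ], reads)), 0)
  dup <- dplyr::bind_rows(a, a[1, ])
  expect_error(pair_ends(dup, reads), "more than one")
})

test_that("protein-mode pairing places hits at gene extents with frame strand", {
  reads <- make_reads(
    c(c1_T7 = "ACGT", c1_SP6 = "ACGT"),
    clone = c("c1", "c1"), end = c("forward", "reverse")
  )
  a <- tibble::tibble(
    read_id = c("c1_T7", "c1_SP6"), mode = "protein", status = "unique",
    subject_id = c("G1_P1", "G2_P1"), gene_id = c("G1", "G2"),
    pct_identity = 80, aln_length = 100, q_start = 1, q_end = 300,
    s_start = 1, s_end = 100, strand = c("+", "-"), evalue = 1e-30,
    hsp_score = 8000
  )
  gene_loci <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = "chr3",
    start = c(50000, 200000), end = c(55000, 207000),
    strand = c("+", "+")
  )
  p <- pair_ends(a, reads, gene_loci = gene_loci)
  expect_equal(p$f_lo, 50000)
  expect_equal(p$f_hi, 55000)
  expect_equal(p$f_strand, "+")   # frame + on a + gene
  expect_equal(p$r_strand, "-")   # frame - on a + gene
  call <- call_synteny(p)
  expect_equal(as.character(call$classification), "MICRO")
  expect_equal(call$span_bp, 200000 - 55000 - 1)
})

test_that("mode intersection is symmetric and counts same-chromosome clones", {
  mk_calls <- function(clones, cls) {
    tibble::tibble(clone_id = clones, species = "sp", mode = NA,
                   classification = factor(cls,
                     levels = c("SINGLE_END", "DISCORDANT", "MACRO_ONLY",
                                "MICRO")),
                   chrom = "chr1", span_bp = 0, orientation_ok = TRUE,
                   ref_start = 1, ref_end = 2)
  }
  a <- mk_calls(c("c1", "c2", "c3"), c("MICRO", "MACRO_ONLY", "DISCORDANT"))
  b <- mk_calls(c("c2", "c3", "c4"), c("MICRO", "MACRO_ONLY", "MICRO"))
  ab <- intersect_modes(a, b)
  expect_equal(ab$n, 1)
  expect_equal(ab$clones, "c2")
  expect_equal(intersect_modes(b, a)$n, ab$n)
  expect_equal(intersect_modes(a, mk_calls("c9", "MICRO"))$n, 0)
  expect_equal(intersect_modes(a, a)$n, 2)
})
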