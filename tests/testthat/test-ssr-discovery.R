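test_that("tandem arrays are reported with period, copies and class", {
  loci <- find_tandem_repeats(c(a = "ACACACACACAC"))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 0L)
  expect_equal(loci$end, 12L)
  expect_equal(loci$period, 2L)
  expect_equal(loci$motif, "AC")
  expect_equal(loci$copies, 6)
  expect_equal(loci$canonical_class, "AC/GT")

  tg <- find_tandem_repeats(c(b = "TGTGTGTGTGTGTGTGTGTG"))
  expect_equal(tg$motif, "TG")
  # TG and CA arrays fall in one reverse-complement class
  expect_equal(tg$canonical_class,
               canonical_class("CA"))

  # a perfect array is not re-reported at its harmonic periods
  expect_equal(nrow(find_tandem_repeats(c(x = strrep("AC", 20)))), 1)
})

test_that("canonical classes merge reverse complements but not rotations", {
  expect_equal(canonical_class("GA"), "GA/TC")
  expect_equal(canonical_class("TC"), "GA/TC")
  expect_equal(canonical_class("AAC"), "AAC/GTT")
  # involution over random motifs
  set.seed(21)
  motifs <- vapply(1:200, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(1:10, 1), TRUE), collapse = "")
  }, character(1))
  expect_equal(canonical_class(rc(motifs)), canonical_class(motifs))
  # rotations stay distinct classes
  expect_false(canonical_class("TG") == canonical_class("AC"))
  expect_error(canonical_class("ANC"), "A, C, G, T")
  expect_error(canonical_class("ACGTACGTACG"), "1-10")
})

test_that("detector equals the exhaustive enumerator on short strings", {
  set.seed(22)
  n_fail <- 0
  for (trial in 1:40) {
    n <- sample(200:600, 1)
    s <- random_seq(n, gc = 0.5)
    # implant a couple of short-period arrays to keep the comparison busy
    for (k in 1:2) {
      p <- sample(1:3, 1)
      motif <- paste(sample(c("A", "C", "G", "T"), p, TRUE), collapse = "")
      reps <- strrep(motif, sample(5:12, 1))
      pos <- sample(n - nchar(reps), 1)
      substr(s, pos, pos + nchar(reps) - 1) <- reps
    }
    got <- find_tandem_repeats(c(x = s), max_period = 3,
                               max_mismatch_frac = 0)
    want <- brute_force_ssrs(s, max_period = 3)
    same <- nrow(got) == nrow(want) &&
      all(got$start == want$start) && all(got$end == want$end) &&
      all(got$period == want$period)
    if (!same) n_fail <- n_fail + 1
  }
  expect_equal(n_fail, 0)
})

test_that("length and copy-number thresholds bound every reported locus", {
  expect_equal(nrow(find_tandem_repeats(c(a = strrep("A", 11)))), 0)
  a12 <- find_tandem_repeats(c(a = strrep("A", 12)))
  expect_equal(nrow(a12), 1)
  expect_equal(a12$period, 1L)
  # period 5, 2.4 copies = 12 bp: below the 3-copy floor for period >= 3
  expect_equal(nrow(find_tandem_repeats(c(p = "TCAAATCAAATC"))), 0)
  # 3 full copies pass
  p5 <- find_tandem_repeats(c(p = strrep("TCAAA", 3)))
  expect_equal(p5$period, 5L)
  expect_equal(p5$copies, 3)

  set.seed(23)
  reads <- make_reads(setNames(replicate(20, random_seq(400)), paste0("r", 1:20)))
  loci <- find_tandem_repeats(reads)
  if (nrow(loci)) {
    expect_true(all(loci$end - loci$start >= 2 * loci$period))
    expect_true(all(loci$purity >= 0.8))
    expect_true(all(nchar(loci$motif) == loci$period))
  }
})

test_that("flank eligibility is mask- and SSR-aware on both sides", {
  reads <- make_reads(c(r = random_seq(200)))
  loci <- tibble::tibble(read_id = "r", start = 60L, end = 80L, period = 2L,
                         motif = "AC", copies = 10, purity = 1,
                         canonical_class = "AC/GT")
  fe <- flank_eligible(reads, loci)
  expect_true(fe$eligible)
  expect_equal(fe$left_clean, 60L)
  expect_equal(fe$right_clean, 120L)

  # left flank of 30 bp is short
  loci2 <- dplyr::mutate(loci, start = 30L, end = 50L)
  expect_false(flank_eligible(reads, loci2)$eligible)

  # 55 bp left flank with 10 bp masked leaves 45 clean: not eligible
  reads3 <- make_reads(c(r = random_seq(200)))
  reads3$mask[[1]] <- bescan:::as_mask(10L, 20L)
  loci3 <- dplyr::mutate(loci, start = 55L, end = 75L)
  fe3 <- flank_eligible(reads3, loci3)
  expect_equal(fe3$left_clean, 45L)
  expect_false(fe3$eligible)

  # a second SSR in the flank is excluded from clean bases
  loci4 <- dplyr::bind_rows(
    loci,
    dplyr::mutate(loci, start = 10L, end = 30L)
  )
  fe4 <- flank_eligible(make_reads(c(r = random_seq(200))), loci4)
  expect_equal(fe4$left_clean[1], 40L)
  expect_false(fe4$eligible[1])

  expect_error(
    flank_eligible(reads, dplyr::mutate(loci, end = 300L)),
    "outside read bounds"
  )
})

test_that("SSR report groups by period and class and rolls small classes", {
  loci <- dplyr::bind_rows(
    tibble::tibble(read_id = paste0("r", 1:6), start = 0L, end = 12L,
                   period = 2L, motif = c(rep("AC", 4), rep("GT", 2)),
                   copies = 6, purity = 1),
    tibble::tibble(read_id = paste0("s", 1:4), start = 0L, end = 12L,
                   period = 2L, motif = "GA", copies = 6, purity = 1)
  )
  loci$canonical_class <- canonical_class(loci$motif)
  rep <- summarize_ssrs(loci, other_threshold = 1)
  t <- tidy(rep)
  expect_equal(sum(t$n), 10)
  expect_equal(t$n[t$class_label == "AC/GT"], 6)
  expect_equal(t$n[t$class_label == "GA/TC"], 4)
  expect_equal(glance(rep)$total_loci, 10)

  # display label puts the majority-observed variant first
  loci_tg <- tibble::tibble(read_id = paste0("t", 1:5), start = 0L, end = 12L,
                            period = 2L, motif = c(rep("TG", 4), "CA"),
                            copies = 6, purity = 1,
                            canonical_class = canonical_class("TG"))
  t_tg <- tidy(summarize_ssrs(loci_tg, other_threshold = 1))
  expect_equal(t_tg$class_label, "TG/CA")

  # small classes roll into Other within their period group
  rolled <- tidy(summarize_ssrs(loci, other_threshold = 5))
  expect_true("Other" %in% rolled$class_label)
  expect_equal(sum(rolled$n), 10)

  empty <- summarize_ssrs(loci[0, ])
  expect_equal(glance(empty)$total_loci, 0)
})

test_that("reported class fractions match the sampling distribution", {
  set.seed(24)
  probs <- c(TG = 0.4, GA = 0.3, AAT = 0.2, CACA = 0.1)
  n <- 600
  motifs <- sample(names(probs), n, replace = TRUE, prob = probs)
  loci <- tibble::tibble(
    read_id = paste0("r", seq_len(n)), start = 0L,
    end = 4L * nchar(motifs), period = nchar(motifs), motif = motifs,
    copies = 4, purity = 1, canonical_class = canonical_class(motifs)
  )
  t <- tidy(summarize_ssrs(loci, other_threshold = 1))
  for (m in names(probs)) {
    lab <- t$class_label[startsWith(t$class_label, paste0(m, "/"))]
    obs <- t$n[t$class_label == lab] / n
    se <- sqrt(probs[[m]] * (1 - probs[[m]]) / n)
    expect_lt(abs(obs - probs[[m]]), 2.5 * se + 1e-9)
  }
})

test_that("implanted perfect SSR loci are recovered with exact boundaries", {
  cfg <- sim_config(seed = 25, genome_len = 3e5, n_clones = 10,
                    insert_range = c(2e4, 4e4), repeat_target_fraction = 0.3,
                    ssr_rate = 0.25, n_genes = 20)
  sim <- simulate_genomes(cfg)
  truth <- sim$registry$ssrs
  expect_gt(nrow(truth), 30)
  found <- find_tandem_repeats(c(g = sim$source))
  key_found <- paste(found$start, found$end)
  key_truth <- paste(truth$start, truth$end)
  hit <- key_truth %in% key_found
  expect_gte(mean(hit), 0.99)
})
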