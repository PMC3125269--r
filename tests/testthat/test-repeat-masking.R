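test_that("library masking finds exact, diverged and reverse-complement copies", {
  set.seed(101)
  cons <- random_seq(300)
  lib <- tibble::tibble(name = "rep1", repeat_class = "DNA/Tc1",
                        consensus = cons)
  left <- random_seq(200)
  reads <- make_reads(c(
    exact = paste0(left, cons),
    revc = paste0(left, rc(cons)),
    none = random_seq(500)
  ))
  m <- mask_with_library(reads, lib)
  expect_equal(unname(m$mask[[1]][1, ]), c(200L, 500L))
  expect_equal(unname(m$mask[[2]][1, ]), c(200L, 500L))
  expect_equal(nrow(m$mask[[3]]), 0)

  # 85% identity copy still masked at min_identity = 0.80
  diverged <- bescan:::mutate_dna(cons, 0.15)
  reads2 <- make_reads(c(div = paste0(left, diverged)))
  m2 <- mask_with_library(reads2, lib, mask_params(min_identity = 0.80))
  expect_gte(bescan:::interval_total(m2$mask[[1]]), 0.9 * 300)
  # and the masked interval stays inside the implanted copy region
  expect_true(all(m2$mask[[1]][, 1] >= 150))
})

test_that("masking agrees with an independent pairwise aligner on identity", {
  skip_if_not_installed("Biostrings")
  set.seed(102)
  cons <- random_seq(200)
  read_seq <- random_seq(400)   # unrelated: chance-level identity only
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read_seq), Biostrings::DNAString(cons),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 10, gapExtension = 10
  )
  # best chance alignment is weak, so the masker must not mask anything
  expect_lt(Biostrings::nchar(Biostrings::pattern(aln)), 30)
  m <- mask_with_library(make_reads(c(r = read_seq)),
                         tibble::tibble(name = "x", repeat_class = "U",
                                        consensus = cons),
                         mask_params(min_identity = 0.9))
  expect_equal(nrow(m$mask[[1]]), 0)
})

test_that("masking is idempotent and monotone in min_identity", {
  set.seed(103)
  lib <- tibble::tibble(
    name = c("a", "b"), repeat_class = "U",
    consensus = c(random_seq(250), random_seq(400))
  )
  reads <- make_reads(c(
    r1 = paste0(random_seq(120), bescan:::mutate_dna(lib$consensus[1], 0.1),
                random_seq(80)),
    r2 = paste0(bescan:::mutate_dna(lib$consensus[2], 0.05), random_seq(150))
  ))
  once <- mask_with_library(reads, lib)
  twice <- mask_with_library(once, lib)
  expect_equal(once$mask, twice$mask)

  loose <- mask_with_library(reads, lib, mask_params(min_identity = 0.7))
  strict <- mask_with_library(reads, lib, mask_params(min_identity = 0.95))
  expect_gte(masked_fraction(loose), masked_fraction(strict))

  # masks are sorted, merged, in-bounds
  for (mk in once$mask) {
    if (nrow(mk) > 1) expect_true(all(diff(mk[, 1]) > 0))
    expect_true(all(mk[, 1] >= 0))
  }
  expect_true(all(once$mask[[1]][, 2] <= nchar(reads$bases[1])))
})

test_that("masked_fraction is plain base-pair arithmetic", {
  reads <- make_reads(c(a = random_seq(100), b = random_seq(100)))
  expect_equal(masked_fraction(reads), 0)
  reads$mask[[1]] <- bescan:::as_mask(0L, 100L)
  reads$mask[[2]] <- bescan:::as_mask(0L, 19L)
  expect_equal(masked_fraction(reads), 59.5)
  reads$mask[[2]] <- bescan:::as_mask(0L, 100L)
  expect_equal(masked_fraction(reads), 100)
  expect_error(masked_fraction(reads[0, ]), "no reads")
})

test_that("cross-library masking: identity, disjointness and containment", {
  set.seed(104)
  lib_a <- tibble::tibble(name = paste0("a", 1:3), repeat_class = "U",
                          consensus = replicate(3, random_seq(300)))
  lib_b <- tibble::tibble(name = paste0("b", 1:3), repeat_class = "U",
                          consensus = replicate(3, random_seq(300)))
  expect_gte(cross_mask_fraction(lib_a, lib_a), 99)
  expect_lte(cross_mask_fraction(lib_a, lib_b,
                                 mask_params(min_identity = 0.8,
                                             min_hit_len = 50)), 2)
  sub <- lib_b[1:2, ]
  expect_equal(cross_mask_fraction(sub, lib_b), 100)
})

test_that("contaminant screening removes only well-covered, high-identity reads", {
  set.seed(105)
  vector_seq <- random_seq(3000)
  contam <- tibble::tibble(name = "vec", repeat_class = "vector",
                           consensus = vector_seq)
  reads <- make_reads(c(
    vec = substr(vector_seq, 101, 600),          # exact substring
    clean = random_seq(500),                      # no shared seed expected
    partial = paste0(substr(vector_seq, 1, 100), random_seq(400))
  ))
  sc <- screen_contaminants(reads, contam, min_identity = 0.9, min_cov = 0.5)
  expect_equal(sc$removed$read_id, "vec")
  expect_setequal(sc$kept$read_id, c("clean", "partial"))
  expect_equal(nrow(sc$kept) + nrow(sc$removed), nrow(reads))
  empty <- screen_contaminants(reads[0, ], contam)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("longest unmasked run decides eligibility with a strict bound", {
  reads <- make_reads(c(a = random_seq(550), b = random_seq(300),
                        c = random_seq(300)))
  # a: unmasked 550 -> eligible, run = whole read
  # b: longest unmasked run exactly 100 -> not eligible
  reads$mask[[2]] <- bescan:::as_mask(c(0L, 200L), c(100L, 300L))
  # c: longest run 101 -> eligible
  reads$mask[[3]] <- bescan:::as_mask(c(0L, 200L), c(99L, 300L))
  e <- nonrepetitive_eligible(reads, min_run = 100)
  expect_equal(e$eligible, c(TRUE, FALSE, TRUE))
  expect_equal(e$run_length, c(550L, 100L, 101L))
  expect_equal(e$run_start[1], 0L)
  expect_equal(e$run_end[1], 550L)
})

test_that("self-hit census counts other reads and bins by the 10/50 thresholds", {
  set.seed(106)
  shared <- random_seq(150)
  reads <- make_reads(c(x1 = shared, x2 = shared, x3 = shared,
                        lone = random_seq(150)))
  cen <- self_hit_census(reads)
  expect_equal(cen$hit_count[1:3], rep(2L, 3))
  expect_equal(cen$hit_count[4], 0L)
  expect_equal(as.character(cen$census_class), rep("LOW", 4))

  # a family of 30 mutated copies -> each member counts ~29 others: MODERATE
  fam <- vapply(1:30, function(i) bescan:::mutate_dna(shared, 0.05),
                character(1))
  fam_reads <- make_reads(setNames(fam, paste0("f", 1:30)))
  cen_fam <- self_hit_census(fam_reads)
  expect_true(all(cen_fam$hit_count >= 25))
  expect_true(all(cen_fam$census_class == "MODERATE"))

  # one read matching 60 distinct others -> HIGH
  big <- make_reads(setNames(c(list(shared), as.list(
    vapply(1:60, function(i) paste0(random_seq(40), shared, random_seq(40)),
           character(1))
  )), c("hub", paste0("o", 1:60))))
  cen_big <- self_hit_census(big)
  expect_equal(as.character(cen_big$census_class[1]), "HIGH")

  # boundary counts fall in the lower bin
  expect_equal(as.character(census_class(c(9, 10, 11, 50, 51))),
               c("LOW", "LOW", "MODERATE", "MODERATE", "HIGH"))

  # masked sequence does not participate
  masked <- make_reads(c(m1 = shared, m2 = shared))
  masked$mask <- list(bescan:::as_mask(0L, 150L), bescan:::as_mask(0L, 150L))
  cen_m <- self_hit_census(masked)
  expect_equal(cen_m$hit_count, c(0L, 0L))
})

test_that("masker recovers implanted repeat bases with few false positives", {
  set.seed(107)
  lib <- tibble::tibble(
    name = paste0("fam", 1:3), repeat_class = "U",
    consensus = c(random_seq(400), random_seq(250), random_seq(600))
  )
  n_reads <- 40
  reads <- list()
  implanted <- list()
  for (i in seq_len(n_reads)) {
    bg_left <- sample(50:250, 1)
    bg_right <- sample(50:250, 1)
    fam <- sample(3, 1)
    copy <- bescan:::mutate_dna(lib$consensus[fam], 0.12)  # within 1 - 0.80
    if (runif(1) < 0.5) copy <- rc(copy)
    reads[[i]] <- paste0(random_seq(bg_left), copy, random_seq(bg_right))
    implanted[[i]] <- c(bg_left, bg_left + nchar(copy))
  }
  rt <- make_reads(setNames(unlist(reads), paste0("r", seq_len(n_reads))))
  m <- mask_with_library(rt, lib, mask_params(min_identity = 0.80))
  rec <- vapply(seq_len(n_reads), function(i) {
    iv <- implanted[[i]]
    bescan:::overlap_with_intervals(iv[1], iv[2], m$mask[[i]]) / (iv[2] - iv[1])
  }, numeric(1))
  fp <- vapply(seq_len(n_reads), function(i) {
    iv <- implanted[[i]]
    len <- nchar(rt$bases[i])
    bg <- len - (iv[2] - iv[1])
    (bescan:::interval_total(m$mask[[i]]) -
       bescan:::overlap_with_intervals(iv[1], iv[2], m$mask[[i]])) / bg
  }, numeric(1))
  expect_gte(mean(rec), 0.95)                # >= 95% of implanted bases
  expect_lte(mean(fp), 0.02)                 # <= 2% of background bases
})
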