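small_cfg <- function(seed = 61, rearrangement_rate = 4, ...) {
  sim_config(seed = seed, genome_len = 8e5, n_clones = 150,
             insert_range = c(4e4, 8e4), repeat_target_fraction = 0.35,
             n_genes = 60, rearrangement_rate = rearrangement_rate, ...)
}

test_that("every generator is byte-identical under the same seed", {
  cfg <- small_cfg()
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$source, s2$source)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$registry$repeats, s2$registry$repeats)

  b1 <- simulate_bes(cfg, s1)
  b2 <- simulate_bes(cfg, s2)
  expect_identical(b1$reads$bases, b2$reads$bases)
  expect_identical(b1$clones, b2$clones)

  h1 <- emulate_blast_hits(cfg, s1, b1, "nucleotide")
  h2 <- emulate_blast_hits(cfg, s2, b2, "nucleotide")
  expect_identical(h1$hits, h2$hits)

  g1 <- simulate_genotypes(seed = 9)
  g2 <- simulate_genotypes(seed = 9)
  expect_identical(g1$genotypes, g2$genotypes)
})

test_that("zero rearrangement rate leaves the reference collinear", {
  cfg <- small_cfg(seed = 62, rearrangement_rate = 0)
  sim <- simulate_genomes(cfg)
  expect_equal(nrow(sim$registry$blocks), 1)
  joined <- paste(sim$reference$seq, collapse = "")
  expect_true(identical(joined, sim$source) ||
                identical(joined, revcomp_dna(sim$source)))
})

test_that("implanted repeat coverage lands within 1% of the target fraction", {
  cfg <- sim_config(seed = 63, genome_len = 2e6, n_clones = 10,
                    insert_range = c(4e4, 8e4),
                    repeat_target_fraction = 0.6, n_genes = 0)
  sim <- simulate_genomes(cfg)
  frac <- sum(sim$registry$repeats$end - sim$registry$repeats$start) /
    nchar(sim$source)
  expect_lt(abs(frac - 0.6), 0.01)

  cfg0 <- sim_config(seed = 63, genome_len = 5e5, n_clones = 10,
                     insert_range = c(4e4, 8e4),
                     repeat_target_fraction = 0, n_genes = 0)
  expect_equal(nrow(simulate_genomes(cfg0)$registry$repeats), 0)
  expect_error(sim_config(seed = 1, repeat_target_fraction = 0.99), "0.95")
})

test_that("paired reads face inward from the insert boundaries", {
  cfg <- small_cfg(seed = 64)
  sim <- simulate_genomes(cfg)
  bes <- simulate_bes(cfg, sim)
  both <- bes$clones[bes$clones$has_forward & bes$clones$has_reverse, ]
  expect_gt(nrow(both), 0)
  # forward read = top strand at the left boundary
  r <- bes$reads
  f <- r[r$end == "forward", ]
  expect_true(all(f$src_strand == "+"))
  expect_true(all(substring(sim$source, f$src_lo, f$src_lo + 19) ==
                    substring(f$bases, 1, 20)))
  # reverse read = bottom strand at the right boundary
  rv <- r[r$end == "reverse", ]
  expect_true(all(rv$src_strand == "-"))
  i <- which(r$read_id == rv$read_id[1])
  expect_equal(
    r$bases[i],
    revcomp_dna(substr(sim$source, r$src_lo[i], r$src_hi[i]))
  )
  # intact same-block clones are tail-to-tail by construction
  intact <- both[both$intact, ]
  expect_true(all(intact$expected_t2t))
})

test_that("read lengths match the configured mean and range", {
  cfg <- sim_config(seed = 65, genome_len = 1e6, n_clones = 2000,
                    insert_range = c(5e4, 9e4), repeat_target_fraction = 0,
                    ssr_rate = 0, n_genes = 0)
  sim <- simulate_genomes(cfg)
  bes <- simulate_bes(cfg, sim)
  lens <- nchar(bes$reads$bases)
  expect_gte(min(lens), 101)
  expect_lte(max(lens), 832)
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 546), 2.5 * se)
  # qualities: high plateau, degraded tails; Q20 length below raw length
  q20 <- q20_length(bes$reads)
  expect_true(all(q20 < lens))
  expect_gt(mean(q20 / lens), 0.85)
})

test_that("forced ties leave no unique assignments", {
  cfg <- small_cfg(seed = 66,
                   hit_noise = c(miss_rate = 0, paralog_rate = 0,
                                 tie_rate = 1))
  sim <- simulate_genomes(cfg)
  bes <- simulate_bes(cfg, sim)
  em <- emulate_blast_hits(cfg, sim, bes, "nucleotide")
  a <- assign_unique(em$hits, "nucleotide")
  tied_reads <- em$per_read$read_id[em$per_read$status == "tied"]
  expect_gt(length(tied_reads), 0)
  expect_true(all(a$status[a$read_id %in% tied_reads] == "ambiguous"))
})

test_that("paralog decoys are removed by filtration, misses drop the read", {
  cfg <- small_cfg(seed = 67,
                   hit_noise = c(miss_rate = 0.3, paralog_rate = 1,
                                 tie_rate = 0))
  sim <- simulate_genomes(cfg)
  bes <- simulate_bes(cfg, sim)
  em <- emulate_blast_hits(cfg, sim, bes, "nucleotide")
  a <- assign_unique(em$hits, "nucleotide", reads = bes$reads)
  ok <- em$per_read$read_id[em$per_read$status == "unique_true"]
  expect_true(all(a$status[a$read_id %in% ok] == "unique"))
  missed <- em$per_read$read_id[em$per_read$status == "missing"]
  expect_gt(length(missed), 0)
  expect_true(all(a$status[a$read_id %in% missed] == "no_hit"))
})

test_that("emulated hits survive a tabular round trip", {
  cfg <- small_cfg(seed = 68)
  sim <- simulate_genomes(cfg)
  bes <- simulate_bes(cfg, sim)
  for (mode in c("nucleotide", "protein")) {
    em <- emulate_blast_hits(cfg, sim, bes, mode)
    f <- withr::local_tempfile(fileext = ".tab")
    write_blast_tab(em$hits, f)
    back <- parse_blast_tab(f)
    expect_equal(nrow(back), nrow(em$hits))
    expect_equal(back$strand, em$hits$strand)
    expect_equal(back$q_start, em$hits$q_start)
    expect_equal(back$subject_id, em$hits$subject_id)
    expect_equal(back$hsp_score, em$hits$hsp_score, tolerance = 1e-6)
  }
})

test_that("registry truth predicts the pipeline on noiseless data", {
  cfg <- sim_config(seed = 69, genome_len = 1.5e6, n_clones = 250,
                    insert_range = c(4e4, 9e4), repeat_target_fraction = 0.35,
                    n_genes = 60, rearrangement_rate = 4,
                    hit_noise = c(miss_rate = 0, paralog_rate = 0,
                                  tie_rate = 0))
  sim <- simulate_genomes(cfg)
  bes <- simulate_bes(cfg, sim)
  em <- emulate_blast_hits(cfg, sim, bes, "nucleotide")
  res <- bes_pipeline(bes$reads, sim$library, hits_nuc = em$hits)
  calls <- res$nucleotide$calls

  status <- merge(em$per_read,
                  as.data.frame(res$reads[, c("read_id", "eligible")]))
  status <- merge(status,
                  as.data.frame(bes$reads[, c("read_id", "clone_id")]))
  ok_reads <- status$status == "unique_true" & status$eligible
  per_clone <- tapply(ok_reads, status$clone_id, sum)
  truth <- bes$clones

  # every intact conserved clone with both ends usable and an in-window gap
  # is called MICRO
  denom <- truth$clone_id[
    truth$intact & truth$has_forward & truth$has_reverse &
      truth$expected_gap >= 1e4 & truth$expected_gap <= 3e5 &
      per_clone[truth$clone_id] == 2
  ]
  micro <- calls$clone_id[calls$classification == "MICRO"]
  expect_gt(length(denom), 20)
  expect_true(all(denom %in% micro))

  # every breakpoint-straddling clone with both ends usable is discordant
  bp <- truth$clone_id[
    truth$expected_class == "DISCORDANT" & per_clone[truth$clone_id] == 2
  ]
  disc <- calls$clone_id[calls$classification == "DISCORDANT"]
  expect_gt(length(bp), 5)
  expect_true(all(bp %in% disc))
})
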