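test_that("bin classification follows the threshold bands", {
  cfg <- classifier_config()
  expect_equal(as.character(classify_bin(c(1, 0.85, 0, -0.2, -1, 0.5, -0.5, NA),
                                         cfg)),
               c("maternal", "maternal", "biparental", "biparental",
                 "paternal", "ambiguous", "ambiguous", NA))
  # Boundary values belong to their bands.
  expect_equal(as.character(classify_bin(c(0.8, -0.8, 0.3, -0.3), cfg)),
               c("maternal", "paternal", "biparental", "biparental"))
})

test_that("classifier config invariants are enforced", {
  expect_error(classifier_config(tau_maternal = 0.2))
  expect_error(classifier_config(tau_biparental_abs = 0))
  expect_error(classifier_config(chrom_consensus_fraction = 0.5))
  expect_error(classifier_config(min_defined_bins_per_chrom = 0))
})

test_that("chromosome calls need enough bins and a consensus", {
  cfg <- classifier_config()
  expect_equal(classify_chromosome(rep("maternal", 30), cfg)$call, "maternal")
  # 24/30 = 0.8 biparental with scattered ambiguous bins still reaches
  # consensus.
  cls <- rep("biparental", 30)
  cls[c(3, 8, 14, 19, 24, 29)] <- "ambiguous"
  r <- classify_chromosome(cls, cfg)
  expect_equal(r$call, "biparental")
  expect_equal(r$support, 0.8)
  # Too few defined bins -> indeterminate, NA bins do not count.
  expect_equal(classify_chromosome(c(rep(NA, 20), rep("maternal", 4)),
                                   cfg)$call, "indeterminate")
})

test_that("contiguous maternal and biparental runs give mixed_segmental", {
  cfg <- classifier_config()
  seg <- classify_chromosome(c(rep("maternal", 15), rep("biparental", 15)),
                             cfg)
  expect_equal(seg$call, "mixed_segmental")
  expect_equal(seg$support, 1)
  # Alternating single bins never form the >= 2-bin runs.
  alt <- classify_chromosome(rep(c("maternal", "biparental"), 8), cfg)
  expect_equal(alt$call, "indeterminate")
})

test_that("consensus calls are invariant to bin order", {
  cfg <- classifier_config()
  cls <- c(rep("biparental", 26), rep("ambiguous", 3), NA)
  set.seed(33)
  for (i in 1:10) {
    expect_equal(classify_chromosome(sample(cls), cfg)$call, "biparental")
  }
})

test_that("genome rules combine chromosome calls as designed", {
  chroms <- paste0("Chr", 1:10)
  cfg <- classifier_config()
  all_mat <- stats::setNames(rep("maternal", 10), chroms)
  expect_equal(classify_genome(all_mat, cfg)$genome_call, "maternal_haploid")
  all_bip <- stats::setNames(rep("biparental", 10), chroms)
  expect_equal(classify_genome(all_bip, cfg)$genome_call, "biparental_diploid")
  # The abortive-embryo signature: biparental genome lacking paternal Chr2.
  loss <- all_bip
  loss["Chr2"] <- "maternal"
  r <- classify_genome(loss, cfg)
  expect_equal(r$genome_call, "biparental_missing_paternal_chroms")
  expect_equal(r$lost_chroms, "Chr2")
  seg <- all_bip
  seg["Chr5"] <- "mixed_segmental"
  expect_equal(classify_genome(seg, cfg)$genome_call,
               "segmental_paternal_loss")
  all_pat <- stats::setNames(rep("paternal", 10), chroms)
  expect_warning(r_pat <- classify_genome(all_pat, cfg), "sample swap")
  expect_equal(r_pat$genome_call, "indeterminate")
})

test_that("noise-free simulations of all four scenarios classify exactly", {
  cm <- small_map()
  m <- simulate_parents(cm, 5e-4, seed = 2)
  hi <- sequencing_model(1000, 0)
  expect_equal(simulate_and_classify(
    m, scenario_spec("maternal_haploid"), hi, 41)$genome_call,
    "maternal_haploid")
  expect_equal(simulate_and_classify(
    m, scenario_spec("biparental_diploid"), hi, 42)$genome_call,
    "biparental_diploid")
  loss <- simulate_and_classify(
    m, scenario_spec("paternal_chrom_loss", lost_chroms = "Chr2"), hi, 43)
  expect_equal(loss$genome_call, "biparental_missing_paternal_chroms")
  expect_equal(loss$lost_chroms, "Chr2")
  iv <- data.frame(chrom = "Chr1", start = 1, end = 5e5)
  expect_equal(simulate_and_classify(
    m, scenario_spec("segmental_paternal_loss", lost_intervals = iv),
    hi, 44)$genome_call, "segmental_paternal_loss")
})

test_that("JSON origin reports round-trip the call", {
  m <- simulate_parents(small_map(), 5e-4, seed = 2)
  call <- simulate_and_classify(m, scenario_spec("maternal_haploid"),
                                sequencing_model(1000, 0), 7)
  parsed <- jsonlite::fromJSON(origin_report(call))
  expect_equal(parsed$genome_call, "maternal_haploid")
  expect_equal(parsed$chromosomes$call, c("maternal", "maternal"))
  expect_equal(parsed$config$tau_maternal, 0.8)
})
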