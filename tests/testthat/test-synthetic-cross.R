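test_that("marker placement follows the Poisson density and stays informative", {
  m <- simulate_parents(chrom_map("Chr1", 1e6), snp_density = 1e-3, seed = 7)
  # Expected 1000 sites; Poisson count should fall within 3*sqrt(1000).
  expect_lt(abs(nrow(m) - 1000), 3 * sqrt(1000))
  expect_true(all(diff(m$pos) > 0))
  expect_true(all(m$maternal_allele != m$paternal_allele))
  expect_true(all(m$maternal_allele %in% c("A", "C", "G", "T")))
  expect_true(all(m$qual > 20))
})

test_that("simulate_parents is deterministic and handles sparse chromosomes", {
  cm <- small_map()
  expect_identical(simulate_parents(cm, 1e-4, seed = 3),
                   simulate_parents(cm, 1e-4, seed = 3))
  # Density low enough that some chromosome draws zero sites: no error.
  sparse <- simulate_parents(chrom_map(c("A", "B"), c(100, 100)),
                             snp_density = 1e-6, seed = 1)
  expect_equal(nrow(sparse), 0L)
  expect_error(simulate_parents(data.frame(), 1e-3, seed = 1))
})

test_that("noise-free high-depth offspring recover the scenario truth exactly", {
  m <- simulate_parents(small_map(), 5e-4, seed = 2)
  hi <- sequencing_model(mean_depth = 1000, base_error = 0)
  hap <- simulate_offspring(m, scenario_spec("maternal_haploid"), hi, seed = 4)
  expect_true(all(hap$call == "hom_maternal"))
  dip <- simulate_offspring(m, scenario_spec("biparental_diploid"), hi, seed = 4)
  expect_true(all(dip$call == "het"))
  loss <- simulate_offspring(
    m, scenario_spec("paternal_chrom_loss", lost_chroms = "Chr2"), hi, seed = 4)
  expect_true(all(loss$call[loss$chrom == "Chr2"] == "hom_maternal"))
  expect_true(all(loss$call[loss$chrom == "Chr1"] == "het"))
})

test_that("segmental loss applies only inside the stated interval", {
  m <- simulate_parents(small_map(), 5e-4, seed = 2)
  hi <- sequencing_model(mean_depth = 1000, base_error = 0)
  iv <- data.frame(chrom = "Chr1", start = 200001, end = 600000)
  seg <- simulate_offspring(
    m, scenario_spec("segmental_paternal_loss", lost_intervals = iv),
    hi, seed = 9)
  inside <- seg$chrom == "Chr1" & seg$pos >= 200001 & seg$pos <= 600000
  expect_true(all(seg$call[inside] == "hom_maternal"))
  expect_true(all(seg$call[!inside] == "het"))
})

test_that("scenarios referencing unknown chromosomes are rejected", {
  m <- simulate_parents(small_map(), 5e-4, seed = 2)
  expect_error(
    simulate_offspring(m, scenario_spec("paternal_chrom_loss",
                                        lost_chroms = "Chr9"),
                       sequencing_model(), seed = 1),
    "absent")
  expect_error(scenario_spec("maternal_haploid", lost_chroms = "Chr1"))
  expect_error(scenario_spec("paternal_chrom_loss"))
  expect_error(scenario_spec("segmental_paternal_loss"))
})

test_that("allele dropout at low depth matches the Poisson closed form", {
  m <- simulate_parents(chrom_map("Chr1", 1e7), 1e-3, seed = 21)
  g <- simulate_offspring(m, scenario_spec("biparental_diploid"),
                          sequencing_model(mean_depth = 5, base_error = 0),
                          seed = 22)
  called <- g$call[g$call != "missing"]
  hom_frac <- mean(called %in% c("hom_maternal", "hom_paternal"))
  p <- expected_hom_fraction(5)
  mc_sigma <- sqrt(p * (1 - p) / length(called))
  expect_lt(abs(hom_frac - p), 3 * mc_sigma)
  # Dropout is symmetric between the two homozygous classes.
  expect_lt(abs(mean(called == "hom_maternal") -
                  mean(called == "hom_paternal")), 3 * mc_sigma)
})

test_that("seed lots conserve totals and respect degenerate rates", {
  for (s in 1:20) {
    spec <- seed_lot_spec(n_seeds = 163, true_hir = 0.2, abortion_rate = 0.2,
                          marker_false_negative = 0.05,
                          marker_false_positive = 0.02, seed = s)
    lot <- simulate_seed_lot(spec)
    expect_identical(lot$germinated_diploid + lot$germinated_haploid +
                       lot$ungerminated_aborted, 163L)
    expect_true(all(c(lot$germinated_diploid, lot$germinated_haploid,
                      lot$ungerminated_aborted) >= 0L))
  }
  none <- simulate_seed_lot(seed_lot_spec(500, true_hir = 0, seed = 1))
  expect_identical(none$germinated_haploid, 0L)
  expect_identical(simulate_seed_lot(seed_lot_spec(100, 0.3, seed = 5)),
                   simulate_seed_lot(seed_lot_spec(100, 0.3, seed = 5)))
})

test_that("seed-lot haploid counts are binomial around the true rate", {
  est <- vapply(1:500, function(s) {
    lot <- simulate_seed_lot(seed_lot_spec(10000, true_hir = 0.2, seed = s))
    lot$germinated_haploid / lot$total_germinated
  }, 0)
  se_mean <- sqrt(0.2 * 0.8 / 10000) / sqrt(500)
  expect_lt(abs(mean(est) - 0.2), 3 * se_mean)
})
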