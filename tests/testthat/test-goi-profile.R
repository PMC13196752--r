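test_that("make_bins tiles chromosomes with half-open truncated bins", {
  b <- make_bins(chrom_map("Chr1", 250000))
  expect_equal(b$start, c(0, 100000, 200000))
  expect_equal(b$end, c(100000, 200000, 250000))
  expect_equal(make_bins(chrom_map("c", 100000))$end, 100000)
  b99 <- make_bins(chrom_map("c", 99))
  expect_equal(nrow(b99), 1L)
  expect_equal(b99$end, 99)
  # Tiling covers every chromosome exactly once with contiguous bins.
  cm <- small_map()
  bb <- make_bins(cm, 30000)
  for (ch in cm$chrom) {
    sub <- bb[bb$chrom == ch, ]
    expect_equal(sub$start[1], 0)
    expect_equal(sub$end[nrow(sub)], cm$length[cm$chrom == ch])
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])
  }
})

test_that("compute_bin_goi evaluates the origin-index formula with the NA rule", {
  expect_equal(compute_bin_goi(10, 0, 0), 1.0)
  expect_equal(compute_bin_goi(2, 2, 6), 0.0)
  expect_equal(compute_bin_goi(6, 2, 2), 0.4)
  expect_true(is.na(compute_bin_goi(2, 1, 1)))   # total 4 -> ignored
  expect_equal(compute_bin_goi(3, 1, 1), 0.4)    # total exactly 5 is defined
  expect_true(is.na(compute_bin_goi(0, 0, 0)))
  expect_error(compute_bin_goi(-1, 0, 0))
})

test_that("both-counts heterozygote mode changes only the denominator", {
  expect_equal(compute_bin_goi(6, 2, 2, het_mode = "both-counts"), 4 / 12)
  expect_equal(compute_bin_goi(10, 0, 0, het_mode = "both-counts"), 1.0)
  expect_equal(compute_bin_goi(2, 2, 6, het_mode = "both-counts"), 0.0)
  # Numerator identical under both readings on random counts.
  set.seed(11)
  m <- rpois(50, 6); p <- rpois(50, 6); h <- rpois(50, 6)
  a <- compute_bin_goi(m, p, h)
  b <- compute_bin_goi(m, p, h, het_mode = "both-counts")
  def <- !is.na(a)
  expect_equal(a[def] * (m + p + h)[def], b[def] * (m + p + 2 * h)[def])
})

test_that("defined GOI is bounded and hits +/-1 only for pure bins", {
  set.seed(42)
  m <- rpois(200, 3); p <- rpois(200, 3); h <- rpois(200, 3)
  g <- compute_bin_goi(m, p, h)
  def <- !is.na(g)
  expect_true(all(g[def] >= -1 & g[def] <= 1))
  expect_equal(g[def] == 1, (p[def] == 0 & h[def] == 0))
  expect_equal(g[def] == -1, (m[def] == 0 & h[def] == 0))
  # Converting one het to hom_paternal strictly decreases GOI.
  expect_true(all(compute_bin_goi(m, p + 1, pmax(h - 1, 0))[def & h > 0] <
                    g[def & h > 0]))
})

test_that("assign_origin maps the closed call vocabulary and rejects strangers", {
  o <- assign_origin(c("hom_maternal", "hom_paternal", "het", "missing"))
  expect_equal(as.character(o), c("maternal", "paternal", "heterozygous", NA))
  expect_error(assign_origin("hom_ref"), "unknown")
})

test_that("profile counts partition the genotyped sites", {
  m <- simulate_parents(small_map(), 5e-4, seed = 13)
  g <- simulate_offspring(m, scenario_spec("biparental_diploid"),
                          sequencing_model(3, 0.005), seed = 14)
  p <- genome_goi_profile(g, m)
  qc <- attr(p, "qc")
  expect_equal(sum(p$n_total) + qc$n_missing, nrow(g))
  expect_equal(p$n_total, p$n_maternal + p$n_paternal + p$n_het)
  expect_true(all(is.na(p$goi) == (p$n_total < 5)))
})

test_that("noise-free profiles are exactly 1 (haploid) and 0 (diploid)", {
  m <- simulate_parents(small_map(), 5e-4, seed = 2)
  hi <- sequencing_model(1000, 0)
  p_hap <- genome_goi_profile(
    simulate_offspring(m, scenario_spec("maternal_haploid"), hi, seed = 5), m)
  expect_true(all(p_hap$goi[!is.na(p_hap$goi)] == 1))
  p_dip <- genome_goi_profile(
    simulate_offspring(m, scenario_spec("biparental_diploid"), hi, seed = 5), m)
  expect_true(all(p_dip$goi[!is.na(p_dip$goi)] == 0))
  loss <- simulate_offspring(
    m, scenario_spec("paternal_chrom_loss", lost_chroms = "Chr2"), hi, seed = 5)
  p_loss <- genome_goi_profile(loss, m)
  def <- !is.na(p_loss$goi)
  expect_true(all(p_loss$goi[def & p_loss$chrom == "Chr2"] == 1))
  expect_true(all(p_loss$goi[def & p_loss$chrom == "Chr1"] == 0))
})

test_that("binned pipeline equals the brute-force recount on shuffled input", {
  cm <- small_map()
  m <- simulate_parents(cm, 6e-4, seed = 19)   # ~1000 sites
  g <- simulate_offspring(m, scenario_spec("paternal_chrom_loss",
                                           lost_chroms = "Chr2"),
                          sequencing_model(5, 0.005), seed = 20)
  oracle <- brute_force_goi(g, cm)
  shuffled <- g[sample.int(nrow(g)), ]
  attributes(shuffled) <- c(attributes(shuffled)[c("names", "row.names")],
                            attributes(g)[c("sample_id", "scenario_kind",
                                            "n_nonparental", "class")])
  p <- genome_goi_profile(shuffled, m, chrom_map = cm)
  expect_equal(p$goi, oracle)
})

test_that("genotypes at non-marker positions are rejected", {
  m <- simulate_parents(small_map(), 5e-4, seed = 2)
  g <- simulate_offspring(m, scenario_spec("biparental_diploid"),
                          sequencing_model(5, 0), seed = 3)
  g$pos[1] <- g$pos[1] + 1L
  expect_error(genome_goi_profile(g, m), "absent from the marker set")
})

test_that("coding raw offspring genotypes matches the direct simulation", {
  m <- simulate_parents(small_map(), 4e-4, seed = 23)
  g <- simulate_offspring(m, scenario_spec("maternal_haploid"),
                          sequencing_model(5, 0.005), seed = 24,
                          sample_id = "s1")
  d <- withr::local_tempdir()
  write_offspring_vcf(g, m, file.path(d, "s1.vcf"))
  coded <- code_offspring_genotypes(read_offspring_vcf(file.path(d, "s1.vcf")),
                                    m, sample_id = "s1")
  expect_equal(as.data.frame(coded), as.data.frame(g), ignore_attr = TRUE)
  # A genotype carrying a non-parental allele is excluded and tallied.
  raw <- data.frame(chrom = m$chrom[1:3], pos = m$pos[1:3],
                    allele1 = m$maternal_allele[1:3],
                    allele2 = m$maternal_allele[1:3])
  other <- setdiff(c("A", "C", "G", "T"),
                   c(m$maternal_allele[2], m$paternal_allele[2]))[1]
  raw$allele2[2] <- other
  coded2 <- code_offspring_genotypes(raw, m)
  expect_equal(as.character(coded2$call),
               c("hom_maternal", "missing", "hom_maternal"))
  expect_equal(attr(coded2, "n_nonparental"), 1L)
})
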