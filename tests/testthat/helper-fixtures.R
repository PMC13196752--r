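# Shared fixtures and independent oracles for the suite.

# Small genome for fast end-to-end runs.
small_map <- function() chrom_map(c("Chr1", "Chr2"), c(1e6, 8e5))

# Independent brute-force GOI recount: walks every bin of make_bins() and
# recounts calls by coordinate subsetting, evaluating the formula directly.
# Deliberately naive (O(bins x sites)) and written without reusing the
# binning/tabulation path it is checking.
brute_force_goi <- function(genotypes, cm, bin_width = 100000L,
                            min_snps = 5L) {
  bins <- make_bins(cm, bin_width)
  goi <- numeric(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    sel <- genotypes$chrom == bins$chrom[i] &
      genotypes$pos >= bins$start[i] + 1L & genotypes$pos <= bins$end[i]
    calls <- as.character(genotypes$call[sel])
    m <- sum(calls == "hom_maternal")
    p <- sum(calls == "hom_paternal")
    h <- sum(calls == "het")
    goi[i] <- if (m + p + h < min_snps) NA_real_ else (m - p) / (m + p + h)
  }
  goi
}

# Closed-form fraction of homozygous calls among non-missing calls for a
# heterozygous site sequenced at Poisson depth with no base error: both
# alleles present, so P(hom | D = d) = 2 * (1/2)^d, conditioned on D >= 1.
expected_hom_fraction <- function(mean_depth, max_d = 200L) {
  d <- seq_len(max_d)
  sum(stats::dpois(d, mean_depth) * 2 * 0.5^d) /
    (1 - stats::dpois(0, mean_depth))
}

# Write a minimal single-sample VCF from parallel record fields (test-local,
# independent of the package's writer).
write_test_vcf <- function(path, sample, chrom, pos, ref, alt, qual, gt) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT", gt, sep = "\t")
  ), path)
  path
}

# Default-condition simulation of one offspring and its genome call.
simulate_and_classify <- function(markers, scenario, seq_model, seed,
                                  cfg = classifier_config()) {
  g <- simulate_offspring(markers, scenario, seq_model, seed = seed)
  classify_profile(genome_goi_profile(g, markers), cfg)
}
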