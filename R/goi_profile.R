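# Genome origin index (GOI): per-bin contrast of maternal- vs paternal-origin
# SNP counts, the quantitative core of haploid verification.

#' Map genotype calls to origin classes
#'
#' `hom_maternal` -> `maternal`, `hom_paternal` -> `paternal`, `het` ->
#' `heterozygous`; `missing` is excluded from all counts and maps to `NA`.
#'
#' @param call Character or factor vector over the genotype-call vocabulary.
#' @return Factor over `maternal`, `paternal`, `heterozygous` with `NA` for
#'   missing calls.
#' @export
assign_origin <- function(call) {
  call <- as.character(call)
  bad <- setdiff(unique(call), CALL_LEVELS)
  if (length(bad) > 0L) {
    stop_input("unknown genotype call(s): ", paste(bad, collapse = ", "))
  }
  map <- c(hom_maternal = "maternal", hom_paternal = "paternal",
           het = "heterozygous", missing = NA_character_)
  factor(unname(map[call]), levels = c("maternal", "paternal", "heterozygous"))
}

#' Genome origin index of a bin
#'
#' GOI = (maternal SNPs - paternal SNPs) / total SNPs in the bin, where total
#' counts the genotyped informative SNPs (maternal + paternal + heterozygous).
#' A bin with fewer than `min_snps` SNPs is ignored and its GOI is `NA`.
#' GOI near 1 indicates a maternal haploid region; GOI near 0 a biparental
#' diploid region.
#'
#' With `het_mode = "both-counts"`, a heterozygous SNP is counted once as
#' maternal and once as paternal; the numerator is unchanged and only the
#' denominator grows (`M + P + 2 het`), so the two modes agree exactly on
#' pure-maternal and hom-free diploid bins.
#'
#' @param n_maternal,n_paternal,n_het Nonnegative per-bin counts (vectorized).
#' @param min_snps Minimum SNPs for a defined GOI (default 5; "less than
#'   five" is undefined, exactly five is defined).
#' @param het_mode `"denominator-only"` (default) or `"both-counts"`.
#' @return Numeric vector in \[-1, 1\] with `NA` for ignored bins.
#' @examples
#' compute_bin_goi(10, 0, 0)  # 1: pure maternal
#' compute_bin_goi(2, 2, 6)   # 0: balanced biparental
#' compute_bin_goi(2, 1, 1)   # NA: only 4 SNPs
#' @export
compute_bin_goi <- function(n_maternal, n_paternal, n_het, min_snps = 5L,
                            het_mode = c("denominator-only", "both-counts")) {
  het_mode <- match.arg(het_mode)
  if (any(n_maternal < 0) || any(n_paternal < 0) || any(n_het < 0)) {
    stop_input("counts must be nonnegative")
  }
  total <- n_maternal + n_paternal + n_het
  denom <- if (het_mode == "both-counts") total + n_het else total
  ifelse(total < min_snps, NA_real_, (n_maternal - n_paternal) / denom)
}

#' Code raw offspring genotypes against the marker set
#'
#' Translates allele-level genotypes (e.g. read from an offspring VCF with
#' [read_offspring_vcf()]) into origin-coded calls at marker sites: both
#' alleles maternal -> `hom_maternal`, both paternal -> `hom_paternal`, one of
#' each -> `het`, no called alleles -> `missing`. Records at non-marker
#' positions are dropped; called genotypes carrying an allele matching
#' neither parent are excluded as `missing` and tallied in the
#' `n_nonparental` attribute.
#'
#' @param gt Data frame with columns `chrom`, `pos`, `allele1`, `allele2`
#'   (single bases, `NA` for uncalled).
#' @param markers A `parental_marker_set`.
#' @param sample_id Sample name attached to the output.
#' @return An `offspring_genotype_table`.
#' @export
code_offspring_genotypes <- function(gt, markers, sample_id = "offspring") {
  stopifnot(inherits(markers, "parental_marker_set"))
  idx <- match(paste(gt$chrom, gt$pos), paste(markers$chrom, markers$pos))
  gt <- gt[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  mat <- markers$maternal_allele[idx]
  pat <- markers$paternal_allele[idx]
  a1 <- gt$allele1
  a2 <- gt$allele2
  uncalled <- is.na(a1) | is.na(a2)
  nonparental <- !uncalled & ((a1 != mat & a1 != pat) | (a2 != mat & a2 != pat))
  call <- rep("missing", nrow(gt))
  ok <- !uncalled & !nonparental
  call[ok & a1 == mat & a2 == mat] <- "hom_maternal"
  call[ok & a1 == pat & a2 == pat] <- "hom_paternal"
  call[ok & ((a1 == mat & a2 == pat) | (a1 == pat & a2 == mat))] <- "het"
  new_genotype_table(
    data.frame(chrom = gt$chrom, pos = gt$pos,
               call = factor(call, levels = CALL_LEVELS),
               stringsAsFactors = FALSE),
    sample_id = sample_id, n_nonparental = sum(nonparental)
  )
}

#' Read an offspring VCF into an allele-level genotype table
#'
#' Extracts GT calls from a single-sample VCF and resolves allele indices to
#' bases. Multiallelic and indel records are skipped; missing genotypes give
#' `NA` alleles.
#'
#' @param path Path to a VCF.
#' @return Data frame with columns `chrom`, `pos`, `allele1`, `allele2`.
#' @export
read_offspring_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(ref) & !is.na(alt) & ref %in% BASES & alt %in% BASES
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(ifelse(is.na(gt), "./.", gt), "/", fixed = TRUE)
  a1i <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  a2i <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  pick <- function(i, r, a) ifelse(is.na(i), NA_character_,
                                   ifelse(i == 0L, r, a))
  data.frame(
    chrom = chrom[keep], pos = pos[keep],
    allele1 = pick(a1i[keep], ref[keep], alt[keep]),
    allele2 = pick(a2i[keep], ref[keep], alt[keep]),
    stringsAsFactors = FALSE
  )
}

#' Binned genome-origin profile of one offspring
#'
#' Partitions every chromosome into consecutive nonoverlapping `bin_width`-bp
#' bins, counts origin-assigned SNPs per bin, and computes the per-bin GOI.
#' Missing calls are excluded from the counts by default (an uncalled site
#' carries no origin information); set `missing_in_total = TRUE` to count
#' them in the bin total, which makes the NA rule act on all marker sites in
#' the bin rather than on genotyped ones.
#'
#' @param genotypes An `offspring_genotype_table` coded against `markers`.
#' @param markers The `parental_marker_set` used for coding; a genotype at a
#'   position absent from it is an error (it indicates an upstream coding
#'   bug).
#' @param chrom_map A [chrom_map]; defaults to the one attached to `markers`.
#' @param bin_width Bin width in bp (default 100,000).
#' @param min_snps Minimum SNPs per bin for a defined GOI (default 5).
#' @param het_mode Heterozygous-SNP accounting; see [compute_bin_goi()].
#' @param missing_in_total Count missing calls in `n_total` (default FALSE).
#' @return A `bin_goi_profile`: bin table with columns `chrom`, `start`,
#'   `end`, `n_maternal`, `n_paternal`, `n_het`, `n_total`, `goi`, one row
#'   per genome bin in order, with attributes `sample_id`, `bin_width`, and
#'   `qc` (excluded-site tallies).
#' @export
genome_goi_profile <- function(genotypes, markers, chrom_map = NULL,
                               bin_width = 100000L, min_snps = 5L,
                               het_mode = c("denominator-only", "both-counts"),
                               missing_in_total = FALSE) {
  stopifnot(inherits(genotypes, "offspring_genotype_table"),
            inherits(markers, "parental_marker_set"))
  het_mode <- match.arg(het_mode)
  chrom_map <- as_chrom_map(chrom_map %||% attr(markers, "chrom_map"))
  in_markers <- paste(genotypes$chrom, genotypes$pos) %in%
    paste(markers$chrom, markers$pos)
  if (!all(in_markers)) {
    stop_input("genotype call(s) at position(s) absent from the marker set ",
               "(first: ", genotypes$chrom[!in_markers][1L], ":",
               genotypes$pos[!in_markers][1L], ")")
  }
  bins <- make_bins(chrom_map, bin_width)
  bin_id <- site_bin_index(genotypes$chrom, genotypes$pos, bins, bin_width,
                           chrom_map)
  origin <- assign_origin(genotypes$call)
  nb <- nrow(bins)
  bins$n_maternal <- tabulate(bin_id[which(origin == "maternal")], nbins = nb)
  bins$n_paternal <- tabulate(bin_id[which(origin == "paternal")], nbins = nb)
  bins$n_het <- tabulate(bin_id[which(origin == "heterozygous")], nbins = nb)
  n_missing_bin <- tabulate(bin_id[is.na(origin)], nbins = nb)
  bins$n_total <- bins$n_maternal + bins$n_paternal + bins$n_het
  if (missing_in_total) bins$n_total <- bins$n_total + n_missing_bin
  bins$goi <- compute_bin_goi(bins$n_maternal, bins$n_paternal, bins$n_het,
                              min_snps = min_snps, het_mode = het_mode)
  if (missing_in_total) {
    bins$goi[bins$n_total < min_snps] <- NA_real_
  }
  structure(bins,
            sample_id = attr(genotypes, "sample_id"),
            bin_width = as.integer(bin_width),
            qc = list(n_missing = sum(is.na(origin)),
                      n_nonparental = attr(genotypes, "n_nonparental") %||% 0L),
            class = c("bin_goi_profile", "data.frame"))
}

#' @export
print.bin_goi_profile <- function(x, ...) {
  cat(sprintf(
    "Binned GOI profile for sample '%s': %d bins (%d defined) on %d chromosome(s), bin width %d bp\n",
    attr(x, "sample_id"), nrow(x), sum(!is.na(x$goi)),
    length(unique(x$chrom)), attr(x, "bin_width")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
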