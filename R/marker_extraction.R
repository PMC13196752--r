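# Parent-informative marker derivation from parental VCFs.

# Read one parent's VCF and reduce it to confident homozygous biallelic SNP
# calls: data frame (chrom, pos, allele, qual). Sites that are heterozygous,
# missing, multiallelic, indels, or at/below the QUAL cutoff are dropped.
read_parent_homozygous <- function(path, qual_min_exclusive) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || ncol(v@gt) < 2L) {
    stop_input("no genotype column in ", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  chrom <- fix[, "CHROM"]
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop_input("malformed record in ", path, " at ", chrom[bad], ":",
               fix[bad, "POS"])
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  snp <- !is.na(ref) & !is.na(alt) & ref %in% BASES & alt %in% BASES
  hom_ref <- gt %in% c("0/0", "0|0")
  hom_alt <- gt %in% c("1/1", "1|1")
  keep <- snp & (hom_ref | hom_alt) & !is.na(qual) & qual > qual_min_exclusive
  data.frame(
    chrom = chrom[keep], pos = pos[keep],
    allele = ifelse(hom_ref[keep], ref[keep], alt[keep]),
    qual = qual[keep], stringsAsFactors = FALSE
  )
}

#' Extract parent-informative SNP markers from parental VCFs
#'
#' A site becomes a marker iff both parents carry a confident homozygous
#' biallelic SNP call there, the two homozygous alleles differ, and the
#' record QUAL strictly exceeds `qual_min_exclusive` in both parents (the
#' boundary value itself is removed, i.e. QUAL <= 20 is filtered out at the
#' default). Heterozygous, missing, multiallelic, and indel records are
#' excluded. The retained marker QUAL is the smaller of the two parental
#' QUALs.
#'
#' @param maternal_vcf,paternal_vcf Paths to single-sample VCFs called
#'   against the same reference.
#' @param qual_min_exclusive Exclusive QUAL threshold (default 20).
#' @param chrom_map Optional [chrom_map]; contigs absent from it are skipped
#'   with a warning, and output follows its chromosome order. When `NULL`,
#'   the map is taken from the maternal VCF's contig headers (or order of
#'   appearance).
#' @return A `parental_marker_set`, sorted by (chrom, pos).
#' @export
extract_informative_markers <- function(maternal_vcf, paternal_vcf,
                                        qual_min_exclusive = 20,
                                        chrom_map = NULL) {
  mat <- read_parent_homozygous(maternal_vcf, qual_min_exclusive)
  pat <- read_parent_homozygous(paternal_vcf, qual_min_exclusive)

  key_m <- paste(mat$chrom, mat$pos)
  key_p <- paste(pat$chrom, pat$pos)
  idx <- match(key_m, key_p)
  hit <- !is.na(idx)
  out <- data.frame(
    chrom = mat$chrom[hit], pos = mat$pos[hit],
    maternal_allele = mat$allele[hit],
    paternal_allele = pat$allele[idx[hit]],
    qual = pmin(mat$qual[hit], pat$qual[idx[hit]]),
    stringsAsFactors = FALSE
  )
  out <- out[out$maternal_allele != out$paternal_allele, , drop = FALSE]

  if (is.null(chrom_map)) {
    chroms <- unique(c(mat$chrom, pat$chrom, out$chrom))
    lens <- vapply(chroms, function(ch) {
      m <- c(mat$pos[mat$chrom == ch], pat$pos[pat$chrom == ch])
      if (length(m)) max(m) else 1
    }, 0)
    chrom_map <- chrom_map(chroms, pmax(lens, 1))
  } else {
    chrom_map <- as_chrom_map(chrom_map)
    stray <- setdiff(unique(out$chrom), chrom_map$chrom)
    if (length(stray) > 0L) {
      warning("skipping contig(s) absent from chromosome map: ",
              paste(stray, collapse = ", "), call. = FALSE)
      out <- out[out$chrom %in% chrom_map$chrom, , drop = FALSE]
    }
  }
  ord <- order(match(out$chrom, chrom_map$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  new_marker_set(out, chrom_map)
}

#' Per-bin marker density report
#'
#' Pre-flight check for the binned GOI: counts markers per bin and flags bins
#' whose count falls below `min_markers` (such bins will have undefined GOI
#' regardless of the offspring data).
#'
#' @param markers A `parental_marker_set`.
#' @param chrom_map A [chrom_map]; defaults to the one attached to `markers`.
#' @param bin_width Bin width in bp (default 100,000).
#' @param min_markers Flagging threshold (default 5, the GOI NA rule).
#' @return Bin table with `n_markers` and logical `flagged` columns; the
#'   overall flagged fraction is attached as attribute `fraction_flagged`.
#' @export
marker_density_report <- function(markers, chrom_map = NULL,
                                  bin_width = 100000L, min_markers = 5L) {
  stopifnot(inherits(markers, "parental_marker_set"))
  chrom_map <- as_chrom_map(chrom_map %||% attr(markers, "chrom_map"))
  bins <- make_bins(chrom_map, bin_width)
  bin_id <- site_bin_index(markers$chrom, markers$pos, bins, bin_width,
                           chrom_map)
  bins$n_markers <- tabulate(bin_id, nbins = nrow(bins))
  bins$flagged <- bins$n_markers < min_markers
  attr(bins, "fraction_flagged") <- mean(bins$flagged)
  bins
}

# Map 1-based site positions to row indices of a make_bins() table.
site_bin_index <- function(chrom, pos, bins, bin_width, chrom_map) {
  n_bins_per_chrom <- ceiling(chrom_map$length / bin_width)
  offset <- c(0, cumsum(n_bins_per_chrom))[match(chrom, chrom_map$chrom)]
  if (anyNA(offset)) {
    stop_input("site chromosome(s) absent from chromosome map: ",
               paste(unique(chrom[is.na(offset)]), collapse = ", "))
  }
  offset + (pos - 1) %/% bin_width + 1
}
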