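# Plain-text interchange: marker TSV, GOI TSV, and a minimal GT-only VCFv4.2
# writer used for simulated parents and offspring. Reading real VCFs goes
# through vcfR (see marker_extraction.R).

#' Write / read a parent-informative marker table
#'
#' Tab-separated with header: `chrom`, `pos` (1-based, as in VCF),
#' `maternal_allele`, `paternal_allele`, `qual`.
#'
#' @param markers A `parental_marker_set`.
#' @param path Output (or input) file path.
#' @param chrom_map Optional [chrom_map] to attach on read; defaults to
#'   chromosome order of appearance with length = max position seen.
#' @return `write_marker_tsv` returns `path` invisibly; `read_marker_tsv`
#'   returns a `parental_marker_set`.
#' @export
write_marker_tsv <- function(markers, path) {
  stopifnot(inherits(markers, "parental_marker_set"))
  utils::write.table(as.data.frame(markers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path, chrom_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric"))
  if (is.null(chrom_map)) {
    chroms <- unique(df$chrom)
    lens <- vapply(chroms, function(ch) max(df$pos[df$chrom == ch]), 0)
    chrom_map <- chrom_map(chroms, lens)
  } else {
    chrom_map <- as_chrom_map(chrom_map)
  }
  new_marker_set(df, chrom_map)
}

# Shared minimal VCFv4.2 writer: biallelic SNP records, GT-only FORMAT.
write_minimal_vcf <- function(path, chrom, pos, ref, alt, qual, gt,
                              sample_name, chrom_map) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplorigin",
    sprintf("##contig=<ID=%s,length=%d>", chrom_map$chrom,
            as.integer(chrom_map$length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_name), collapse = "\t")
  )
  body <- paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT", gt,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write simulated parents as a minimal VCF pair
#'
#' One GT-only VCFv4.2 file per parent, sharing record coordinates: REF is the
#' maternal allele and ALT the paternal allele at every marker site, the
#' maternal sample carries `0/0` and the paternal sample `1/1`, and both files
#' carry the marker's QUAL. [extract_informative_markers()] recovers the
#' original marker set exactly from this pair.
#'
#' @param markers A `parental_marker_set`.
#' @param maternal_path,paternal_path Output VCF paths.
#' @param maternal_name,paternal_name Sample names written in the headers.
#' @return Invisibly, the two paths.
#' @export
write_parental_vcfs <- function(markers, maternal_path, paternal_path,
                                maternal_name = "maternal",
                                paternal_name = "paternal") {
  stopifnot(inherits(markers, "parental_marker_set"))
  cm <- attr(markers, "chrom_map")
  write_minimal_vcf(maternal_path, markers$chrom, markers$pos,
                    markers$maternal_allele, markers$paternal_allele,
                    markers$qual, "0/0", maternal_name, cm)
  write_minimal_vcf(paternal_path, markers$chrom, markers$pos,
                    markers$maternal_allele, markers$paternal_allele,
                    markers$qual, "1/1", paternal_name, cm)
  invisible(c(maternal_path, paternal_path))
}

#' Write an offspring genotype table as a minimal VCF
#'
#' Records are emitted at every marker site with REF = maternal allele and
#' ALT = paternal allele; origin-coded calls map to GT as `hom_maternal` ->
#' `0/0`, `het` -> `0/1`, `hom_paternal` -> `1/1`, `missing` -> `./.`.
#'
#' @param genotypes An `offspring_genotype_table`.
#' @param markers The `parental_marker_set` the calls were coded against.
#' @param path Output VCF path.
#' @param sample_name Sample name; defaults to the table's `sample_id`.
#' @return `path`, invisibly.
#' @export
write_offspring_vcf <- function(genotypes, markers, path,
                                sample_name = NULL) {
  stopifnot(inherits(genotypes, "offspring_genotype_table"),
            inherits(markers, "parental_marker_set"))
  sample_name <- sample_name %||% attr(genotypes, "sample_id")
  idx <- match(paste(genotypes$chrom, genotypes$pos),
               paste(markers$chrom, markers$pos))
  if (anyNA(idx)) {
    stop_input("genotype table contains sites absent from the marker set")
  }
  gt <- c(hom_maternal = "0/0", hom_paternal = "1/1",
          het = "0/1", missing = "./.")[as.character(genotypes$call)]
  write_minimal_vcf(path, genotypes$chrom, genotypes$pos,
                    markers$maternal_allele[idx], markers$paternal_allele[idx],
                    ".", gt, sample_name, attr(markers, "chrom_map"))
}

#' Write a binned GOI profile as TSV
#'
#' One row per bin in genome order with columns `sample_id`, `chrom`, `start`,
#' `end`, `n_maternal`, `n_paternal`, `n_het`, `n_total`, `goi`. Coordinates
#' are 0-based half-open (BED-like); undefined GOI is written as the literal
#' `NA`. This is the plotting table for per-chromosome genome-dosage tracks.
#'
#' @param profile A `bin_goi_profile` (see [genome_goi_profile()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_goi_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "bin_goi_profile"))
  out <- cbind(sample_id = attr(profile, "sample_id"),
               as.data.frame(profile))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
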