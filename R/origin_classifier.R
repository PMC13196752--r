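# Classification of binned GOI profiles into per-chromosome and whole-genome
# origin calls: maternal haploid, biparental diploid, or diploid lacking
# paternal chromosomes/segments.

#' Classifier thresholds
#'
#' GOI is interpreted qualitatively (near 1 means a maternal haploid region,
#' near 0 a biparental diploid region); these cutoffs make that quantitative.
#' Defaults separate the analytic GOI distributions of haploid and diploid
#' bins by well over 5 standard deviations at 5x depth with a dozen markers
#' per bin.
#'
#' @param tau_maternal Bin GOI at or above this is maternal (default 0.8).
#' @param tau_paternal Bin GOI at or below this is paternal (default -0.8).
#' @param tau_biparental_abs Bin |GOI| at or below this is biparental
#'   (default 0.3); anything between the bands is ambiguous.
#' @param chrom_consensus_fraction Fraction of defined bins that must share a
#'   class for a chromosome call (default 0.8; must exceed 0.5).
#' @param min_defined_bins_per_chrom Minimum defined bins to call a
#'   chromosome at all (default 5).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(tau_maternal = 0.8, tau_paternal = -0.8,
                              tau_biparental_abs = 0.3,
                              chrom_consensus_fraction = 0.8,
                              min_defined_bins_per_chrom = 5L) {
  ok <- tau_paternal >= -1 && tau_paternal < -tau_biparental_abs &&
    tau_biparental_abs > 0 && tau_biparental_abs < tau_maternal &&
    tau_maternal <= 1
  if (!ok) {
    stop_input("thresholds must satisfy -1 <= tau_paternal < ",
               "-tau_biparental_abs < 0 < tau_biparental_abs < ",
               "tau_maternal <= 1")
  }
  if (!(chrom_consensus_fraction > 0.5 && chrom_consensus_fraction <= 1)) {
    stop_input("`chrom_consensus_fraction` must be in (0.5, 1]")
  }
  if (!is_count(min_defined_bins_per_chrom) ||
      min_defined_bins_per_chrom < 1L) {
    stop_input("`min_defined_bins_per_chrom` must be a positive integer")
  }
  structure(
    list(tau_maternal = tau_maternal, tau_paternal = tau_paternal,
         tau_biparental_abs = tau_biparental_abs,
         chrom_consensus_fraction = chrom_consensus_fraction,
         min_defined_bins_per_chrom = as.integer(min_defined_bins_per_chrom)),
    class = "classifier_config"
  )
}

BIN_CLASSES <- c("maternal", "paternal", "biparental", "ambiguous")

#' Classify bins by GOI
#'
#' @param goi Numeric vector of bin GOI values (`NA` for undefined bins).
#' @param cfg A [classifier_config()].
#' @return Factor over `maternal`, `paternal`, `biparental`, `ambiguous`,
#'   with `NA` preserved for undefined bins.
#' @examples
#' classify_bin(c(1, 0, 0.5, NA), classifier_config())
#' @export
classify_bin <- function(goi, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  out <- rep(NA_character_, length(goi))
  def <- !is.na(goi)
  out[def & goi >= cfg$tau_maternal] <- "maternal"
  out[def & goi <= cfg$tau_paternal] <- "paternal"
  mid <- def & is.na(out) & abs(goi) <= cfg$tau_biparental_abs
  out[mid] <- "biparental"
  out[def & is.na(out)] <- "ambiguous"
  factor(out, levels = BIN_CLASSES)
}

#' Classify one chromosome from its bin classes
#'
#' A chromosome with fewer than `min_defined_bins_per_chrom` defined bins is
#' indeterminate. Otherwise, if at least `chrom_consensus_fraction` of the
#' defined bins share one of the maternal/paternal/biparental classes, that
#' class is the chromosome call. Failing consensus, a chromosome whose
#' defined bins split between maternal and biparental stretches — each
#' contributing at least one run of >= 2 contiguous bins, and jointly making
#' up the consensus fraction — is called `mixed_segmental` (segmental
#' paternal loss). Anything else is indeterminate.
#'
#' @param bin_classes Factor/character vector from [classify_bin()], in
#'   genomic bin order for one chromosome (`NA` = undefined bin).
#' @param cfg A [classifier_config()].
#' @return List with `call` (one of `maternal`, `paternal`, `biparental`,
#'   `mixed_segmental`, `indeterminate`), `n_defined`, `support` (fraction
#'   backing the call), and `fractions` (per-class fractions of defined
#'   bins).
#' @export
classify_chromosome <- function(bin_classes, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  cls <- as.character(bin_classes)
  def <- cls[!is.na(cls)]
  n_def <- length(def)
  frac <- vapply(BIN_CLASSES, function(k) mean(def == k), 0)
  if (n_def < cfg$min_defined_bins_per_chrom) {
    return(list(call = "indeterminate", n_defined = n_def, support = NA_real_,
                fractions = frac))
  }
  callable <- c("maternal", "paternal", "biparental")
  best <- callable[which.max(frac[callable])]
  if (frac[[best]] >= cfg$chrom_consensus_fraction) {
    return(list(call = best, n_defined = n_def, support = frac[[best]],
                fractions = frac))
  }
  # Segmental path: maternal and biparental stretches coexist along the
  # chromosome, each with at least one run of >= 2 contiguous defined bins.
  runs <- rle(def)
  has_mat_run <- any(runs$values == "maternal" & runs$lengths >= 2L)
  has_bip_run <- any(runs$values == "biparental" & runs$lengths >= 2L)
  joint <- frac[["maternal"]] + frac[["biparental"]]
  if (has_mat_run && has_bip_run && joint >= cfg$chrom_consensus_fraction) {
    return(list(call = "mixed_segmental", n_defined = n_def, support = joint,
                fractions = frac))
  }
  list(call = "indeterminate", n_defined = n_def, support = NA_real_,
       fractions = frac)
}

#' Combine per-chromosome calls into a whole-genome origin call
#'
#' Rules: all chromosomes maternal -> `maternal_haploid`; all biparental ->
#' `biparental_diploid`; any `mixed_segmental` chromosome ->
#' `segmental_paternal_loss`; a mixture of whole biparental and whole
#' maternal chromosomes only -> `biparental_missing_paternal_chroms` (with
#' the maternal chromosome list — the abortive-embryo signature; any whole
#' biparental chromosome proves diploidy); anything else is `indeterminate`. An all-paternal genome is reported as indeterminate
#' with a warning, since the cross design cannot produce it (it signals a
#' sample swap).
#'
#' @param chrom_calls Named character vector of per-chromosome calls.
#' @param cfg A [classifier_config()] (recorded, not used by the rules).
#' @return List with `genome_call`, `lost_chroms` (maternal chromosomes under
#'   a missing-chromosome call), and `segmental_chroms`.
#' @export
classify_genome <- function(chrom_calls, cfg = classifier_config()) {
  calls <- as.character(chrom_calls)
  chroms <- names(chrom_calls) %||% as.character(seq_along(calls))
  if (length(calls) == 0L) stop_input("no chromosome calls supplied")
  segmental <- chroms[calls == "mixed_segmental"]
  maternal <- chroms[calls == "maternal"]
  if (all(calls == "maternal")) {
    genome <- "maternal_haploid"
  } else if (all(calls == "biparental")) {
    genome <- "biparental_diploid"
  } else if (all(calls == "paternal")) {
    warning("all chromosomes called paternal: impossible for this cross ",
            "design, possible sample swap", call. = FALSE)
    genome <- "indeterminate"
  } else if (length(segmental) > 0L) {
    genome <- "segmental_paternal_loss"
  } else if (all(calls %in% c("biparental", "maternal")) &&
             any(calls == "biparental") && length(maternal) > 0L) {
    # Any whole biparental chromosome proves diploidy, so the maternal
    # chromosomes must have lost their paternal copy.
    genome <- "biparental_missing_paternal_chroms"
  } else {
    genome <- "indeterminate"
  }
  list(
    genome_call = genome,
    lost_chroms = if (genome == "biparental_missing_paternal_chroms")
      maternal else character(),
    segmental_chroms = segmental
  )
}

#' Classify a binned GOI profile
#'
#' End-to-end classification of one offspring: bins -> per-chromosome calls
#' -> whole-genome origin call.
#'
#' @param profile A `bin_goi_profile` from [genome_goi_profile()].
#' @param cfg A [classifier_config()].
#' @return A `genome_origin_call`: list with `sample_id`, `genome_call`,
#'   `lost_chroms`, `segmental_chroms`, a per-chromosome table
#'   (`chromosomes`), the config, and QC tallies.
#' @export
classify_profile <- function(profile, cfg = classifier_config()) {
  stopifnot(inherits(profile, "bin_goi_profile"))
  bin_cls <- classify_bin(profile$goi, cfg)
  chroms <- unique(profile$chrom)
  per <- lapply(chroms, function(ch) {
    classify_chromosome(bin_cls[profile$chrom == ch], cfg)
  })
  calls <- vapply(per, `[[`, "", "call")
  names(calls) <- chroms
  genome <- classify_genome(calls, cfg)
  chrom_tab <- data.frame(
    chrom = chroms,
    call = calls,
    n_defined_bins = vapply(per, `[[`, 0L, "n_defined"),
    support = vapply(per, `[[`, 0, "support"),
    frac_maternal = vapply(per, function(p) p$fractions[["maternal"]], 0),
    frac_paternal = vapply(per, function(p) p$fractions[["paternal"]], 0),
    frac_biparental = vapply(per, function(p) p$fractions[["biparental"]], 0),
    frac_ambiguous = vapply(per, function(p) p$fractions[["ambiguous"]], 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(sample_id = attr(profile, "sample_id"),
         genome_call = genome$genome_call,
         lost_chroms = genome$lost_chroms,
         segmental_chroms = genome$segmental_chroms,
         chromosomes = chrom_tab,
         config = unclass(cfg),
         qc = attr(profile, "qc")),
    class = "genome_origin_call"
  )
}

#' @export
print.genome_origin_call <- function(x, ...) {
  cat(sprintf("Sample '%s': %s", x$sample_id, x$genome_call))
  if (length(x$lost_chroms)) {
    cat(" {", paste(x$lost_chroms, collapse = ", "), "}", sep = "")
  }
  cat("\n")
  print(x$chromosomes, row.names = FALSE)
  invisible(x)
}

#' Serialize a genome origin call as JSON
#'
#' @param call A `genome_origin_call` from [classify_profile()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
origin_report <- function(call, path = NULL) {
  stopifnot(inherits(call, "genome_origin_call"))
  json <- jsonlite::toJSON(unclass(call), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null", dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
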