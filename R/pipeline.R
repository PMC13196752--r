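# End-to-end orchestration: parental VCFs -> markers -> per-sample GOI
# profiles -> genome origin calls -> summary, with provenance.

#' Pipeline run configuration
#'
#' Collects the paths and parameters of one reproducible run. All referenced
#' paths must exist when the pipeline starts; the configuration is serialized
#' verbatim into the output directory for provenance.
#'
#' @param maternal_vcf,paternal_vcf Parental VCF paths.
#' @param offspring_vcfs Character vector of offspring VCF paths, optionally
#'   named (names become sample ids; otherwise file stems are used). May be
#'   empty.
#' @param chrom_sizes Path to a chrom-sizes/.fai-style file, or a
#'   [chrom_map].
#' @param out_dir Output directory (created if absent).
#' @param bin_width GOI bin width in bp (default 100,000).
#' @param qual_min Exclusive QUAL threshold for marker extraction
#'   (default 20).
#' @param classifier A [classifier_config()].
#' @param het_mode Heterozygous-SNP accounting; see [compute_bin_goi()].
#' @return A `run_config` list.
#' @export
run_config <- function(maternal_vcf, paternal_vcf, offspring_vcfs,
                       chrom_sizes, out_dir, bin_width = 100000L,
                       qual_min = 20, classifier = classifier_config(),
                       het_mode = c("denominator-only", "both-counts")) {
  het_mode <- match.arg(het_mode)
  offspring_vcfs <- as.character(offspring_vcfs) |>
    stats::setNames(names(offspring_vcfs) %||%
                      tools::file_path_sans_ext(basename(offspring_vcfs)))
  paths <- c(maternal_vcf, paternal_vcf, unname(offspring_vcfs))
  if (is.character(chrom_sizes)) paths <- c(paths, chrom_sizes)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop_input("input path(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(
    list(maternal_vcf = maternal_vcf, paternal_vcf = paternal_vcf,
         offspring_vcfs = offspring_vcfs, chrom_sizes = chrom_sizes,
         out_dir = out_dir, bin_width = as.integer(bin_width),
         qual_min = qual_min, classifier = classifier, het_mode = het_mode),
    class = "run_config"
  )
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[haplorigin] ", ...)
}

#' Run the genome-origin pipeline
#'
#' Executes extract-markers -> code-offspring -> GOI profile -> classify for
#' every offspring sample, writing per-sample bin TSVs and JSON origin
#' reports, a run summary CSV, and a provenance file (package version plus
#' the full configuration). The run is deterministic: identical configuration
#' and inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @param verbose Log progress to standard error (default TRUE).
#' @return Invisibly, the summary data frame (one row per sample: sample id,
#'   genome call, lost chromosomes, defined-bin count, and mean |GOI| of
#'   maternal- and biparental-classified bins).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cm <- if (is.character(config$chrom_sizes)) {
    read_chrom_sizes(config$chrom_sizes)
  } else {
    as_chrom_map(config$chrom_sizes)
  }

  stage <- "extract-markers"
  result <- tryCatch({
    pipeline_log(verbose, "extracting markers (QUAL > ", config$qual_min, ")")
    markers <- extract_informative_markers(
      config$maternal_vcf, config$paternal_vcf,
      qual_min_exclusive = config$qual_min, chrom_map = cm
    )
    pipeline_log(verbose, nrow(markers), " informative markers")

    rows <- vector("list", length(config$offspring_vcfs))
    for (i in seq_along(config$offspring_vcfs)) {
      sample_id <- names(config$offspring_vcfs)[i]
      stage <- paste0("sample:", sample_id)
      raw <- read_offspring_vcf(config$offspring_vcfs[[i]])
      coded <- code_offspring_genotypes(raw, markers, sample_id = sample_id)
      profile <- genome_goi_profile(coded, markers, chrom_map = cm,
                                    bin_width = config$bin_width,
                                    het_mode = config$het_mode)
      call <- classify_profile(profile, config$classifier)
      write_goi_tsv(profile, file.path(config$out_dir,
                                       paste0(sample_id, ".goi.tsv")))
      origin_report(call, file.path(config$out_dir,
                                    paste0(sample_id, ".call.json")))
      cls <- classify_bin(profile$goi, config$classifier)
      rows[[i]] <- data.frame(
        sample_id = sample_id,
        genome_call = call$genome_call,
        lost_chroms = paste(call$lost_chroms, collapse = ";"),
        n_defined_bins = sum(!is.na(profile$goi)),
        mean_abs_goi_maternal_bins =
          mean(abs(profile$goi[which(cls == "maternal")])),
        mean_abs_goi_biparental_bins =
          mean(abs(profile$goi[which(cls == "biparental")])),
        stringsAsFactors = FALSE
      )
      pipeline_log(verbose, sample_id, ": ", call$genome_call)
    }
    summary_df <- if (length(rows)) {
      do.call(rbind, rows)
    } else {
      data.frame(sample_id = character(), genome_call = character(),
                 lost_chroms = character(), n_defined_bins = integer(),
                 mean_abs_goi_maternal_bins = numeric(),
                 mean_abs_goi_biparental_bins = numeric(),
                 stringsAsFactors = FALSE)
    }
    summary_df
  }, error = function(e) {
    stop_input("pipeline failed at stage [", stage, "]: ", conditionMessage(e))
  })

  utils::write.csv(result, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  provenance <- list(
    tool = "haplorigin",
    version = as.character(utils::packageVersion("haplorigin")),
    config = serializable_config(config)
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(verbose, "run complete: ", nrow(result), " sample(s) -> ",
               config$out_dir)
  invisible(result)
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$classifier <- unclass(cfg$classifier)
  if (!is.character(cfg$chrom_sizes)) {
    cfg$chrom_sizes <- as.data.frame(cfg$chrom_sizes)
  }
  cfg
}

#' Generate the demo fixture and run the full pipeline on it
#'
#' Simulates a small cross (a maternal haploid, a biparental diploid, and a
#' diploid lacking paternal Chr2), writes all inputs as VCFs, and runs
#' [run_pipeline()] end to end. Completes in seconds and demonstrates every
#' stage of the package.
#'
#' @param out_dir Output directory.
#' @param seed Integer RNG seed.
#' @param verbose Log progress (default TRUE).
#' @return Invisibly, the run summary data frame.
#' @export
run_demo <- function(out_dir, seed = 1L, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cm <- chrom_map(paste0("Chr", 1:3), c(2e6, 2e6, 2e6))
  markers <- simulate_parents(cm, snp_density = 5e-4, seed = seed)
  seq_model <- sequencing_model(mean_depth = 5, base_error = 0.005)

  input_dir <- file.path(out_dir, "inputs")
  dir.create(input_dir, showWarnings = FALSE)
  mat_vcf <- file.path(input_dir, "maternal.vcf")
  pat_vcf <- file.path(input_dir, "paternal.vcf")
  write_parental_vcfs(markers, mat_vcf, pat_vcf)
  sizes <- file.path(input_dir, "chrom.sizes")
  utils::write.table(as.data.frame(cm), sizes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  scenarios <- list(
    haploid = scenario_spec("maternal_haploid"),
    diploid = scenario_spec("biparental_diploid"),
    chr2_loss = scenario_spec("paternal_chrom_loss", lost_chroms = "Chr2")
  )
  offspring <- character()
  for (i in seq_along(scenarios)) {
    sid <- names(scenarios)[i]
    geno <- simulate_offspring(markers, scenarios[[i]], seq_model,
                               seed = seed + i, sample_id = sid)
    path <- file.path(input_dir, paste0(sid, ".vcf"))
    write_offspring_vcf(geno, markers, path)
    offspring[sid] <- path
  }

  cfg <- run_config(mat_vcf, pat_vcf, offspring, sizes,
                    out_dir = file.path(out_dir, "results"))
  run_pipeline(cfg, verbose = verbose)
}
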