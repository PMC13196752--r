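#' Sequencing-noise model for simulated genotype calls
#'
#' Describes low-coverage short-read genotyping of offspring: per-site depth is
#' Poisson with mean `mean_depth`, each read miscalls its allele with
#' probability `base_error` (uniformly to one of the three other bases;
#' non-parental bases are dropped before genotype calling), and a site is
#' called only if at least `min_depth_call` reads carry a parental allele.
#'
#' Offspring in the emulated study design are sequenced at ~5x, parents at
#' ~30x; the default reflects the offspring setting.
#'
#' @param mean_depth Positive mean reads per site (Poisson mean).
#' @param base_error Per-read miscall probability, in \[0, 0.1\].
#' @param min_depth_call Minimum informative reads for a genotype call (>= 1).
#' @return A `sequencing_model` list.
#' @export
sequencing_model <- function(mean_depth = 5, base_error = 0.005,
                             min_depth_call = 1L) {
  if (!is.numeric(mean_depth) || length(mean_depth) != 1L || mean_depth <= 0) {
    stop_input("`mean_depth` must be a positive number")
  }
  if (!is_prob(base_error) || base_error > 0.1) {
    stop_input("`base_error` must be in [0, 0.1]")
  }
  if (!is_count(min_depth_call) || min_depth_call < 1L) {
    stop_input("`min_depth_call` must be an integer >= 1")
  }
  structure(
    list(mean_depth = mean_depth, base_error = base_error,
         min_depth_call = as.integer(min_depth_call)),
    class = "sequencing_model"
  )
}

#' Cross scenario specification
#'
#' The four offspring classes the simulator can generate: a maternal haploid
#' (the intended induction outcome), a normal biparental diploid hybrid, a
#' diploid missing one or more whole paternal chromosomes (the abortive-embryo
#' signature), and a diploid with segmental paternal loss.
#'
#' @param kind One of `"maternal_haploid"`, `"biparental_diploid"`,
#'   `"paternal_chrom_loss"`, `"segmental_paternal_loss"`.
#' @param lost_chroms Character vector of chromosomes whose paternal copy is
#'   lost; only for `kind = "paternal_chrom_loss"`.
#' @param lost_intervals Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive bp) of paternal segments lost; only for
#'   `kind = "segmental_paternal_loss"`.
#' @return A `scenario_spec` list.
#' @examples
#' scenario_spec("paternal_chrom_loss", lost_chroms = "Chr2")
#' @export
scenario_spec <- function(kind = c("maternal_haploid", "biparental_diploid",
                                   "paternal_chrom_loss",
                                   "segmental_paternal_loss"),
                          lost_chroms = character(),
                          lost_intervals = NULL) {
  kind <- match.arg(kind)
  lost_chroms <- as.character(lost_chroms)
  if (kind == "paternal_chrom_loss") {
    if (length(lost_chroms) == 0L) {
      stop_input("paternal_chrom_loss requires at least one lost chromosome")
    }
  } else if (length(lost_chroms) > 0L) {
    stop_input("`lost_chroms` only applies to kind = \"paternal_chrom_loss\"")
  }
  if (kind == "segmental_paternal_loss") {
    if (is.null(lost_intervals) || !is.data.frame(lost_intervals) ||
        !all(c("chrom", "start", "end") %in% names(lost_intervals)) ||
        nrow(lost_intervals) == 0L) {
      stop_input(
        "segmental_paternal_loss requires `lost_intervals` with chrom/start/end")
    }
    if (any(lost_intervals$start < 1) ||
        any(lost_intervals$end < lost_intervals$start)) {
      stop_input("lost intervals must satisfy 1 <= start <= end")
    }
  } else if (!is.null(lost_intervals)) {
    stop_input(
      "`lost_intervals` only applies to kind = \"segmental_paternal_loss\"")
  }
  structure(
    list(kind = kind, lost_chroms = lost_chroms,
         lost_intervals = lost_intervals),
    class = "scenario_spec"
  )
}

#' Simulate two homozygous inbred parents
#'
#' Places parent-informative biallelic SNPs along each chromosome as a Poisson
#' process with the given density, assigning each site a maternal and a
#' distinct paternal allele (both parents homozygous by construction, as for
#' inbred lines). A per-site QUAL in \[30, 60\] is attached so the marker set
#' survives the downstream quality filter and round-trips through VCF.
#'
#' @param chrom_map A [chrom_map].
#' @param snp_density Expected SNPs per bp (> 0).
#' @param seed Integer RNG seed.
#' @return A `parental_marker_set` data frame with columns `chrom`, `pos`
#'   (1-based), `maternal_allele`, `paternal_allele`, `qual`, sorted by
#'   genome order; the chromosome map is attached as attribute `chrom_map`.
#' @examples
#' m <- simulate_parents(chrom_map("Chr1", 1e6), snp_density = 1e-3, seed = 7)
#' nrow(m)
#' @export
simulate_parents <- function(chrom_map, snp_density, seed) {
  chrom_map <- as_chrom_map(chrom_map)
  if (nrow(chrom_map) == 0L) {
    stop_input("chromosome map is empty: nothing to simulate")
  }
  if (!is.numeric(snp_density) || length(snp_density) != 1L ||
      !is.finite(snp_density) || snp_density <= 0) {
    stop_input("`snp_density` must be a positive number (SNPs per bp)")
  }
  markers <- with_seed(seed, {
    pieces <- lapply(seq_len(nrow(chrom_map)), function(i) {
      len <- chrom_map$length[i]
      n <- stats::rpois(1L, len * snp_density)
      n <- min(n, len)
      pos <- sort(sample.int(len, n))
      mat <- sample(BASES, n, replace = TRUE)
      shift <- sample.int(3L, n, replace = TRUE)
      pat <- BASES[(match(mat, BASES) - 1L + shift) %% 4L + 1L]
      data.frame(
        chrom = rep(chrom_map$chrom[i], n), pos = pos,
        maternal_allele = mat, paternal_allele = pat,
        qual = round(stats::runif(n, 30, 60), 2),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, pieces)
  })
  rownames(markers) <- NULL
  new_marker_set(markers, chrom_map)
}

new_marker_set <- function(df, chrom_map) {
  structure(df, chrom_map = chrom_map,
            class = c("parental_marker_set", "data.frame"))
}

# True allele content per marker site for a scenario: TRUE = maternal-only
# (paternal copy absent), FALSE = heterozygous biparental.
scenario_maternal_only <- function(markers, scenario) {
  switch(scenario$kind,
    maternal_haploid = rep(TRUE, nrow(markers)),
    biparental_diploid = rep(FALSE, nrow(markers)),
    paternal_chrom_loss = {
      missing_chroms <- setdiff(scenario$lost_chroms, unique(markers$chrom))
      if (length(missing_chroms) > 0L) {
        stop_input("scenario references chromosome(s) absent from markers: ",
                   paste(missing_chroms, collapse = ", "))
      }
      markers$chrom %in% scenario$lost_chroms
    },
    segmental_paternal_loss = {
      iv <- scenario$lost_intervals
      missing_chroms <- setdiff(unique(iv$chrom), unique(markers$chrom))
      if (length(missing_chroms) > 0L) {
        stop_input("scenario references chromosome(s) absent from markers: ",
                   paste(missing_chroms, collapse = ", "))
      }
      hit <- rep(FALSE, nrow(markers))
      for (j in seq_len(nrow(iv))) {
        hit <- hit | (markers$chrom == iv$chrom[j] &
                        markers$pos >= iv$start[j] & markers$pos <= iv$end[j])
      }
      hit
    }
  )
}

#' Simulate offspring genotype calls at marker sites
#'
#' Builds the noise-free truth layer implied by the scenario (maternal-only or
#' heterozygous at every marker site), then overlays the sequencing model:
#' per-site depth is Poisson, reads are drawn from the true allele(s) with
#' per-read miscalls, reads carrying non-parental bases are discarded, and the
#' genotype is called heterozygous if both parental alleles are observed,
#' homozygous if exactly one is, and missing if fewer than `min_depth_call`
#' informative reads remain.
#'
#' @param markers A `parental_marker_set` (see [simulate_parents()]).
#' @param scenario A [scenario_spec()].
#' @param seq A [sequencing_model()].
#' @param seed Integer RNG seed.
#' @param sample_id Sample name attached to the output.
#' @return An `offspring_genotype_table`: data frame with columns `chrom`,
#'   `pos`, `call` (factor over `hom_maternal`, `hom_paternal`, `het`,
#'   `missing`), with attributes `sample_id` and `scenario_kind`.
#' @export
simulate_offspring <- function(markers, scenario, seq = sequencing_model(),
                               seed = 1L, sample_id = "offspring") {
  stopifnot(inherits(markers, "parental_marker_set"),
            inherits(scenario, "scenario_spec"),
            inherits(seq, "sequencing_model"))
  if (nrow(markers) == 0L) stop_input("marker set is empty")
  mat_only <- scenario_maternal_only(markers, scenario)
  n <- nrow(markers)
  e <- seq$base_error
  # Per-read probability of reporting the maternal / paternal allele.
  # Maternal-only truth: correct read w.p. 1-e; an erroneous read lands on the
  # paternal base w.p. e/3. Het truth: symmetric.
  p_m <- ifelse(mat_only, 1 - e, 0.5 * (1 - e) + 0.5 * e / 3)
  p_p <- ifelse(mat_only, e / 3, 0.5 * (1 - e) + 0.5 * e / 3)
  call <- with_seed(seed, {
    depth <- stats::rpois(n, seq$mean_depth)
    n_m <- stats::rbinom(n, depth, p_m)
    # Paternal reads among the remainder; when p_m = 1 (error-free
    # maternal-only sites) the remainder is empty and no paternal reads occur.
    p_p_cond <- ifelse(p_m >= 1, 0, p_p / (1 - p_m))
    n_p <- stats::rbinom(n, depth - n_m, p_p_cond)
    out <- rep("missing", n)
    informative <- n_m + n_p
    out[informative >= seq$min_depth_call & n_m > 0L & n_p == 0L] <- "hom_maternal"
    out[informative >= seq$min_depth_call & n_p > 0L & n_m == 0L] <- "hom_paternal"
    out[informative >= seq$min_depth_call & n_m > 0L & n_p > 0L] <- "het"
    out
  })
  new_genotype_table(
    data.frame(chrom = markers$chrom, pos = markers$pos,
               call = factor(call, levels = CALL_LEVELS),
               stringsAsFactors = FALSE),
    sample_id = sample_id, scenario_kind = scenario$kind
  )
}

new_genotype_table <- function(df, sample_id, scenario_kind = NA_character_,
                               n_nonparental = 0L) {
  structure(df, sample_id = sample_id, scenario_kind = scenario_kind,
            n_nonparental = n_nonparental,
            class = c("offspring_genotype_table", "data.frame"))
}

#' Seed-lot screening specification
#'
#' Parameters of a simulated marker-screened seed lot: lot size, true haploid
#' induction rate among germinated seeds, seed abortion rate (applied before
#' germination counting), and marker misclassification rates (a false negative
#' scores a true haploid as diploid; a false positive scores a diploid as
#' haploid). Misclassification moves seeds between observed classes but never
#' changes totals.
#'
#' @param n_seeds Total seeds in the lot (> 0).
#' @param true_hir True haploid fraction among germinated seeds, in \[0, 1\].
#' @param abortion_rate Fraction of seeds that abort, in \[0, 1).
#' @param marker_false_negative,marker_false_positive Screening error rates,
#'   in \[0, 1).
#' @param seed Integer RNG seed.
#' @return A `seed_lot_spec` list.
#' @export
seed_lot_spec <- function(n_seeds, true_hir, abortion_rate = 0,
                          marker_false_negative = 0,
                          marker_false_positive = 0, seed = 1L) {
  if (!is_count(n_seeds) || n_seeds <= 0) {
    stop_input("`n_seeds` must be a positive integer")
  }
  if (!is_prob(true_hir)) stop_input("`true_hir` must be in [0, 1]")
  for (nm in c("abortion_rate", "marker_false_negative",
               "marker_false_positive")) {
    v <- get(nm)
    if (!is_prob(v) || v >= 1) stop_input("`", nm, "` must be in [0, 1)")
  }
  structure(
    list(n_seeds = as.integer(n_seeds), true_hir = true_hir,
         abortion_rate = abortion_rate,
         marker_false_negative = marker_false_negative,
         marker_false_positive = marker_false_positive,
         seed = as.integer(seed)),
    class = "seed_lot_spec"
  )
}

#' Simulate one marker-screened seed lot
#'
#' Draws the lot's fate hierarchically: seeds abort with `abortion_rate`;
#' germinated seeds are truly haploid with `true_hir`; marker screening then
#' flips class labels with the specified error rates. The three observed
#' categories always sum to `n_seeds`.
#'
#' @param spec A [seed_lot_spec()].
#' @param cross_id Identifier carried into the output.
#' @return A [seed_screen_counts()] object.
#' @export
simulate_seed_lot <- function(spec, cross_id = "sim") {
  stopifnot(inherits(spec, "seed_lot_spec"))
  with_seed(spec$seed, {
    n_aborted <- stats::rbinom(1L, spec$n_seeds, spec$abortion_rate)
    n_germ <- spec$n_seeds - n_aborted
    n_hap_true <- stats::rbinom(1L, n_germ, spec$true_hir)
    n_dip_true <- n_germ - n_hap_true
    fn <- stats::rbinom(1L, n_hap_true, spec$marker_false_negative)
    fp <- stats::rbinom(1L, n_dip_true, spec$marker_false_positive)
    obs_hap <- n_hap_true - fn + fp
    seed_screen_counts(
      germinated_diploid = n_germ - obs_hap,
      germinated_haploid = obs_hap,
      ungerminated_aborted = n_aborted,
      cross_id = cross_id
    )
  })
}
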