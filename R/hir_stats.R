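# Haploid-induction-rate screening arithmetic: per-cross HIR with exact
# binomial intervals, cross averages, seed-set rates, and spontaneous
# chromosome-doubling categories.

#' Seed screening counts for one cross
#'
#' Category counts from marker screening of one seed lot: germinated seeds
#' scored diploid or haploid, plus ungerminated aborted seeds. Totals are
#' derived: `total_germinated = diploid + haploid`,
#' `total_seeds = total_germinated + aborted`.
#'
#' @param germinated_diploid,germinated_haploid,ungerminated_aborted
#'   Nonnegative integer counts.
#' @param cross_id Identifier for the cross.
#' @return A `seed_screen_counts` one-row data frame including the derived
#'   totals.
#' @export
seed_screen_counts <- function(germinated_diploid, germinated_haploid,
                               ungerminated_aborted, cross_id = NA_character_) {
  for (nm in c("germinated_diploid", "germinated_haploid",
               "ungerminated_aborted")) {
    if (!is_count(get(nm))) stop_input("`", nm, "` must be a nonnegative integer")
  }
  structure(
    data.frame(
      cross_id = as.character(cross_id),
      germinated_diploid = as.integer(germinated_diploid),
      germinated_haploid = as.integer(germinated_haploid),
      ungerminated_aborted = as.integer(ungerminated_aborted),
      total_germinated = as.integer(germinated_diploid + germinated_haploid),
      total_seeds = as.integer(germinated_diploid + germinated_haploid +
                                 ungerminated_aborted),
      stringsAsFactors = FALSE
    ),
    class = c("seed_screen_counts", "data.frame")
  )
}

#' Read a seed-screening count table
#'
#' CSV with one row per cross and columns `germinated_diploid`,
#' `germinated_haploid`, `ungerminated_aborted` plus an optional `cross_id`;
#' screening-table style column names ("Total germinated diploid seeds", ...)
#' are also recognized.
#'
#' @param path CSV path.
#' @return A `seed_screen_counts` data frame with one row per cross.
#' @export
read_seed_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canon <- function(x) gsub("[^a-z]", "", tolower(x))
  nm <- canon(names(df))
  find <- function(target) {
    hit <- which(nm == canon(target))
    if (length(hit) == 0L) stop_input("column `", target, "` not found in ", path)
    df[[hit[1L]]]
  }
  dip <- tryCatch(find("germinated_diploid"),
                  error = function(e) find("Total germinated diploid seeds"))
  hap <- tryCatch(find("germinated_haploid"),
                  error = function(e) find("Total germinated haploid seeds"))
  ab <- tryCatch(find("ungerminated_aborted"),
                 error = function(e) find("Total ungerminated aborted seeds"))
  id <- if (any(nm %in% canon(c("cross_id", "No. of crossings")))) {
    df[[which(nm %in% canon(c("cross_id", "No. of crossings")))[1L]]]
  } else {
    seq_len(nrow(df))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    seed_screen_counts(dip[i], hap[i], ab[i], cross_id = id[i])
  }))
  structure(out, class = c("seed_screen_counts", "data.frame"))
}

#' Haploid induction rate of one or more crosses
#'
#' HIR is the percentage of haploids among screened seeds; by default the
#' denominator is germinated seeds only (aborted seeds are excluded), the
#' convention of germination-stage screening tables. For embryo-stage
#' screening, where every dissected seed is scored, use
#' `denominator = "dissected"` to divide by total seeds instead. A 95%
#' Clopper-Pearson exact binomial interval is attached. Percentages are
#' rounded half-up to 2 decimals at report time only.
#'
#' @param counts A `seed_screen_counts` data frame (one or more rows).
#' @param denominator `"germinated"` (default) or `"dissected"`.
#' @param conf_level Confidence level for the exact interval (default 0.95).
#' @return A `hir_result` data frame with columns `cross_id`, `n_haploid`,
#'   `n_denominator`, `hir_percent`, `ci_low`, `ci_high` (percent).
#' @examples
#' compute_hir(seed_screen_counts(101, 25, 37))  # 19.84%
#' @export
compute_hir <- function(counts, denominator = c("germinated", "dissected"),
                        conf_level = 0.95) {
  stopifnot(is.data.frame(counts))
  denominator <- match.arg(denominator)
  n_hap <- counts$germinated_haploid
  n_den <- if (denominator == "germinated") {
    counts$germinated_diploid + counts$germinated_haploid
  } else {
    counts$germinated_diploid + counts$germinated_haploid +
      counts$ungerminated_aborted
  }
  if (any(n_den == 0L)) {
    stop_input("HIR undefined: zero seeds in the denominator for cross ",
               paste(counts$cross_id[n_den == 0L], collapse = ", "))
  }
  ci <- t(vapply(seq_along(n_hap), function(i) {
    stats::binom.test(n_hap[i], n_den[i], conf.level = conf_level)$conf.int
  }, c(0, 0)))
  structure(
    data.frame(
      cross_id = counts$cross_id %||% NA_character_,
      n_haploid = as.integer(n_hap),
      n_denominator = as.integer(n_den),
      hir_percent = round_half_up(100 * n_hap / n_den, 2L),
      ci_low = round_half_up(100 * ci[, 1L], 2L),
      ci_high = round_half_up(100 * ci[, 2L], 2L),
      stringsAsFactors = FALSE
    ),
    denominator = denominator,
    class = c("hir_result", "data.frame")
  )
}

#' Average HIR across crosses
#'
#' The unweighted arithmetic mean of the per-cross HIR percentages, computed
#' from the unrounded per-cross rates and rounded half-up to 2 decimals at
#' the end. (This is a mean of rates, not a pooled rate: crosses with
#' different lot sizes carry equal weight.)
#'
#' @param results A `hir_result` data frame from [compute_hir()].
#' @return The average HIR in percent (2 decimals).
#' @export
average_hir <- function(results) {
  stopifnot(inherits(results, "hir_result"))
  if (nrow(results) == 0L) stop_input("no HIR results to average")
  round_half_up(mean(100 * results$n_haploid / results$n_denominator), 2L)
}

#' Seed set rate
#'
#' Seeds formed per floret pollinated, as a percentage (2 decimals).
#'
#' @param seeds_set Nonnegative integer count of seeds formed.
#' @param florets Positive integer count of florets pollinated.
#' @return Percentage, rounded half-up to 2 decimals.
#' @examples
#' seed_set_rate(24, 97)  # 24.74
#' @export
seed_set_rate <- function(seeds_set, florets) {
  if (!is_count(seeds_set)) stop_input("`seeds_set` must be a nonnegative integer")
  if (!is_count(florets) || florets == 0) {
    stop_input("`florets` must be a positive integer")
  }
  round_half_up(100 * seeds_set / florets, 2L)
}

#' Spontaneous chromosome-doubling category
#'
#' Haploids are categorized by their selfed seed set: none (0%), low
#' (0.01 to 5%), medium (5 to 10%), and high (>10%). Boundaries are read as
#' right-inclusive: exactly 5% is low and exactly 10% is medium.
#'
#' @param seed_set_percent Seed set percentage(s), in \[0, 100\].
#' @return Factor over `none`, `low`, `medium`, `high`.
#' @examples
#' classify_doubling(c(0, 3, 7.3, 15))
#' @export
classify_doubling <- function(seed_set_percent) {
  x <- as.numeric(seed_set_percent)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    stop_input("`seed_set_percent` must be within [0, 100]")
  }
  out <- ifelse(x == 0, "none",
                ifelse(x <= 5, "low", ifelse(x <= 10, "medium", "high")))
  factor(out, levels = c("none", "low", "medium", "high"))
}

#' Validate the HIR estimator against the seed-lot simulator
#'
#' Simulates `replicates` independent seed lots under `spec`, estimates the
#' HIR of each, and summarizes estimator bias (mean estimated minus true HIR,
#' in percentage points) and the fraction of replicates whose exact interval
#' covers the truth.
#'
#' @param spec A [seed_lot_spec()]; its own `seed` field is ignored here.
#' @param replicates Number of simulated lots (>= 100).
#' @param seed Integer RNG seed for the whole check.
#' @return List with `bias_pp`, `coverage`, `mean_hir_percent`,
#'   `true_hir_percent`, and `replicates`.
#' @export
hir_recovery_check <- function(spec, replicates = 500L, seed = 1L) {
  stopifnot(inherits(spec, "seed_lot_spec"))
  if (!is_count(replicates) || replicates < 100L) {
    stop_input("`replicates` must be an integer >= 100")
  }
  lot_seeds <- with_seed(seed, {
    sample.int(.Machine$integer.max, replicates)
  })
  true_pct <- 100 * spec$true_hir
  est <- numeric(replicates)
  covered <- logical(replicates)
  for (i in seq_len(replicates)) {
    s <- spec
    s$seed <- lot_seeds[i]
    lot <- simulate_seed_lot(s, cross_id = sprintf("rep%04d", i))
    res <- compute_hir(lot)
    est[i] <- 100 * res$n_haploid / res$n_denominator
    covered[i] <- res$ci_low <= true_pct && true_pct <= res$ci_high
  }
  list(bias_pp = mean(est) - true_pct,
       coverage = mean(covered),
       mean_hir_percent = mean(est),
       true_hir_percent = true_pct,
       replicates = as.integer(replicates))
}
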