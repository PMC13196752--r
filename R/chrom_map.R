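#' Chromosome map
#'
#' A chromosome map is an ordered table of chromosome names and lengths (bp).
#' Its row order is the plotting and reporting order used by every downstream
#' binning and classification step.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#'
#' @return A `chrom_map` data frame with columns `chrom` and `length`.
#' @examples
#' chrom_map(c("Chr1", "Chr2"), c(1e6, 8e5))
#' @export
chrom_map <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    stop_input("`chrom` and `length` must have equal length")
  }
  if (anyDuplicated(chrom)) stop_input("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0) ||
      any(length != trunc(length))) {
    stop_input("chromosome lengths must be positive integers (bp)")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("chrom_map", "data.frame")
  )
}

#' @rdname chrom_map
#' @param x A data frame with columns `chrom` and `length` (or a two-column
#'   chrom-sizes table).
#' @export
as_chrom_map <- function(x) {
  if (inherits(x, "chrom_map")) return(x)
  if (!is.data.frame(x)) stop_input("cannot coerce to chrom_map")
  if (all(c("chrom", "length") %in% names(x))) {
    return(chrom_map(x$chrom, x$length))
  }
  if (ncol(x) >= 2L) return(chrom_map(x[[1L]], x[[2L]]))
  stop_input("cannot coerce to chrom_map: need chrom and length columns")
}

#' Default desk-scale chromosome map
#'
#' Ten chromosomes (Chr1 to Chr10) at one tenth of the sorghum BTx623 v3
#' assembly lengths, so whole-genome simulations stay small while preserving
#' realistic relative chromosome sizes. Supply a real chrom-sizes table via
#' [read_chrom_sizes()] to work at full scale.
#'
#' @return A `chrom_map` with 10 chromosomes totalling ~68 Mb.
#' @export
default_chrom_map <- function() {
  chrom_map(
    paste0("Chr", 1:10),
    c(8088000, 7774000, 7439000, 6866000, 7185000,
      6128000, 6551000, 6269000, 5942000, 6123000)
  )
}

#' Read a chromosome-sizes file
#'
#' Accepts the usual two-column `chrom.sizes` layout (name, length) or a
#' FASTA-index (`.fai`) style file whose first two columns are name and length.
#' Extra columns are ignored.
#'
#' @param path Path to a tab- or whitespace-separated file.
#' @return A [chrom_map].
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_input("chrom-sizes file needs at least 2 columns")
  chrom_map(tab[[1L]], tab[[2L]])
}

#' Partition a genome into nonoverlapping bins
#'
#' Tiles every chromosome with consecutive, nonoverlapping, half-open
#' `[start, end)` bins of `bin_width` bp (0-based coordinates, BED-like).
#' The final bin of each chromosome is truncated at the chromosome length.
#'
#' @param chrom_map A [chrom_map].
#' @param bin_width Bin width in bp (default 100,000).
#' @return Data frame with columns `chrom`, `start`, `end`, one row per bin,
#'   in genome order.
#' @examples
#' make_bins(chrom_map("Chr1", 250000))
#' @export
make_bins <- function(chrom_map, bin_width = 100000L) {
  chrom_map <- as_chrom_map(chrom_map)
  if (!is_count(bin_width) || bin_width <= 0) {
    stop_input("`bin_width` must be a positive integer")
  }
  bin_width <- as.numeric(bin_width)
  if (nrow(chrom_map) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  pieces <- lapply(seq_len(nrow(chrom_map)), function(i) {
    len <- chrom_map$length[i]
    starts <- seq(0, len - 1, by = bin_width)
    data.frame(
      chrom = chrom_map$chrom[i],
      start = starts,
      end = pmin(starts + bin_width, len),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}
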