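#' Define a genomic binning
#'
#' Partitions each chromosome into consecutive fixed-width bins. Bins are
#' 0-based half-open intervals `[start, start + bin_width)`, clipped at the
#' chromosome end, so the last bin of a chromosome may be shorter than
#' `bin_width`. Bins tile each chromosome without gaps or overlaps.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names; lengths must be positive).
#' @param bin_width Bin width in bp (positive integer-valued scalar).
#'
#' @return An object of class `genomic_binning` with elements
#'   `chrom_lengths`, `bin_width` and `n_bins` (bins per chromosome,
#'   `ceiling(length / bin_width)`).
#' @examples
#' gb <- genomic_binning(c(chr1 = 1e6, chr2 = 2.5e5), bin_width = 1e5)
#' gb$n_bins
#' @export
genomic_binning <- function(chrom_lengths, bin_width) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("`chrom_lengths` must be a named vector of chromosome lengths")
  }
  if (any(chrom_lengths <= 0) || any(chrom_lengths != round(chrom_lengths))) {
    stop("chromosome lengths must be positive integers (bp)")
  }
  if (length(bin_width) != 1L || bin_width <= 0 || bin_width != round(bin_width)) {
    stop("`bin_width` must be a single positive integer (bp)")
  }
  structure(
    list(
      chrom_lengths = chrom_lengths,
      bin_width = as.numeric(bin_width),
      n_bins = stats::setNames(
        as.integer(ceiling(chrom_lengths / bin_width)),
        names(chrom_lengths)
      )
    ),
    class = "genomic_binning"
  )
}

#' @export
print.genomic_binning <- function(x, ...) {
  cat(
    "<genomic_binning> ", length(x$chrom_lengths), " chromosome(s), bin width ",
    format(x$bin_width, big.mark = ","), " bp, ", sum(x$n_bins), " bins\n",
    sep = ""
  )
  invisible(x)
}

#' Bin table of a genomic binning
#'
#' @param x A `genomic_binning`.
#' @return A tibble with columns `chrom`, `bin` (0-based index within the
#'   chromosome), `start`, `end` (0-based half-open, bp).
#' @export
bin_table <- function(x) {
  stopifnot(inherits(x, "genomic_binning"))
  purrr::map_dfr(names(x$chrom_lengths), function(ch) {
    n <- x$n_bins[[ch]]
    start <- (seq_len(n) - 1) * x$bin_width
    tibble::tibble(
      chrom = ch,
      bin = seq_len(n) - 1L,
      start = start,
      end = pmin(start + x$bin_width, x$chrom_lengths[[ch]])
    )
  })
}

# 1-based genomic position -> 0-based bin index
pos_to_bin <- function(pos, bin_width) {
  as.integer((pos - 1) %/% bin_width)
}
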