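#' Construct a binned contact matrix
#'
#' Container for per-chromosome symmetric cis contact counts stored as the
#' upper triangle (`bin1 <= bin2`) of each chromosome's binned matrix,
#' together with optional iterative-correction weights and a record of how
#' many diagonals are masked. Trans (inter-chromosomal) binned counts are
#' carried along in a separate table but are not used by the contact
#' probability decay analysis, which is cis-only.
#'
#' @param binning A [genomic_binning()].
#' @param pixels Tibble with columns `chrom`, `bin1`, `bin2`, `count`
#'   (0-based chromosome-local bins, `bin1 <= bin2`, non-negative counts).
#' @param trans Optional tibble of trans counts with columns `chrom1`,
#'   `bin1`, `chrom2`, `bin2`, `count`.
#' @param weights Optional tibble with columns `chrom`, `bin`, `weight`
#'   (positive, or `NA` for bins flagged invalid during balancing).
#' @param n_masked_diagonals Number of leading diagonals (`|i - j| <
#'   n_masked_diagonals`) excluded from balancing and from all balanced
#'   queries.
#' @param converged Logical; whether iterative correction converged
#'   (`NA` for unbalanced matrices).
#'
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(binning, pixels,
                           trans = NULL,
                           weights = NULL,
                           n_masked_diagonals = 0L,
                           converged = NA) {
  stopifnot(inherits(binning, "genomic_binning"))
  pixels <- tibble::as_tibble(pixels)
  req <- c("chrom", "bin1", "bin2", "count")
  if (!all(req %in% names(pixels))) {
    stop("`pixels` must have columns chrom, bin1, bin2, count")
  }
  if (nrow(pixels)) {
    bad <- setdiff(unique(pixels$chrom), names(binning$chrom_lengths))
    if (length(bad)) stop("unknown chromosome in pixels: ", bad[1])
    if (any(pixels$count < 0) || any(!is.finite(pixels$count))) {
      stop("counts must be finite and non-negative")
    }
    if (any(pixels$bin1 > pixels$bin2)) {
      stop("pixels must be upper-triangle: bin1 <= bin2")
    }
    nb <- binning$n_bins[pixels$chrom]
    if (any(pixels$bin1 < 0) || any(pixels$bin2 >= nb)) {
      stop("bin index outside chromosome")
    }
  }
  if (is.null(trans)) {
    trans <- tibble::tibble(
      chrom1 = character(), bin1 = integer(),
      chrom2 = character(), bin2 = integer(), count = numeric()
    )
  }
  structure(
    list(
      pixels = pixels,
      binning = binning,
      trans = tibble::as_tibble(trans),
      weights = weights,
      n_masked_diagonals = as.integer(n_masked_diagonals),
      converged = converged
    ),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", length(x$binning$chrom_lengths), " chromosome(s), ",
    format(x$binning$bin_width, big.mark = ","), " bp bins, ",
    format(sum(x$pixels$count), big.mark = ","), " cis contacts",
    if (!is.null(x$weights)) " (balanced)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Total cis contact count
#' @param x A `contact_matrix`.
#' @return Numeric scalar.
#' @export
total_contacts <- function(x) {
  stopifnot(inherits(x, "contact_matrix"))
  sum(x$pixels$count)
}

#' Dense per-chromosome matrix
#'
#' Expands the stored upper triangle of one chromosome into a full symmetric
#' matrix of raw counts.
#'
#' @param x A `contact_matrix`.
#' @param chrom Chromosome name; defaults to the first chromosome.
#' @return A symmetric numeric matrix.
#' @export
as_dense_matrix <- function(x, chrom = NULL) {
  stopifnot(inherits(x, "contact_matrix"))
  if (is.null(chrom)) chrom <- names(x$binning$chrom_lengths)[1]
  if (!chrom %in% names(x$binning$chrom_lengths)) {
    stop("unknown chromosome: ", chrom)
  }
  n <- x$binning$n_bins[[chrom]]
  m <- matrix(0, n, n)
  px <- x$pixels[x$pixels$chrom == chrom, ]
  if (nrow(px)) {
    m[cbind(px$bin1 + 1L, px$bin2 + 1L)] <- px$count
    m[cbind(px$bin2 + 1L, px$bin1 + 1L)] <- px$count
  }
  m
}

# aggregate a cis pair tibble (chrom, pos1, pos2; 1-based bp) into pixels;
# tallied per chromosome on an encoded bin-pair key (sort + rle), which is
# much faster than grouped counting for deep pair lists
bin_cis_pairs <- function(pairs, binning) {
  bw <- binning$bin_width
  purrr::map_dfr(sort(unique(pairs$chrom)), function(ch) {
    sel <- pairs$chrom == ch
    b1 <- pos_to_bin(pairs$pos1[sel], bw)
    b2 <- pos_to_bin(pairs$pos2[sel], bw)
    lo <- pmin(b1, b2)
    hi <- pmax(b1, b2)
    nb <- as.numeric(binning$n_bins[[ch]])
    r <- rle(sort(lo * nb + hi))
    tibble::tibble(
      chrom = ch,
      bin1 = as.integer(r$values %/% nb),
      bin2 = as.integer(r$values %% nb),
      count = as.numeric(r$lengths)
    )
  })
}
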