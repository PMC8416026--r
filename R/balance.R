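#' Iterative correction (ICE) balancing of a contact matrix
#'
#' Equalizes per-bin marginals by iterative correction: each chromosome's
#' matrix entries are repeatedly divided by the product of their row and
#' column marginal factors until the variance of the nonzero scaled
#' marginals falls below `tol` or `max_iter` is reached. The first
#' `n_masked_diagonals` diagonals (`|i - j| < n_masked_diagonals`) are
#' excluded from the marginals and from all balanced output, which removes
#' short-range artifacts such as re-ligation products near the main
#' diagonal. Bins with zero marginal are flagged invalid (`NA` weight).
#'
#' @param m A [contact_matrix()] (unbalanced).
#' @param n_masked_diagonals Number of leading diagonals to mask
#'   (default 2: the main diagonal and the first off-diagonal).
#' @param tol Convergence tolerance on the variance of nonzero scaled
#'   marginals.
#' @param max_iter Maximum number of iterations.
#' @return A `contact_matrix` with a `weights` table such that the balanced
#'   value of entry `(i, j)` is `count * w_i * w_j`; `converged` records
#'   whether all chromosomes converged. A warning is raised on
#'   non-convergence.
#' @export
balance_matrix <- function(m, n_masked_diagonals = 2L, tol = 1e-5,
                           max_iter = 200L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (n_masked_diagonals < 0) stop("`n_masked_diagonals` must be >= 0")
  chroms <- names(m$binning$chrom_lengths)
  all_conv <- TRUE
  weights <- purrr::map_dfr(chroms, function(ch) {
    n <- m$binning$n_bins[[ch]]
    px <- m$pixels[m$pixels$chrom == ch, ]
    keep <- (px$bin2 - px$bin1) >= n_masked_diagonals
    px <- px[keep, ]
    b <- rep(1, n)
    conv <- FALSE
    if (nrow(px)) {
      i1 <- px$bin1 + 1L
      i2 <- px$bin2 + 1L
      diag_px <- i1 == i2
      for (iter in seq_len(max_iter)) {
        val <- px$count / (b[i1] * b[i2])
        marg <- as.numeric(tapply_sum(i1, val, n)) +
          as.numeric(tapply_sum(i2, val[!diag_px], n, subset = !diag_px))
        nz <- marg > 0
        if (!any(nz)) break
        scaled <- marg / mean(marg[nz])
        if (stats::var(scaled[nz]) < tol) {
          conv <- TRUE
          break
        }
        b[nz] <- b[nz] * scaled[nz]
      }
      val <- px$count / (b[i1] * b[i2])
      marg <- as.numeric(tapply_sum(i1, val, n)) +
        as.numeric(tapply_sum(i2, val[!diag_px], n, subset = !diag_px))
      nz <- marg > 0
    } else {
      nz <- rep(FALSE, n)
    }
    if (!conv) all_conv <<- FALSE
    w <- ifelse(nz, 1 / b, NA_real_)
    tibble::tibble(chrom = ch, bin = seq_len(n) - 1L, weight = w)
  })
  if (!all_conv) {
    warning("iterative correction did not converge within ", max_iter,
      " iterations",
      call. = FALSE
    )
  }
  out <- m
  out$weights <- weights
  out$n_masked_diagonals <- as.integer(n_masked_diagonals)
  out$converged <- all_conv
  out
}

# sum `val` by integer index 1..n (optionally using a subset of the rows)
tapply_sum <- function(idx, val, n, subset = NULL) {
  if (!is.null(subset)) idx <- idx[subset]
  out <- numeric(n)
  if (!length(idx)) return(out)
  tmp <- rowsum(val, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

#' Balanced marginals of a contact matrix
#'
#' Recomputes per-bin marginals of the balanced matrix (masked diagonals
#' excluded), mainly for convergence checks.
#'
#' @param m A balanced [contact_matrix()].
#' @return A tibble with columns `chrom`, `bin`, `marginal` (`NA` for
#'   invalid bins).
#' @export
balanced_marginals <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (is.null(m$weights)) stop("matrix is not balanced")
  purrr::map_dfr(names(m$binning$chrom_lengths), function(ch) {
    n <- m$binning$n_bins[[ch]]
    w <- m$weights$weight[m$weights$chrom == ch]
    px <- m$pixels[m$pixels$chrom == ch, ]
    px <- px[(px$bin2 - px$bin1) >= m$n_masked_diagonals, ]
    i1 <- px$bin1 + 1L
    i2 <- px$bin2 + 1L
    val <- px$count * w[i1] * w[i2]
    ok <- !is.na(val)
    marg <- tapply_sum(i1[ok], val[ok], n) +
      tapply_sum(i2[ok & i1 != i2], val[ok & i1 != i2], n)
    marg[is.na(w)] <- NA_real_
    tibble::tibble(chrom = ch, bin = seq_len(n) - 1L, marginal = marg)
  })
}
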