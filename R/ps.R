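#' Geometric (log-spaced) distance binning scheme
#'
#' Bin edges are geometric: `e_k = s_min * 10^(k / bins_per_decade)`,
#' truncated so the last edge equals `s_max`. Used to aggregate contact
#' separations for the contact probability decay curve P(s).
#'
#' @param s_min Smallest separation (bp). Default 1 kb.
#' @param s_max Largest separation (bp). Default 100 Mb.
#' @param bins_per_decade Number of log bins per decade of genomic distance.
#' @return A tibble of class `log_bin_scheme` with columns `s_lo`, `s_hi`
#'   (half-open `[s_lo, s_hi)`).
#' @export
log_bin_scheme <- function(s_min = 1e3, s_max = 1e8, bins_per_decade = 8L) {
  stopifnot(s_min > 0, s_max > s_min, bins_per_decade >= 1)
  k_max <- ceiling(bins_per_decade * log10(s_max / s_min) - 1e-9)
  edges <- s_min * 10^((0:k_max) / bins_per_decade)
  edges[k_max + 1] <- min(edges[k_max + 1], s_max)
  out <- tibble::tibble(s_lo = edges[-(k_max + 1)], s_hi = edges[-1])
  class(out) <- c("log_bin_scheme", class(out))
  attr(out, "bins_per_decade") <- bins_per_decade
  out
}

#' Contact probability decay curve P(s)
#'
#' Computes the genome-wide average contact probability as a function of
#' genomic separation `s`. Within each log-spaced distance bin, the observed
#' number of interactions is divided by the total possible number of locus
#' pairs at those separations, pooled over chromosomes before dividing; the
#' curve is then normalized by the total number of interactions so that
#' curves from different sequencing depths are directly comparable.
#'
#' For matrix input the separation of element `(i, j)` is
#' `(j - i) * bin_width` and the possible-pair count is the number of matrix
#' elements at those offsets (restricted to bins with valid balancing
#' weights when `use_weights = TRUE`). For pair input the possible-pair
#' count at bp resolution is `sum over chromosomes c and integer s in the
#' bin of (length_c - s)`. Each bin's representative separation `s_mid` is
#' the possible-pair-weighted geometric mean of the separations it
#' contains, which keeps the log-log slope free of discretization ripple.
#'
#' @param x A [contact_matrix()], or a pair tibble from [read_pairs()].
#' @param scheme A [log_bin_scheme()].
#' @param use_weights For matrix input, use balancing weights (balanced
#'   value `count * w_i * w_j`)? Defaults to `TRUE` when weights are
#'   present.
#' @param per_chromosome If `TRUE`, return one curve per chromosome instead
#'   of the genome-wide pooled curve.
#' @param chrom_lengths Chromosome lengths for pair input lacking a
#'   `chrom_lengths` attribute.
#' @return A tibble of class `ps_curve` with columns `s_lo`, `s_hi`, `s_mid`,
#'   `n_obs` (observed interaction weight), `n_possible` (possible pair
#'   count), `p` (normalized contact probability) and `valid`
#'   (`n_possible > 0`); attribute `total` holds the normalization constant.
#' @export
compute_ps <- function(x, scheme = log_bin_scheme(), use_weights = NULL,
                       per_chromosome = FALSE, chrom_lengths = NULL) {
  UseMethod("compute_ps")
}

#' @export
compute_ps.contact_matrix <- function(x, scheme = log_bin_scheme(),
                                      use_weights = NULL,
                                      per_chromosome = FALSE,
                                      chrom_lengths = NULL) {
  if (is.null(use_weights)) use_weights <- !is.null(x$weights)
  if (use_weights && is.null(x$weights)) {
    stop("`use_weights = TRUE` but the matrix has no balancing weights")
  }
  bw <- x$binning$bin_width
  if (min(scheme$s_lo) < bw) {
    warning("scheme extends below the bin width (", bw,
      " bp); distance bins without matrix elements are flagged invalid",
      call. = FALSE
    )
  }
  chroms <- names(x$binning$chrom_lengths)
  acc <- purrr::map(chroms, function(ch) {
    n <- x$binning$n_bins[[ch]]
    px <- x$pixels[x$pixels$chrom == ch, ]
    d <- px$bin2 - px$bin1
    keep <- d >= max(1L, x$n_masked_diagonals)
    px <- px[keep, ]
    d <- d[keep]
    if (use_weights) {
      w <- x$weights$weight[x$weights$chrom == ch]
      val <- px$count * w[px$bin1 + 1L] * w[px$bin2 + 1L]
      ok <- !is.na(val)
      obs_d <- tapply_sum(d[ok], val[ok], n - 1L)
      vmask <- !is.na(w)
      poss_d <- offset_pair_counts(vmask)
    } else {
      obs_d <- tapply_sum(d, px$count, n - 1L)
      poss_d <- (n - 1L):1
    }
    dd <- seq_len(n - 1L)
    dmin <- max(1L, x$n_masked_diagonals)
    poss_d[dd < dmin] <- 0
    list(s = dd * bw, obs = obs_d, poss = as.numeric(poss_d), chrom = ch)
  })
  if (per_chromosome) {
    purrr::map_dfr(acc, function(a) {
      dplyr::mutate(
        aggregate_ps(list(a), scheme),
        chrom = a$chrom, .before = 1
      )
    })
  } else {
    aggregate_ps(acc, scheme)
  }
}

#' @export
compute_ps.data.frame <- function(x, scheme = log_bin_scheme(),
                                  use_weights = NULL,
                                  per_chromosome = FALSE,
                                  chrom_lengths = NULL) {
  lens <- chrom_lengths %||% attr(x, "chrom_lengths")
  if (is.null(lens)) {
    stop("pair input needs chromosome lengths (`chrom_lengths`)")
  }
  cis <- x[x$chrom1 == x$chrom2, ]
  if (per_chromosome) {
    return(purrr::map_dfr(unique(cis$chrom1), function(ch) {
      sub <- cis[cis$chrom1 == ch, ]
      attr(sub, "chrom_lengths") <- lens[ch]
      dplyr::mutate(
        compute_ps.data.frame(sub, scheme, chrom_lengths = lens[ch]),
        chrom = ch, .before = 1
      )
    }))
  }
  s <- abs(cis$pos2 - cis$pos1)
  edges <- c(scheme$s_lo, scheme$s_hi[nrow(scheme)])
  k <- findInterval(s, edges, rightmost.closed = FALSE)
  k[s >= edges[length(edges)]] <- 0L # beyond the last edge
  obs <- tabulate(k, nbins = nrow(scheme))
  poss <- possible_pairs_bp(scheme, lens)
  tot <- sum(obs)
  p <- ifelse(poss$n > 0, obs / poss$n, NA_real_)
  out <- tibble::tibble(
    s_lo = scheme$s_lo, s_hi = scheme$s_hi, s_mid = poss$s_rep,
    n_obs = as.numeric(obs), n_possible = poss$n,
    p = p / max(tot, 1),
    valid = poss$n > 0
  )
  class(out) <- c("ps_curve", class(out))
  attr(out, "total") <- tot
  out
}

# number of valid element pairs at each offset d = 1..n-1, via FFT
# autocorrelation of the validity mask
offset_pair_counts <- function(vmask) {
  n <- length(vmask)
  if (all(vmask)) return(as.numeric((n - 1L):1))
  v <- as.numeric(vmask)
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(v, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
  round(ac[2:n])
}

aggregate_ps <- function(acc, scheme) {
  edges <- c(scheme$s_lo, scheme$s_hi[nrow(scheme)])
  nb <- nrow(scheme)
  O <- N <- LS <- numeric(nb)
  for (a in acc) {
    k <- findInterval(a$s, edges, rightmost.closed = FALSE)
    k[a$s >= edges[length(edges)]] <- 0L
    sel <- k >= 1L
    if (!any(sel)) next
    kk <- k[sel]
    O <- O + tapply_sum(kk, a$obs[sel], nb)
    N <- N + tapply_sum(kk, a$poss[sel], nb)
    LS <- LS + tapply_sum(kk, a$poss[sel] * log10(a$s[sel]), nb)
  }
  s_rep <- ifelse(N > 0, 10^(LS / N), sqrt(scheme$s_lo * scheme$s_hi))
  tot <- sum(O)
  out <- tibble::tibble(
    s_lo = scheme$s_lo, s_hi = scheme$s_hi, s_mid = s_rep,
    n_obs = O, n_possible = N,
    p = ifelse(N > 0, O / N / max(tot, 1), NA_real_),
    valid = N > 0
  )
  class(out) <- c("ps_curve", class(out))
  attr(out, "total") <- tot
  out
}

# bp-resolution possible pair counts per distance bin:
# N_k = sum_c sum_{s in [s_lo, s_hi), s integer} (len_c - s)
possible_pairs_bp <- function(scheme, lens) {
  n <- numeric(nrow(scheme))
  ls <- numeric(nrow(scheme))
  for (k in seq_len(nrow(scheme))) {
    a <- ceiling(scheme$s_lo[k])
    b <- ceiling(scheme$s_hi[k]) - 1
    nk <- 0
    lsk <- 0
    for (len in lens) {
      bb <- min(b, len - 1)
      if (bb < a) next
      cnt <- bb - a + 1
      nk <- nk + cnt * len - (a + bb) * cnt / 2
      # log-mean separation: moderate quadrature over the bin
      sg <- exp(seq(log(a), log(bb + 1), length.out = 33))
      wgt <- pmax(len - sg, 0) * sg # d s = s d(log s)
      lsk <- lsk + sum(wgt * log10(sg)) / sum(wgt) *
        (cnt * len - (a + bb) * cnt / 2)
    }
    n[k] <- nk
    ls[k] <- lsk
  }
  list(n = n, s_rep = ifelse(n > 0, 10^(ls / n), sqrt(scheme$s_lo * scheme$s_hi)))
}

#' Log-log derivative of a P(s) curve
#'
#' Computes the raw slope `d log10 P / d log10 s` by central differences on
#' valid bins, and a smoothed slope by locally weighted linear regression
#' (tricube weights, degree 1) with bandwidth `span` in log10(s) units.
#' Loop- and layer-size estimation uses the smoothed slope; the raw slope is
#' kept for diagnostics.
#'
#' @param p A `ps_curve` (or any tibble with `s_mid`, `p`, `valid`).
#' @param span Smoothing bandwidth: the tricube kernel's half-width in
#'   decades of genomic distance.
#' @return A tibble of class `deriv_curve` with columns `s_mid`,
#'   `slope_raw`, `slope_smooth`; attribute `span`.
#' @export
ps_derivative <- function(p, span = 0.3) {
  ok <- p$valid & !is.na(p$p) & p$p > 0
  if (sum(ok) < 3) stop("need at least 3 valid P(s) bins to differentiate")
  x <- log10(p$s_mid[ok])
  y <- log10(p$p[ok])
  n <- length(x)
  lo <- c(1L, 1:(n - 1L))
  hi <- c(2:n, n)
  slope <- (y[hi] - y[lo]) / (x[hi] - x[lo])
  smooth <- tricube_smooth(x, slope, x, h = span)
  out <- tibble::tibble(s_mid = 10^x, slope_raw = slope, slope_smooth = smooth)
  class(out) <- c("deriv_curve", class(out))
  attr(out, "span") <- span
  out
}

# local linear regression with tricube weights, bandwidth h (in x units)
tricube_smooth <- function(x, y, xout, h) {
  vapply(xout, function(x0) {
    u <- abs(x - x0) / h
    w <- ifelse(u < 1, (1 - u^3)^3, 0)
    if (sum(w > 0) < 3) {
      # widen to the 3 nearest points so the fit stays defined at the edges
      h3 <- sort(abs(x - x0))[min(3L, length(x))] * 1.001
      u <- abs(x - x0) / max(h3, h)
      w <- ifelse(u < 1, (1 - u^3)^3, 1e-9)
    }
    xm <- x - x0
    sw <- sum(w)
    sx <- sum(w * xm)
    sxx <- sum(w * xm^2)
    sy <- sum(w * y)
    sxy <- sum(w * xm * y)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-300) sy / sw else (sxx * sy - sx * sxy) / det
  }, numeric(1))
}

smoothed_on_grid <- function(d, lo, hi, ngrid = 400) {
  x <- log10(d$s_mid)
  xl <- max(log10(lo), min(x))
  xh <- min(log10(hi), max(x))
  if (xh <= xl) stop("no valid derivative points inside the search window")
  xs <- seq(xl, xh, length.out = ngrid)
  list(x = xs, y = tricube_smooth(x, d$slope_raw, xs, h = attr(d, "span") %||% 0.3))
}

#' Loop size from the derivative peak
#'
#' The average loop size is estimated as the genomic distance at the
#' maximum of the smoothed log-log slope of P(s) within the search window
#' (ties broken toward smaller `s`). A flatness diagnostic is raised when
#' the peak barely rises above the window's median slope, as happens for
#' chromosomes with broad loop-size distributions.
#'
#' @param d A `deriv_curve` from [ps_derivative()].
#' @param search_lo,search_hi Search window in bp (default 10 kb to 1 Mb,
#'   the range in which the derivative peak of mitotic chromosomes falls).
#' @param flat_eps Flatness threshold: flag the peak flat when
#'   `max - median` of the smoothed slope inside the window is below this.
#' @return A one-row tibble: `loop_size` (bp), `peak_slope`, `flat_peak`,
#'   `at_boundary`.
#' @export
estimate_loop_size <- function(d, search_lo = 1e4, search_hi = 1e6,
                               flat_eps = 0.02) {
  g <- smoothed_on_grid(d, search_lo, search_hi)
  # first index among near-maximal values: ties break toward smaller s
  i <- which(g$y >= max(g$y) - 1e-9)[1]
  tibble::tibble(
    loop_size = 10^g$x[i],
    peak_slope = g$y[i],
    flat_peak = (g$y[i] - stats::median(g$y)) < flat_eps,
    at_boundary = i == 1L || i == length(g$y)
  )
}

#' Layer size from the derivative drop
#'
#' The amount of DNA per radial layer of loops is estimated as the genomic
#' distance at the minimum of the smoothed log-log slope within the search
#' window: the point of steepest decay of P(s), marking the sharp drop in
#' contact probability between loci on different layers. A minimum at the
#' window boundary is flagged unreliable (no interior drop detected).
#'
#' @param d A `deriv_curve` from [ps_derivative()].
#' @param search_lo,search_hi Search window in bp (default 1 Mb to 100 Mb).
#' @return A one-row tibble: `layer_size` (bp), `drop_slope`, `at_boundary`.
#' @export
estimate_layer_size <- function(d, search_lo = 1e6, search_hi = 1e8) {
  g <- smoothed_on_grid(d, search_lo, search_hi)
  i <- which(g$y <= min(g$y) + 1e-9)[1]
  tibble::tibble(
    layer_size = 10^g$x[i],
    drop_slope = g$y[i],
    at_boundary = i == 1L || i == length(g$y)
  )
}

#' Joint loop/layer estimate from a derivative curve
#'
#' Convenience wrapper running [estimate_loop_size()] and
#' [estimate_layer_size()] and deriving the number of loops per layer
#' `n = layer_size / loop_size`.
#'
#' @inheritParams estimate_loop_size
#' @param loop_window,layer_window Length-2 numeric search windows (bp).
#' @return A one-row tibble of class `loop_layer_estimate` with columns
#'   `loop_size`, `layer_size`, `loops_per_layer`, `peak_slope`,
#'   `drop_slope`, `flat_peak`, `loop_at_boundary`, `layer_at_boundary`.
#' @export
estimate_loop_layer <- function(d, loop_window = c(1e4, 1e6),
                                layer_window = c(1e6, 1e8),
                                flat_eps = 0.02) {
  le <- estimate_loop_size(d, loop_window[1], loop_window[2], flat_eps)
  de <- estimate_layer_size(d, layer_window[1], layer_window[2])
  out <- tibble::tibble(
    loop_size = le$loop_size,
    layer_size = de$layer_size,
    loops_per_layer = de$layer_size / le$loop_size,
    peak_slope = le$peak_slope,
    drop_slope = de$drop_slope,
    flat_peak = le$flat_peak,
    loop_at_boundary = le$at_boundary,
    layer_at_boundary = de$at_boundary
  )
  class(out) <- c("loop_layer_estimate", class(out))
  out
}

#' Loops per layer
#'
#' @param e A `loop_layer_estimate` (or any list with `loop_size` and
#'   `layer_size`).
#' @return `layer_size / loop_size` (dimensionless).
#' @export
loops_per_layer <- function(e) {
  if (is.null(e$loop_size) || is.null(e$layer_size) ||
    is.na(e$loop_size) || is.na(e$layer_size)) {
    stop("both loop_size and layer_size must be available")
  }
  unname(e$layer_size / e$loop_size)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.loop_layer_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("loop_size", "layer_size", "loops_per_layer"),
    estimate = c(x$loop_size, x$layer_size, x$loops_per_layer),
    unit = c("bp", "bp", "loops")
  )
}

#' @export
glance.loop_layer_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
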