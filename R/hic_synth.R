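#' Loop-layer contact decay model for rod-shaped mitotic chromosomes
#'
#' Defines the three-regime expected contact decay P*(s) of a mitotic
#' chromosome organized as layers of chromatin loops stacked along a rod
#' axis: an intra-loop regime (exponent `alpha_loop`) up to the mean loop
#' size `L`, an intra-layer regime (`alpha_layer`) between `L` and the
#' layer size `D`, and a steep inter-layer regime (`alpha_inter`) beyond
#' `D`. The model is specified through its log-log slope profile, which
#' attains `-alpha_loop` at its local maximum at `s = L` (the derivative
#' peak used for loop-size estimation), sits at `-alpha_layer` across the
#' intra-layer plateau, and dips to `-alpha_inter` at `s = D` (the
#' derivative drop used for layer-size estimation), recovering towards the
#' plateau beyond the drop as observed in mitotic Hi-C derivative curves.
#' A steeper short-range regime below the fiber scale `s_fiber` mimics
#' chromatin-fiber contact decay at sub-loop distances.
#'
#' With `loop_variation = "exponential"`, individual loop sizes follow an
#' exponential distribution with mean `L` (floored at `loop_floor`), and a
#' layer aggregates `loops_per_layer` consecutive loops so the layer size
#' follows the corresponding Gamma distribution. The slope peak and dip are
#' broadened by the log-scale densities of these distributions — producing
#' the flattened derivative peak characteristic of chromosomes with a broad
#' loop-size distribution — while remaining centered at `L` and `D`. With
#' `loop_variation = "fixed"` the knees are sharp triangular features of
#' half-widths `peak_width` and `drop_width` (decades).
#'
#' When all three exponents are equal the profile degenerates to a single
#' power law with slope `-alpha_loop` everywhere.
#'
#' @param loop_size Mean loop size `L` in bp.
#' @param loops_per_layer Loops per layer `n` (>= 1; layer size `D = n * L`
#'   unless `layer_size` is given).
#' @param layer_size Optional layer size `D` in bp; overrides
#'   `loops_per_layer` (which is then derived as `D / L`).
#' @param alpha_loop,alpha_layer,alpha_inter Regime decay exponents; must
#'   satisfy `alpha_loop <= alpha_layer <= alpha_inter`.
#' @param chrom_lengths Named chromosome lengths (bp). Default: one
#'   synthetic 100 Mb chromosome.
#' @param loop_variation `"exponential"` (default) or `"fixed"`.
#' @param loop_floor Minimum loop size (bp) for the exponential draw.
#' @param s_fiber Fiber scale (bp): upper end of the steep short-range
#'   regime.
#' @param peak_width,drop_width Triangular half-widths (decades) of the
#'   slope peak and dip before broadening.
#' @param ramp Steepness coefficient of the short-range regime: the slope
#'   at `s_min` is `-alpha_loop - ramp * (alpha_inter - alpha_loop)`.
#' @param s_min Smallest modeled separation (bp).
#' @return An object of class `loop_layer_model`.
#' @export
loop_layer_model <- function(loop_size = 140e3, loops_per_layer = 40,
                             layer_size = NULL,
                             alpha_loop = 0.5, alpha_layer = 0.6,
                             alpha_inter = 3.0,
                             chrom_lengths = c(chrSim = 1e8),
                             loop_variation = c("exponential", "fixed"),
                             loop_floor = 5e3, s_fiber = 1e4,
                             peak_width = 0.35, drop_width = 0.35,
                             ramp = 0.4, s_min = 1e3) {
  loop_variation <- match.arg(loop_variation)
  if (loop_size <= 0) stop("`loop_size` must be positive")
  if (!(alpha_loop <= alpha_layer && alpha_layer <= alpha_inter)) {
    stop("exponents must satisfy alpha_loop <= alpha_layer <= alpha_inter")
  }
  if (!all(is.finite(c(alpha_loop, alpha_layer, alpha_inter)))) {
    stop("non-normalizable exponent combination")
  }
  if (is.null(layer_size)) {
    if (loops_per_layer < 1) stop("`loops_per_layer` must be >= 1")
    layer_size <- loops_per_layer * loop_size
  } else {
    loops_per_layer <- layer_size / loop_size
    if (loops_per_layer < 1) stop("`layer_size` must be >= `loop_size`")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chrSim", seq_along(chrom_lengths))
  }
  structure(
    list(
      loop_size = loop_size, layer_size = layer_size,
      loops_per_layer = loops_per_layer,
      alpha_loop = alpha_loop, alpha_layer = alpha_layer,
      alpha_inter = alpha_inter,
      chrom_lengths = chrom_lengths,
      loop_variation = loop_variation, loop_floor = loop_floor,
      s_fiber = s_fiber, peak_width = peak_width, drop_width = drop_width,
      ramp = ramp, s_min = s_min
    ),
    class = "loop_layer_model"
  )
}

#' @export
print.loop_layer_model <- function(x, ...) {
  cat(sprintf(
    "<loop_layer_model> loop %s kb, layer %s Mb (%.3g loops/layer), %s loops\n",
    format(x$loop_size / 1e3), format(x$layer_size / 1e6),
    x$loops_per_layer, x$loop_variation
  ))
  invisible(x)
}

# unit-peak shape broadened by a log10-scale kernel density, re-centered so
# its maximum sits exactly at u = 0
broadened_shape <- function(u, half_width, kernel_density, du = 0.005) {
  ug <- seq(-4, 4, by = du)
  kv <- kernel_density(ug)
  kv <- kv / sum(kv)
  xs <- seq(min(u, -1) - 4, max(u, 1) + 4, by = du)
  base <- pmax(0, 1 - abs(xs) / half_width)
  conv <- stats::convolve(base, rev(kv), type = "open")
  xc <- seq(xs[1] + ug[1], by = du, length.out = length(conv))
  shift <- xc[which.max(conv)]
  conv <- conv / max(conv)
  stats::approx(xc - shift, conv, xout = u, rule = 2)$y
}

#' Log-log slope profile of a loop-layer model
#'
#' @param model A [loop_layer_model()].
#' @param s Separations (bp) at which to evaluate the slope
#'   `d log10 P* / d log10 s`.
#' @return Numeric vector of slopes.
#' @export
model_slope <- function(model, s) {
  x <- log10(s)
  aL <- -model$alpha_loop
  aY <- -model$alpha_layer
  aD <- -model$alpha_inter
  a0 <- aL - model$ramp * (model$alpha_inter - model$alpha_loop)
  x0 <- log10(model$s_min)
  xF <- log10(model$s_fiber)
  xL <- log10(model$loop_size)
  xD <- log10(model$layer_size)
  g <- ifelse(x < xF, a0 + (aY - a0) * (x - x0) / max(xF - x0, 1e-9), aY)
  if (model$loop_variation == "exponential") {
    umin <- log10(model$loop_floor / model$loop_size)
    kl <- function(u) {
      ifelse(u > umin, log(10) * 10^u * exp(-10^u), 0)
    }
    nl <- model$loops_per_layer
    kd <- function(u) log(10) * 10^u * stats::dgamma(10^u, shape = nl, rate = nl)
    bump <- broadened_shape(x - xL, model$peak_width, kl)
    dip <- broadened_shape(x - xD, model$drop_width, kd)
  } else {
    tri <- function(t) pmax(0, 1 - abs(t))
    bump <- tri((x - xL) / model$peak_width)
    dip <- tri((x - xD) / model$drop_width)
  }
  g + (aL - aY) * bump + (aD - aY) * dip
}

# cumulative log10 P* on a fine log-spaced grid up to x1 = log10(max s)
model_logp_grid <- function(model, x1, n = 2001) {
  x0 <- log10(model$s_min)
  x <- seq(x0, x1, length.out = n)
  g <- model_slope(model, 10^x)
  dx <- diff(x)
  logp <- c(0, cumsum((g[-1] + g[-n]) / 2 * dx))
  list(x = x, logp = logp)
}

#' Expected P(s) curve of a loop-layer model
#'
#' Integrates the analytic decay P*(s) over each distance bin of the
#' scheme. The `mass` column is the probability mass per bin (normalized to
#' sum to 1 over the scheme's range); `p` is the corresponding mean density
#' over the bin, directly comparable in shape to a depth-normalized
#' [compute_ps()] curve.
#'
#' @param model A [loop_layer_model()].
#' @param scheme A [log_bin_scheme()].
#' @return A tibble of class `ps_curve` with columns `s_lo`, `s_hi`,
#'   `s_mid`, `p`, `mass`, `valid`.
#' @export
expected_ps <- function(model, scheme = log_bin_scheme()) {
  s_max <- max(scheme$s_hi)
  grid <- model_logp_grid(model, log10(s_max), n = 4001)
  s <- 10^grid$x
  dens <- 10^(grid$logp - max(grid$logp)) # unnormalized density in s
  # mass density per unit log10 s, integrated to a cumulative curve that is
  # then read off at the exact bin edges
  f <- dens * s * log(10)
  dx <- grid$x[2] - grid$x[1]
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dx))
  edges <- c(scheme$s_lo, scheme$s_hi[nrow(scheme)])
  cum_at <- stats::approx(grid$x, cum, xout = log10(edges), rule = 2)$y
  mass <- diff(cum_at)
  mass <- mass / sum(mass)
  width <- scheme$s_hi - scheme$s_lo
  out <- tibble::tibble(
    s_lo = scheme$s_lo, s_hi = scheme$s_hi,
    s_mid = sqrt(scheme$s_lo * scheme$s_hi),
    n_obs = NA_real_, n_possible = NA_real_,
    p = mass / width,
    mass = mass,
    valid = TRUE
  )
  class(out) <- c("ps_curve", class(out))
  out
}

#' Sample a synthetic contact map from a loop-layer model
#'
#' Draws `depth` cis contacts: separations are drawn from the model's decay
#' P*(s) weighted by the number of genomic positions admitting each
#' separation (inverse-CDF sampling on a fine log-spaced grid), and the
#' pair's position is uniform along the chromosome. Contacts are aggregated
#' into a [contact_matrix()] at `bin_width`. Chromosomes receive contacts
#' in proportion to their total admissible weight.
#'
#' @param model A [loop_layer_model()].
#' @param depth Total number of contacts to draw.
#' @param bin_width Aggregation bin width (bp).
#' @param seed Optional integer seed for reproducible maps (uses an
#'   isolated RNG state).
#' @return A `contact_matrix`.
#' @export
sample_contact_map <- function(model, depth = 5e6, bin_width = 1e4,
                               seed = NULL) {
  stopifnot(inherits(model, "loop_layer_model"))
  if (depth < 0) stop("`depth` must be non-negative")
  if (bin_width > model$loop_size / 4) {
    warning("bin_width exceeds a quarter of the loop size; the intra-loop ",
      "regime will be poorly resolved",
      call. = FALSE
    )
  }
  run <- function() {
    lens <- model$chrom_lengths
    binning <- genomic_binning(lens, bin_width)
    grids <- purrr::map(lens, function(len) {
      g <- model_logp_grid(model, log10(len))
      s <- 10^g$x
      w <- 10^(g$logp - max(g$logp)) * pmax(len - s, 0) * s
      list(x = g$x, w = w, total = sum(w))
    })
    totals <- purrr::map_dbl(grids, "total")
    nper <- if (depth > 0) {
      as.vector(stats::rmultinom(1, depth, totals / sum(totals)))
    } else {
      rep(0L, length(lens))
    }
    px_all <- purrr::map_dfr(seq_along(lens), function(ci) {
      nc <- nper[ci]
      if (nc == 0) return(NULL)
      g <- grids[[ci]]
      len <- lens[[ci]]
      idx <- sample.int(length(g$x), nc, replace = TRUE, prob = g$w)
      dx <- g$x[2] - g$x[1]
      s <- pmin(round(10^(g$x[idx] + stats::runif(nc, -dx / 2, dx / 2))),
        len - 1
      )
      s <- pmax(s, 1)
      p1 <- floor(stats::runif(nc) * (len - s)) + 1
      tibble::tibble(
        chrom = names(lens)[ci],
        pos1 = p1, pos2 = p1 + s
      )
    })
    pixels <- if (nrow(px_all) == 0) {
      tibble::tibble(
        chrom = character(), bin1 = integer(), bin2 = integer(),
        count = numeric()
      )
    } else {
      bin_cis_pairs(px_all, binning)
    }
    contact_matrix(binning, pixels)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
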