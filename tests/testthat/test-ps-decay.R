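# helper: synthetic P(s) curve following an exact functional form
analytic_ps_curve <- function(f, scheme = log_bin_scheme(1e3, 1e8, 8)) {
  s <- sqrt(scheme$s_lo * scheme$s_hi)
  out <- tibble::tibble(
    s_lo = scheme$s_lo, s_hi = scheme$s_hi, s_mid = s,
    n_obs = 1, n_possible = 1, p = f(s), valid = TRUE
  )
  class(out) <- c("ps_curve", class(out))
  out
}

test_that("default scheme spans 1 kb to 100 Mb", {
  sc <- log_bin_scheme()
  expect_equal(min(sc$s_lo), 1e3)
  expect_equal(max(sc$s_hi), 1e8)
  expect_true(all(diff(sc$s_lo) > 0))
  expect_equal(sc$s_hi[-nrow(sc)], sc$s_lo[-1]) # contiguous edges
})

test_that("all contacts at one separation put mass in exactly one bin", {
  gb <- genomic_binning(c(chr1 = 1e6), 10000)
  px <- tibble::tibble(
    chrom = "chr1", bin1 = c(0L, 10L, 40L), bin2 = c(5L, 15L, 45L),
    count = c(2, 3, 4)
  ) # all at separation 50 kb
  ps <- compute_ps(contact_matrix(gb, px), log_bin_scheme(1e4, 1e6, 8))
  hit <- ps$s_lo <= 5e4 & ps$s_hi > 5e4
  expect_equal(sum(ps$n_obs[hit]), 9)
  expect_true(all(ps$n_obs[!hit] == 0))
})

test_that("compute_ps equals the brute-force oracle exactly (<= 50 bins)", {
  for (seed in c(11, 12)) {
    set.seed(seed)
    n <- if (seed == 11) 6 else 50
    bw <- 10000
    cts <- matrix(rpois(n * n, 3), n, n)
    cts <- cts + t(cts)
    gb <- genomic_binning(c(chr1 = n * bw), bw)
    idx <- which(upper.tri(cts, diag = TRUE) & cts != 0, arr.ind = TRUE)
    m <- contact_matrix(gb, tibble::tibble(
      chrom = "chr1", bin1 = as.integer(idx[, 1] - 1L),
      bin2 = as.integer(idx[, 2] - 1L), count = cts[idx]
    ))
    scheme <- log_bin_scheme(1e4, n * bw, 6)
    ps <- compute_ps(m, scheme)
    edges <- c(scheme$s_lo, scheme$s_hi[nrow(scheme)])
    orc <- oracle_ps(cts, bw, edges, n_masked = 1)
    expect_identical(ps$n_obs, orc$O)
    expect_identical(ps$n_possible, orc$N)
    expect_equal(ps$p, orc$p, tolerance = 1e-14)
  }
})

test_that("normalized P(s) is invariant under depth downsampling", {
  m <- sample_contact_map(
    loop_layer_model(loop_size = 140e3, loops_per_layer = 36),
    depth = 1e6, bin_width = 1e4, seed = 21
  )
  thin <- m
  set.seed(22)
  thin$pixels$count <- rbinom(
    nrow(thin$pixels), as.integer(thin$pixels$count), 0.1
  )
  ps_full <- suppressWarnings(compute_ps(m))
  ps_thin <- suppressWarnings(compute_ps(thin))
  sel <- ps_full$n_obs >= 500 & ps_thin$n_obs >= 50
  dd <- abs(log10(ps_full$p[sel]) - log10(ps_thin$p[sel]))
  expect_lt(stats::median(dd), 0.02) # equal within Monte-Carlo error
  expect_lt(max(dd), 0.1)
})

test_that("derivative recovers exact power-law exponents to 1e-6", {
  for (alpha in c(0.25, 0.5, 1, 1.5)) {
    ps <- analytic_ps_curve(function(s) s^(-alpha))
    d <- ps_derivative(ps)
    expect_lt(max(abs(d$slope_raw + alpha)), 1e-6)
  }
  # constant P(s) has slope zero
  d0 <- ps_derivative(analytic_ps_curve(function(s) rep(1, length(s))))
  expect_lt(max(abs(d0$slope_raw)), 1e-12)
})

test_that("derivative needs at least 3 valid bins", {
  ps <- analytic_ps_curve(function(s) s^-1)
  ps$valid[-(1:2)] <- FALSE
  expect_error(ps_derivative(ps), "3 valid")
})

test_that("LOESS smoothing reduces slope error on a noisy power law", {
  set.seed(31)
  alpha <- 0.7
  ps <- analytic_ps_curve(function(s) s^(-alpha) * exp(rnorm(length(s), sd = 0.05)))
  d <- ps_derivative(ps, span = 0.3)
  rmse_raw <- sqrt(mean((d$slope_raw + alpha)^2))
  rmse_smooth <- sqrt(mean((d$slope_smooth + alpha)^2))
  expect_lt(rmse_smooth, rmse_raw)
})

test_that("loop estimator returns the derivative peak; ties go to smaller s", {
  # symmetric peak centered exactly at 140 kb
  xs <- log10(1.4e5) + seq(-1.6, 1.6, by = 0.05)
  peak <- tibble::tibble(
    s_mid = 10^xs,
    slope_raw = -0.6 + 0.15 * pmax(0, 1 - abs(xs - log10(1.4e5)) / 0.5),
    slope_smooth = NA_real_
  )
  class(peak) <- c("deriv_curve", class(peak))
  attr(peak, "span") <- 0.3
  est <- estimate_loop_size(peak)
  expect_equal(est$loop_size, 1.4e5, tolerance = 0.02)
  expect_false(est$flat_peak)

  # two equal maxima: the smaller s wins
  x2 <- seq(3.5, 6.5, by = 0.05)
  bumps <- pmax(0, 1 - abs(x2 - 4.5) / 0.3) + pmax(0, 1 - abs(x2 - 5.5) / 0.3)
  two <- tibble::tibble(
    s_mid = 10^x2, slope_raw = -0.7 + 0.2 * bumps, slope_smooth = NA_real_
  )
  class(two) <- c("deriv_curve", class(two))
  attr(two, "span") <- 0.1
  est2 <- estimate_loop_size(two)
  expect_lt(est2$loop_size, 1e5)

  # flat curve raises the flatness diagnostic
  flat <- tibble::tibble(
    s_mid = 10^x2, slope_raw = rep(-0.6, length(x2)), slope_smooth = NA_real_
  )
  class(flat) <- c("deriv_curve", class(flat))
  attr(flat, "span") <- 0.3
  expect_true(estimate_loop_size(flat)$flat_peak)
})

test_that("layer estimator finds the interlayer drop within one log bin", {
  model <- loop_layer_model(
    loop_size = 140e3, layer_size = 5e6, loop_variation = "fixed"
  )
  ps <- expected_ps(model)
  d <- ps_derivative(ps)
  est <- estimate_layer_size(d)
  expect_false(est$at_boundary)
  expect_lt(abs(log10(est$layer_size) - log10(5e6)), 1 / 8)
})

test_that("a monotone power law yields a boundary-flagged layer estimate", {
  ps <- analytic_ps_curve(function(s) s^(-1.2))
  d <- ps_derivative(ps)
  est <- estimate_layer_size(d)
  expect_true(est$at_boundary)
})

test_that("loops per layer is the layer/loop ratio", {
  e <- list(loop_size = 1.4e5, layer_size = 5.6e6)
  expect_equal(loops_per_layer(e), 40)
  expect_equal(loops_per_layer(list(loop_size = 2e5, layer_size = 2e5)), 1)
  expect_error(loops_per_layer(list(loop_size = 1e5)), "layer_size")
})

test_that("estimate_loop_layer combines both estimates with tidy methods", {
  model <- loop_layer_model(
    loop_size = 140e3, layer_size = 5.6e6, loop_variation = "fixed"
  )
  d <- ps_derivative(expected_ps(model))
  e <- estimate_loop_layer(d)
  expect_s3_class(e, "loop_layer_estimate")
  expect_equal(e$loops_per_layer, e$layer_size / e$loop_size)
  td <- tidy(e)
  expect_equal(td$term, c("loop_size", "layer_size", "loops_per_layer"))
  expect_equal(nrow(glance(e)), 1)
})
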