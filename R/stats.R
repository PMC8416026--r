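#' Normalize grouped measurements to the control condition
#'
#' Within each replicate, every value is divided by that replicate's
#' control-condition median, so the control median maps to exactly 1. This
#' puts per-nucleus intensity measurements from independent experiments on
#' a common scale before they are pooled or compared. The operation is
#' idempotent: normalizing an already-normalized table changes nothing.
#'
#' @param g Tibble of grouped measurements with columns `condition`,
#'   `value` and optionally `replicate` (absent = a single replicate).
#' @param control Name of the control condition (default `"dIgG"`,
#'   a mock depletion).
#' @return `g` with `value` rescaled.
#' @export
normalize_to_control <- function(g, control = "dIgG") {
  stopifnot(all(c("condition", "value") %in% names(g)))
  if (!control %in% g$condition) {
    stop("control condition '", control, "' not present")
  }
  has_rep <- "replicate" %in% names(g)
  grp <- if (has_rep) dplyr::group_by(g, .data$replicate) else g
  out <- dplyr::mutate(grp, value = {
    ctrl <- stats::median(.data$value[.data$condition == control])
    if (!length(ctrl) || is.na(ctrl)) {
      stop("control condition missing in a replicate")
    }
    if (ctrl == 0) stop("control median is zero; cannot normalize")
    .data$value / ctrl
  })
  dplyr::ungroup(out)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum test with tie correction. The reported statistic follows the
#' `min(U_a, U_b)` convention. For small samples (pooled n <= 20 by
#' default) the two-tailed p-value is computed by exhaustive enumeration of
#' all group assignments (exact even under ties); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. When every pooled value is identical the test is vacuous and
#' p = 1.
#'
#' @param a,b Numeric vectors of measurements (both nonempty).
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default chooses exact when `length(a) + length(b) <= 20`.
#' @return A one-row tibble: `statistic` (U, min convention), `n_a`, `n_b`,
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(
      statistic = na * nb / 2, n_a = na, n_b = nb,
      p_value = 1, method = "degenerate (all values tied)"
    ))
  }
  r <- rank(pooled)
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  if (is.null(exact)) exact <- (na + nb) <= 20L
  if (exact) {
    combs <- utils::combn(na + nb, na)
    ua_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    umin_all <- pmin(ua_all, na * nb - ua_all)
    p <- mean(umin_all <= u + 1e-9)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(pooled)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tiecor)
    z <- (abs(ua - na * nb / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(
    statistic = u, n_a = na, n_b = nb, p_value = p, method = method
  )
}

#' Unpaired t-test on replicate medians
#'
#' Aggregates each replicate of the two conditions to its median and
#' compares the conditions by an unpaired two-sample Student's t-test
#' (equal variances by default; set `var_equal = FALSE` for Welch). This
#' is the second statistical tier applied to data pooled across
#' independent experiments: per-nucleus values feed the rank test, the
#' replicate medians feed this test.
#'
#' @param g Tibble with columns `condition`, `replicate`, `value`.
#' @param cond_a,cond_b The two condition labels to compare.
#' @param var_equal Assume equal variances (Student's) rather than Welch.
#' @return A one-row tibble: `t`, `df`, `p_value`, `n_rep_a`, `n_rep_b`,
#'   `degenerate` (`TRUE` when the pooled variance of the medians is zero).
#' @export
t_test_on_medians <- function(g, cond_a, cond_b, var_equal = TRUE) {
  stopifnot(all(c("condition", "replicate", "value") %in% names(g)))
  med <- dplyr::summarise(
    dplyr::group_by(
      g[g$condition %in% c(cond_a, cond_b), ],
      .data$condition, .data$replicate
    ),
    value = stats::median(.data$value), .groups = "drop"
  )
  ma <- med$value[med$condition == cond_a]
  mb <- med$value[med$condition == cond_b]
  if (length(ma) < 2 || length(mb) < 2) {
    stop("need at least 2 replicates per condition")
  }
  if (stats::var(ma) + stats::var(mb) == 0) {
    same <- mean(ma) == mean(mb)
    return(tibble::tibble(
      t = if (same) 0 else NA_real_,
      df = length(ma) + length(mb) - 2,
      p_value = if (same) 1 else NA_real_,
      n_rep_a = length(ma), n_rep_b = length(mb),
      degenerate = !same
    ))
  }
  tt <- stats::t.test(ma, mb, var.equal = var_equal)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    n_rep_a = length(ma), n_rep_b = length(mb),
    degenerate = FALSE
  )
}
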