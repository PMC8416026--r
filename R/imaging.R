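#' Multi-channel 3D image stack
#'
#' Container for a 3D fluorescence stack: named channels (e.g. `dna`,
#' `cenpa`, a protein marker) as congruent numeric arrays indexed
#' `[y, x, z]`, with physical voxel spacing.
#'
#' @param channels Named list of 3D numeric arrays (or 2D matrices, treated
#'   as single-slice stacks), non-negative, identical dimensions.
#' @param xy_nm Pixel spacing in the imaging plane (nm/px).
#' @param z_nm Slice spacing (nm/slice).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, xy_nm, z_nm) {
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a named list")
  }
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, c(dim(ch), 1L))
    if (length(dim(ch)) != 3L) stop("channels must be 2D or 3D arrays")
    if (any(ch < 0) || any(!is.finite(ch))) {
      stop("channel intensities must be finite and non-negative")
    }
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must have identical dimensions")
  }
  if (xy_nm <= 0 || z_nm <= 0) stop("voxel spacings must be positive")
  structure(
    list(channels = channels, xy_nm = xy_nm, z_nm = z_nm),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<image_stack> %d x %d px, %d slice(s); channels: %s; %g nm/px, %g nm/slice\n",
    d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
    x$xy_nm, x$z_nm
  ))
  invisible(x)
}

get_channel <- function(stack, name) {
  ch <- stack$channels[[name]]
  if (is.null(ch)) stop("stack has no channel named '", name, "'")
  ch
}

#' Otsu threshold
#'
#' Computes the intensity threshold maximizing the between-class variance
#' over a histogram of the input's intensity range. Pixels strictly above
#' the threshold form the foreground.
#'
#' @param x Numeric array/matrix/vector with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold (numeric scalar).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("cannot threshold a constant image")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(
    pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
    nbins = n_bins
  ))
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  m0 <- cumsum(h * mids)
  mtot <- sum(h * mids)
  # between-class variance for a cut after bin k (k = 1 .. n_bins - 1)
  k <- seq_len(n_bins - 1L)
  mu0 <- m0[k] / w0[k]
  mu1 <- (mtot - m0[k]) / w1[k]
  bcv <- w0[k] * w1[k] * (mu0 - mu1)^2
  bcv[!is.finite(bcv)] <- -Inf
  edges[which.max(bcv) + 1L]
}

#' Label connected components of a binary mask
#'
#' 26-connectivity in 3D, 8-connectivity in 2D (the most permissive
#' neighborhoods, merging touching objects into a single mass).
#'
#' @param mask Logical/0-1 matrix or 3D array.
#' @return Integer array of the same shape: 0 for background, labels
#'   `1..k` for components, numbered by first (column-major) occurrence.
#' @export
label_components <- function(mask) {
  two_d <- is.matrix(mask)
  m <- if (two_d) array(mask != 0, c(dim(mask), 1L)) else (mask != 0)
  d <- dim(m)
  fg <- which(m)
  out <- array(0L, d)
  if (!length(fg)) return(if (two_d) out[, , 1] else out)
  id <- array(0L, d)
  id[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  # backward half of the 26- (or 8-) neighborhood
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[offs$dz < 0 | (offs$dz == 0 & (offs$dx < 0 |
    (offs$dx == 0 & offs$dy < 0))), ]
  if (two_d || d[3] == 1L) offs <- offs[offs$dz == 0, ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    ny <- co[, 1] + offs$dy[r]
    nx <- co[, 2] + offs$dx[r]
    nz <- co[, 3] + offs$dz[r]
    okb <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(okb)) next
    nid <- id[cbind(ny[okb], nx[okb], nz[okb])]
    hit <- nid > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(okb)[hit], nid[hit]))
    }
  }
  if (is.null(edges)) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::make_graph(as.vector(t(edges)),
      n = length(fg), directed = FALSE
    )
    memb <- igraph::components(g)$membership
  }
  relab <- integer(max(memb))
  nxt <- 0L
  for (i in seq_along(fg)) {
    mi <- memb[i]
    if (relab[mi] == 0L) {
      nxt <- nxt + 1L
      relab[mi] <- nxt
    }
  }
  out[fg] <- relab[memb]
  if (two_d) out[, , 1] else out
}

# running-max binary dilation with a square/cube structuring element
dilate_box <- function(mask, r) {
  m <- mask != 0
  d <- dim(m)
  two_d <- length(d) == 2L
  if (two_d) {
    m <- array(m, c(d, 1L))
    d <- dim(m)
  }
  shift_or <- function(a, axis) {
    out <- a
    for (k in seq_len(r)) {
      idx_lo <- 1:(d[axis] - k)
      idx_hi <- (1 + k):d[axis]
      if (axis == 1) {
        out[idx_hi, , ] <- out[idx_hi, , ] | a[idx_lo, , ]
        out[idx_lo, , ] <- out[idx_lo, , ] | a[idx_hi, , ]
      } else if (axis == 2) {
        out[, idx_hi, ] <- out[, idx_hi, ] | a[, idx_lo, ]
        out[, idx_lo, ] <- out[, idx_lo, ] | a[, idx_hi, ]
      } else {
        out[, , idx_hi] <- out[, , idx_hi] | a[, , idx_lo]
        out[, , idx_lo] <- out[, , idx_lo] | a[, , idx_hi]
      }
      a <- out
    }
    out
  }
  m <- shift_or(m, 1)
  m <- shift_or(m, 2)
  if (dim(m)[3] > 1) m <- shift_or(m, 3)
  if (two_d) m[, , 1] else m
}

# index of the z slice with maximal total DNA intensity
max_dna_slice <- function(stack, dna = "dna") {
  ch <- get_channel(stack, dna)
  which.max(apply(ch, 3, sum))
}

#' Per-mass immunofluorescence quantification
#'
#' Implements single-slice marker quantification: the z slice with maximal
#' total DNA intensity is selected, a constant background (the median
#' intensity outside a generously dilated DNA mask) is subtracted from both
#' channels, the DNA mask is produced by Otsu thresholding, and for every
#' connected DNA mass the mean marker intensity is reported normalized to
#' the mean DNA intensity in the same mass.
#'
#' @param stack An [image_stack()] with a DNA channel and the marker
#'   channel.
#' @param marker Name of the marker channel.
#' @param dna Name of the DNA channel.
#' @param dilate_radius Dilation radius (px) used to define the background
#'   region.
#' @return A tibble with one row per DNA mass: `mass`, `n_pixels`,
#'   `mean_dna`, `mean_marker`, `ratio` (= `mean_marker / mean_dna`).
#' @export
quantify_if <- function(stack, marker, dna = "dna", dilate_radius = 10L) {
  zi <- max_dna_slice(stack, dna)
  dna_sl <- get_channel(stack, dna)[, , zi]
  mk_sl <- get_channel(stack, marker)[, , zi]
  t_dna <- otsu_threshold(dna_sl)
  mask <- dna_sl > t_dna
  if (!any(mask)) stop("empty DNA mask after thresholding")
  bgreg <- !dilate_box(mask, dilate_radius)
  bg_dna <- if (any(bgreg)) stats::median(dna_sl[bgreg]) else 0
  bg_mk <- if (any(bgreg)) stats::median(mk_sl[bgreg]) else 0
  dna_c <- pmax(dna_sl - bg_dna, 0)
  mk_c <- pmax(mk_sl - bg_mk, 0)
  lab <- label_components(mask)
  labs <- sort(unique(lab[lab > 0]))
  purrr::map_dfr(labs, function(l) {
    sel <- lab == l
    md <- mean(dna_c[sel])
    mm <- mean(mk_c[sel])
    tibble::tibble(
      mass = l, n_pixels = sum(sel),
      mean_dna = md, mean_marker = mm,
      ratio = mm / md
    )
  })
}

# linear interpolation of a volume along z to a target slice spacing;
# output slice count is ceiling(span / target) + 1 (clamped at the ends)
interpolate_z <- function(vol, z_nm, target_z_nm) {
  d <- dim(vol)
  span <- (d[3] - 1) * z_nm
  n_out <- as.integer(ceiling(span / target_z_nm)) + 1L
  zpos <- (seq_len(n_out) - 1) * target_z_nm / z_nm # in input-slice units
  zpos <- pmin(zpos, d[3] - 1)
  lo <- pmin(floor(zpos), d[3] - 2)
  lo[lo < 0] <- 0
  w <- zpos - lo
  out <- array(0, c(d[1], d[2], n_out))
  for (k in seq_len(n_out)) {
    out[, , k] <- (1 - w[k]) * vol[, , lo[k] + 1] + w[k] * vol[, , lo[k] + 2]
  }
  out
}

#' 3D surface area of chromosome masses
#'
#' Interpolates the DNA channel along z to `target_z_nm` slice spacing,
#' segments the interpolated volume by Otsu thresholding, labels connected
#' components (26-connectivity), discards components of `min_voxels` voxels
#' or fewer, and reports each surviving component's surface area and
#' integrated DNA intensity. The headline statistic is
#' `surface_area / dna_intensity` per component, the normalized surface
#' area used to compare chromosome dispersal between conditions.
#'
#' Surface areas are measured on a triangulated isosurface (marching
#' tetrahedra at level 0.5 on the binary component mask after a light
#' Gaussian smoothing, `smooth_sigma` voxels), in physical units from the
#' voxel spacings; this tracks the true area of smooth objects to within a
#' few percent. `method = "voxel"` instead counts exposed voxel faces,
#' which overestimates curved surfaces but is exact for axis-aligned boxes.
#'
#' @param stack An [image_stack()] with a DNA channel.
#' @param dna Name of the DNA channel.
#' @param target_z_nm Target slice spacing after interpolation (nm).
#' @param min_voxels Voxel-count filter: only components strictly larger
#'   than this are analyzed.
#' @param method `"mesh"` (marching tetrahedra) or `"voxel"` (face
#'   counting).
#' @param smooth_sigma Gaussian pre-smoothing (voxels) for the mesh method.
#' @param voxel_budget Maximum allowed number of voxels in the interpolated
#'   volume.
#' @return A tibble with one row per component: `mass`, `n_voxels`,
#'   `surface_area_um2`, `dna_intensity`, `sa_per_dna`.
#' @export
surface_area_3d <- function(stack, dna = "dna", target_z_nm = 67,
                            min_voxels = 10000L,
                            method = c("mesh", "voxel"),
                            smooth_sigma = 1, voxel_budget = 2.5e8) {
  method <- match.arg(method)
  vol <- get_channel(stack, dna)
  if (stack$z_nm < target_z_nm) {
    stop("z spacing (", stack$z_nm, " nm) is below the interpolation target")
  }
  d <- dim(vol)
  n_out <- ceiling((d[3] - 1) * stack$z_nm / target_z_nm) + 1
  if (d[1] * d[2] * n_out > voxel_budget) {
    stop(
      "interpolated volume would hold ", d[1] * d[2] * n_out,
      " voxels, above the budget of ", voxel_budget,
      "; downsample the stack in xy first"
    )
  }
  ivol <- interpolate_z(vol, stack$z_nm, target_z_nm)
  t_dna <- otsu_threshold(ivol)
  mask <- ivol > t_dna
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes > min_voxels)
  spacing <- c(stack$xy_nm, stack$xy_nm, target_z_nm)
  purrr::map_dfr(keep, function(l) {
    comp <- lab == l
    area_nm2 <- if (method == "mesh") {
      mesh_surface_area(comp, spacing, smooth_sigma)
    } else {
      voxel_face_area(comp, spacing)
    }
    dna_int <- sum(ivol[comp])
    tibble::tibble(
      mass = l, n_voxels = sizes[l],
      surface_area_um2 = area_nm2 / 1e6,
      dna_intensity = dna_int,
      sa_per_dna = area_nm2 / 1e6 / dna_int
    )
  })
}

#' Count centromere (CENP-A) foci per DNA mass
#'
#' Segments DNA and CENP-A independently by Otsu thresholding, treats each
#' connected object of the DNA mask as a single chromosomal mass, and
#' counts the CENP-A foci whose centroid falls inside each mass. Foci whose
#' centroids are closer than `merge_radius` pixels are merged and counted
#' once, approximating the convention that a sister-centromere doublet is
#' one focus. A mass is classified as an individualized chromosome when it
#' holds fewer than 4 foci, and as a chromosome cluster otherwise.
#'
#' @param stack An [image_stack()] with DNA and CENP-A channels.
#' @param cenpa Name of the CENP-A channel.
#' @param dna Name of the DNA channel.
#' @param mode `"slice"` (default): segment the z slice with maximal DNA
#'   intensity in 2D; `"volume"`: segment the full 3D stack.
#' @param merge_radius Centroid distance (px) under which foci are merged.
#' @param min_focus_px Minimum focus size in pixels; smaller detections are
#'   discarded as noise.
#' @param min_mass_px Minimum DNA mass size in pixels; smaller objects are
#'   noise specks, not chromosomal masses.
#' @param smooth_sigma Gaussian pre-smoothing (px) applied to both channels
#'   before thresholding. Matched filtering at roughly the spot scale keeps
#'   Otsu's threshold out of the read-noise distribution when foci occupy
#'   only a tiny fraction of the image; set to 0 to threshold raw pixels.
#' @return A tibble with one row per DNA mass: `mass`, `n_pixels`,
#'   `n_foci`, `individualized` (`n_foci < 4`).
#' @export
count_cenpa_foci <- function(stack, cenpa = "cenpa", dna = "dna",
                             mode = c("slice", "volume"),
                             merge_radius = 3, min_focus_px = 2L,
                             min_mass_px = 20L, smooth_sigma = 1) {
  mode <- match.arg(mode)
  if (mode == "slice") {
    zi <- max_dna_slice(stack, dna)
    dna_img <- get_channel(stack, dna)[, , zi]
    cen_img <- get_channel(stack, cenpa)[, , zi]
  } else {
    dna_img <- get_channel(stack, dna)
    cen_img <- get_channel(stack, cenpa)
  }
  if (smooth_sigma > 0) {
    smooth_any <- function(img) {
      d <- dim(img)
      if (length(d) == 2L) {
        gauss_smooth3(array(img, c(d, 1L)), smooth_sigma)[, , 1]
      } else {
        gauss_smooth3(img, smooth_sigma)
      }
    }
    dna_img <- smooth_any(dna_img)
    cen_img <- smooth_any(cen_img)
  }
  dna_mask <- dna_img > otsu_threshold(dna_img)
  # close single-pixel noise holes so centroid membership is not lost to
  # speckle inside a mass
  dna_mask <- !dilate_box(!dilate_box(dna_mask, 1L), 1L)
  cen_mask <- if (length(unique(as.numeric(cen_img))) < 2L) {
    array(FALSE, dim(cen_img))
  } else {
    cen_img > otsu_threshold(cen_img)
  }
  mass_lab <- label_components(dna_mask)
  if (max(mass_lab) > 0L && min_mass_px > 1L) {
    sz <- tabulate(mass_lab[mass_lab > 0L])
    drop <- which(sz < min_mass_px)
    if (length(drop)) {
      mass_lab[mass_lab %in% drop] <- 0L
      keep <- sort(unique(mass_lab[mass_lab > 0L]))
      mass_lab[] <- match(mass_lab, keep, nomatch = 0L)
    }
  }
  foci_lab <- label_components(cen_mask)
  n_mass <- max(mass_lab)
  if (n_mass == 0L) {
    return(tibble::tibble(
      mass = integer(), n_pixels = integer(),
      n_foci = integer(), individualized = logical()
    ))
  }
  centroids <- NULL
  if (max(foci_lab) > 0L) {
    # foci = local intensity maxima inside the focus mask, so that touching
    # spots separated by a valley are still counted individually; maxima
    # closer than merge_radius collapse to one focus (doublet convention)
    comp_size <- tabulate(foci_lab[foci_lab > 0L])
    mx <- local_maxima(cen_img, cen_mask)
    mx <- mx[comp_size[foci_lab[mx$idx]] >= min_focus_px, , drop = FALSE]
    if (nrow(mx)) {
      cen <- tibble::tibble(
        y = mx$y, x = mx$x, z = mx$z, n = 1
      )
      centroids <- merge_close_foci(cen, merge_radius)
    }
  }
  counts <- integer(n_mass)
  if (!is.null(centroids) && nrow(centroids)) {
    yy <- pmin(pmax(round(centroids$y), 1), dim(mass_lab)[1])
    xx <- pmin(pmax(round(centroids$x), 1), dim(mass_lab)[2])
    idx <- if (length(dim(mass_lab)) == 3L) {
      zz <- pmin(pmax(round(centroids$z), 1), dim(mass_lab)[3])
      cbind(yy, xx, zz)
    } else {
      cbind(yy, xx)
    }
    ml <- mass_lab[idx]
    hit <- ml > 0L
    if (any(hit)) {
      tab <- tabulate(ml[hit], nbins = n_mass)
      counts <- counts + tab
    }
  }
  sizes <- tabulate(mass_lab[mass_lab > 0], nbins = n_mass)
  tibble::tibble(
    mass = seq_len(n_mass),
    n_pixels = sizes,
    n_foci = counts,
    individualized = counts < 4L
  )
}

# local maxima of img restricted to mask (plateau pixels all qualify and
# are collapsed later by the merge radius)
local_maxima <- function(img, mask) {
  d <- dim(img)
  two_d <- length(d) == 2L
  if (two_d) {
    img <- array(img, c(d, 1L))
    mask <- array(mask, c(d, 1L))
    d <- dim(img)
  }
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- img
  is_max <- array(TRUE, d)
  for (dy in -1:1) {
    for (dx in -1:1) {
      for (dz in -1:1) {
        if (dy == 0 && dx == 0 && dz == 0) next
        nb <- pad[
          (2:(d[1] + 1)) + dy, (2:(d[2] + 1)) + dx, (2:(d[3] + 1)) + dz,
          drop = FALSE
        ]
        is_max <- is_max & (img >= nb)
      }
    }
  }
  idx <- which(is_max & mask)
  co <- arrayInd(idx, d)
  data.frame(idx = idx, y = co[, 1], x = co[, 2], z = co[, 3])
}

# single-linkage merge of focus centroids closer than `radius`
merge_close_foci <- function(cen, radius) {
  n <- nrow(cen)
  if (n <= 1L) return(cen)
  dd <- as.matrix(stats::dist(cen[, c("y", "x", "z")]))
  adj <- which(dd < radius & upper.tri(dd), arr.ind = TRUE)
  if (!nrow(adj)) return(cen)
  g <- igraph::make_graph(as.vector(t(adj)), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      grp = memb, y = cen$y, x = cen$x, z = cen$z, n = cen$n
    ), .data$grp),
    y = stats::weighted.mean(.data$y, .data$n),
    x = stats::weighted.mean(.data$x, .data$n),
    z = stats::weighted.mean(.data$z, .data$n),
    n = sum(.data$n), .groups = "drop"
  )
}

#' Frequency of individualized chromosomes
#'
#' Percentage of DNA masses classified as individualized chromosomes
#' (fewer than 4 CENP-A foci). When the records carry a `replicate`
#' column, per-replicate frequencies are returned.
#'
#' @param records Tibble with an `individualized` logical column, e.g. from
#'   [count_cenpa_foci()]; optionally a `replicate` column.
#' @return A tibble with columns (`replicate`,) `n_masses`,
#'   `n_individualized`, `pct_individualized`.
#' @export
individualization_frequency <- function(records) {
  if (!nrow(records)) stop("no mass records")
  if ("replicate" %in% names(records)) {
    grp <- dplyr::group_by(records, .data$replicate)
  } else {
    grp <- records
  }
  dplyr::summarise(
    grp,
    n_masses = dplyr::n(),
    n_individualized = sum(.data$individualized),
    pct_individualized = 100 * mean(.data$individualized),
    .groups = "drop"
  )
}
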