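#' Specify a synthetic 3D microscopy scene
#'
#' Describes a multi-channel 3D stack containing DNA masses (ellipsoids or
#' curved tubes) with embedded point foci, for generating test images with
#' known ground truth. Default spacings mirror wide-field acquisition at
#' 100x (65 nm/px, 200 nm z-sections) so the 67 nm z-interpolation path of
#' [surface_area_3d()] is exercised.
#'
#' @param dim Stack dimensions `c(y, x, z)` in voxels.
#' @param xy_nm,z_nm Voxel spacings (nm).
#' @param masses List of mass specifications from [mass_ellipsoid()] or
#'   [mass_tube()].
#' @param foci Tibble of CENP-A-like point foci: columns `mass` (index into
#'   `masses`), `y`, `x`, `z` (voxel coordinates), `amplitude`, `sigma_px`.
#' @param noise_sd Gaussian read-noise standard deviation added to every
#'   channel.
#' @param shot_noise If `TRUE`, voxel intensities are Poisson-resampled
#'   before read noise is added.
#' @param seed Optional seed for reproducible rendering.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(dim = c(96, 96, 11), xy_nm = 65, z_nm = 200,
                       masses = list(), foci = NULL,
                       noise_sd = 0, shot_noise = FALSE, seed = NULL) {
  stopifnot(length(dim) == 3, all(dim >= 1), xy_nm > 0, z_nm > 0, noise_sd >= 0)
  if (!is.null(foci)) {
    foci <- tibble::as_tibble(foci)
    req <- c("mass", "y", "x", "z", "amplitude", "sigma_px")
    if (!all(req %in% names(foci))) {
      stop("`foci` needs columns ", paste(req, collapse = ", "))
    }
    if (any(foci$amplitude < 0)) stop("focus amplitudes must be >= 0")
  }
  structure(
    list(
      dim = as.integer(dim), xy_nm = xy_nm, z_nm = z_nm,
      masses = masses, foci = foci,
      noise_sd = noise_sd, shot_noise = shot_noise, seed = seed
    ),
    class = "scene_spec"
  )
}

#' Ellipsoidal DNA mass
#'
#' @param center Center `c(y, x, z)` in voxel coordinates.
#' @param semiaxes Semi-axes `c(ry, rx, rz)` in voxels.
#' @param intensity DNA intensity of the mass (arbitrary units).
#' @param marker_ratio Marker-channel intensity relative to DNA.
#' @return A mass specification for [scene_spec()].
#' @export
mass_ellipsoid <- function(center, semiaxes, intensity = 1000,
                           marker_ratio = 1) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0))
  list(
    type = "ellipsoid", center = center, semiaxes = semiaxes,
    intensity = intensity, marker_ratio = marker_ratio
  )
}

#' Curved-tube DNA mass
#'
#' A sphere of radius `radius` swept along a random smooth path, mimicking
#' an elongated chromosome; `waviness` controls the per-step random change
#' of direction. Exposing radius and length lets thinner/longer versus
#' thicker/shorter chromosome contrasts be synthesized.
#'
#' @param start Path start `c(y, x, z)` in voxels.
#' @param length_px Path length in voxels (unit steps).
#' @param radius Tube radius in voxels.
#' @param intensity DNA intensity.
#' @param marker_ratio Marker-channel intensity relative to DNA.
#' @param waviness Standard deviation (radians) of the per-step direction
#'   change.
#' @return A mass specification for [scene_spec()].
#' @export
mass_tube <- function(start, length_px, radius, intensity = 1000,
                      marker_ratio = 1, waviness = 0.15) {
  stopifnot(length(start) == 3, length_px >= 1, radius > 0)
  list(
    type = "tube", start = start, length_px = length_px, radius = radius,
    intensity = intensity, marker_ratio = marker_ratio, waviness = waviness
  )
}

# Knud Thomsen approximation to the ellipsoid surface area
ellipsoid_area_kt <- function(a, b, c) {
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

#' Render a synthetic scene
#'
#' Rasterizes the scene into an [image_stack()] with channels `dna`,
#' `marker` and `cenpa`, plus a ground-truth table. Masses assigned to
#' different labels must not overlap (the truth would be ambiguous) and
#' every focus center must lie inside its assigned mass. Ellipsoid truth
#' rows carry the analytic volume (voxels) and the Knud Thomsen
#' surface-area approximation in physical units.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `stack` (an `image_stack`), `labels`
#'   (integer array of mass labels), `truth` (list of tibbles `masses` and
#'   `foci`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  run <- function() {
    d <- spec$dim
    labels <- array(0L, d)
    dna <- array(0, d)
    marker <- array(0, d)
    cenpa <- array(0, d)
    truth <- purrr::map_dfr(seq_along(spec$masses), function(i) {
      ms <- spec$masses[[i]]
      vox <- rasterize_mass(ms, d)
      if (!length(vox)) stop("mass ", i, " rasterizes to zero voxels")
      clash <- labels[vox] != 0L
      if (any(clash)) {
        stop(
          "masses ", unique(labels[vox][clash])[1], " and ", i,
          " overlap; assign overlapping shapes to the same mass"
        )
      }
      labels[vox] <<- i
      dna[vox] <<- dna[vox] + ms$intensity
      marker[vox] <<- marker[vox] + ms$intensity * ms$marker_ratio
      tibble::tibble(
        mass = i,
        type = ms$type,
        n_voxels = length(vox),
        volume_analytic = if (ms$type == "ellipsoid") {
          4 / 3 * pi * prod(ms$semiaxes)
        } else {
          NA_real_
        },
        surface_area_analytic_um2 = if (ms$type == "ellipsoid") {
          ellipsoid_area_kt(
            ms$semiaxes[1] * spec$xy_nm,
            ms$semiaxes[2] * spec$xy_nm,
            ms$semiaxes[3] * spec$z_nm
          ) / 1e6
        } else {
          NA_real_
        },
        marker_ratio = ms$marker_ratio,
        intensity = ms$intensity
      )
    })
    n_foci <- integer(length(spec$masses))
    if (!is.null(spec$foci) && nrow(spec$foci)) {
      for (r in seq_len(nrow(spec$foci))) {
        f <- spec$foci[r, ]
        cy <- round(f$y)
        cx <- round(f$x)
        cz <- round(f$z)
        if (cy < 1 || cy > d[1] || cx < 1 || cx > d[2] || cz < 1 || cz > d[3] ||
          labels[cy, cx, cz] != f$mass) {
          stop("focus ", r, " does not lie inside mass ", f$mass)
        }
        n_foci[f$mass] <- n_foci[f$mass] + 1L
        rr <- ceiling(3 * f$sigma_px)
        ys <- max(1, cy - rr):min(d[1], cy + rr)
        xs <- max(1, cx - rr):min(d[2], cx + rr)
        zs <- max(1, cz - rr):min(d[3], cz + rr)
        gy <- exp(-((ys - f$y)^2) / (2 * f$sigma_px^2))
        gx <- exp(-((xs - f$x)^2) / (2 * f$sigma_px^2))
        gz <- exp(-((zs - f$z)^2) / (2 * f$sigma_px^2))
        spot <- f$amplitude * outer(outer(gy, gx), gz)
        cenpa[ys, xs, zs] <- cenpa[ys, xs, zs] + spot
      }
    }
    if (nrow(truth)) truth$n_foci <- n_foci
    add_noise <- function(ch) {
      if (spec$shot_noise) ch[] <- stats::rpois(length(ch), pmax(ch, 0))
      if (spec$noise_sd > 0) {
        ch <- ch + stats::rnorm(length(ch), sd = spec$noise_sd)
      }
      pmax(ch, 0)
    }
    stack <- image_stack(
      list(
        dna = add_noise(dna),
        marker = add_noise(marker),
        cenpa = add_noise(cenpa)
      ),
      xy_nm = spec$xy_nm, z_nm = spec$z_nm
    )
    list(
      stack = stack, labels = labels,
      truth = list(masses = truth, foci = spec$foci)
    )
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, run()) else run()
}

rasterize_mass <- function(ms, d) {
  if (ms$type == "ellipsoid") {
    ctr <- ms$center
    sa <- ms$semiaxes
    ys <- max(1, floor(ctr[1] - sa[1])):min(d[1], ceiling(ctr[1] + sa[1]))
    xs <- max(1, floor(ctr[2] - sa[2])):min(d[2], ceiling(ctr[2] + sa[2]))
    zs <- max(1, floor(ctr[3] - sa[3])):min(d[3], ceiling(ctr[3] + sa[3]))
    g <- expand.grid(y = ys, x = xs, z = zs)
    inside <- ((g$y - ctr[1]) / sa[1])^2 + ((g$x - ctr[2]) / sa[2])^2 +
      ((g$z - ctr[3]) / sa[3])^2 <= 1
    g <- g[inside, ]
    unique(g$y + (g$x - 1L) * d[1] + (g$z - 1L) * d[1] * d[2])
  } else {
    # sphere swept along a smooth random path
    nstep <- ms$length_px
    theta <- stats::runif(1, 0, 2 * pi)
    phi <- 0
    pos <- matrix(0, nstep, 3)
    pos[1, ] <- ms$start
    for (k in 2:nstep) {
      theta <- theta + stats::rnorm(1, sd = ms$waviness)
      phi <- phi * 0.9 + stats::rnorm(1, sd = ms$waviness / 3)
      step <- c(sin(theta) * cos(phi), cos(theta) * cos(phi), sin(phi))
      pos[k, ] <- pos[k - 1, ] + step
    }
    r <- ms$radius
    rr <- ceiling(r)
    sph <- expand.grid(dy = -rr:rr, dx = -rr:rr, dz = -rr:rr)
    sph <- sph[sph$dy^2 + sph$dx^2 + sph$dz^2 <= r^2, ]
    vox <- purrr::map(seq_len(nstep), function(k) {
      y <- round(pos[k, 1]) + sph$dy
      x <- round(pos[k, 2]) + sph$dx
      z <- round(pos[k, 3]) + sph$dz
      ok <- y >= 1 & y <= d[1] & x >= 1 & x <= d[2] & z >= 1 & z <= d[3]
      y[ok] + (x[ok] - 1L) * d[1] + (z[ok] - 1L) * d[1] * d[2]
    })
    unique(unlist(vox))
  }
}
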