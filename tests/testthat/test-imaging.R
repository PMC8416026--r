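box_stack <- function(dim = c(48, 48, 5), boxes, xy_nm = 65, z_nm = 200,
                      extra = list()) {
  dna <- array(0, dim)
  for (b in boxes) {
    dna[b$y, b$x, b$z] <- b$intensity
  }
  image_stack(c(list(dna = dna), extra), xy_nm = xy_nm, z_nm = z_nm)
}

test_that("Otsu separates a bimodal image and matches the brute-force oracle", {
  img <- c(rep(10, 1000), rep(200, 1000))
  t <- otsu_threshold(img)
  expect_gt(t, 10)
  expect_lt(t, 200)

  # small toy histogram: exhaustive search over all cuts
  toy <- rep(c(3, 7, 8, 20, 22, 40), times = c(50, 30, 25, 10, 12, 4))
  expect_equal(otsu_threshold(toy), oracle_otsu(toy))

  # random images
  for (seed in 1:4) {
    set.seed(seed)
    img <- matrix(rgamma(64^2, shape = 0.8, scale = 50), 64)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("Otsu threshold is equivariant under affine intensity rescaling", {
  set.seed(9)
  img <- c(rnorm(500, 20, 3), rnorm(500, 90, 8))
  t0 <- otsu_threshold(img)
  t1 <- otsu_threshold(3.5 * img + 12)
  expect_equal(t1, 3.5 * t0 + 12, tolerance = 1e-9)
})

test_that("Otsu refuses a constant image", {
  expect_error(otsu_threshold(rep(5, 100)), "constant")
})

test_that("connected-component labeling matches a flood-fill oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    mask3 <- array(runif(20^3) < 0.2, c(20, 20, 20))
    expect_same_partition(label_components(mask3), oracle_flood_fill(mask3))
    expect_equal(
      max(label_components(mask3)),
      max(oracle_flood_fill(mask3))
    )
    mask2 <- matrix(runif(32^2) < 0.3, 32)
    expect_same_partition(label_components(mask2), oracle_flood_fill(mask2))
  }
})

test_that("marker quantification is exact for proportional channels", {
  dna <- array(0, c(40, 40, 3))
  dna[5:15, 5:15, 2] <- 800
  dna[25:35, 22:32, 2] <- 600
  st_same <- image_stack(list(dna = dna, marker = dna), 65, 200)
  q1 <- quantify_if(st_same, "marker")
  expect_equal(nrow(q1), 2)
  expect_equal(q1$ratio, c(1, 1))
  st_double <- image_stack(list(dna = dna, marker = 2 * dna), 65, 200)
  expect_equal(quantify_if(st_double, "marker")$ratio, c(2, 2))
})

test_that("marker ratios are invariant to a common intensity scale", {
  sp <- scene_spec(
    dim = c(64, 64, 5),
    masses = list(
      mass_ellipsoid(c(18, 18, 3), c(9, 9, 2), marker_ratio = 0.5),
      mass_ellipsoid(c(46, 46, 3), c(9, 9, 2), marker_ratio = 1.5)
    ),
    noise_sd = 0, seed = 5
  )
  st <- render_scene(sp)$stack
  q <- quantify_if(st, "marker")
  st2 <- image_stack(
    lapply(st$channels, function(ch) 3 * ch),
    st$xy_nm, st$z_nm
  )
  q2 <- quantify_if(st2, "marker")
  expect_equal(q2$ratio, q$ratio, tolerance = 1e-9)
})

test_that("planted per-mass marker ratios are recovered under noise", {
  sp <- scene_spec(
    dim = c(72, 72, 5),
    masses = list(
      mass_ellipsoid(c(20, 20, 3), c(10, 10, 2),
        intensity = 1000, marker_ratio = 0.5
      ),
      mass_ellipsoid(c(52, 50, 3), c(10, 10, 2),
        intensity = 1000, marker_ratio = 1.5
      )
    ),
    noise_sd = 30, seed = 11
  )
  st <- render_scene(sp)$stack
  q <- quantify_if(st, "marker")
  expect_equal(sort(q$ratio), c(0.5, 1.5), tolerance = 0.05)
})

test_that("z interpolation produces the forced slice count", {
  vol <- array(runif(10 * 10 * 11), c(10, 10, 11))
  out <- mitoscale:::interpolate_z(vol, z_nm = 200, target_z_nm = 67)
  expect_equal(dim(out)[3], ceiling(2000 / 67) + 1) # 31 slices
  # endpoints preserved
  expect_equal(out[, , 1], vol[, , 1])
  # interior slices interpolate between neighbors
  expect_true(all(out >= 0))
})

test_that("the large-object filter keeps > 10,000 voxel components only", {
  # 67 nm z-sections: interpolation is the identity, voxel counts are exact
  dna <- array(0, c(120, 130, 3))
  dna[1:99, 1:101, 2] <- 1000 # 99 * 101 = 9,999 voxels
  dna[110:120, 110:130, 1:3] <- 1000 # 11 * 21 * 3 = 693 voxels
  st <- image_stack(list(dna = dna), xy_nm = 65, z_nm = 67)
  r <- surface_area_3d(st, target_z_nm = 67)
  expect_equal(nrow(r), 0) # 9,999 excluded

  dna[1:99, 1:101, 2] <- 1000
  dna[100, 1:2, 2] <- 1000 # now 10,001 voxels
  st2 <- image_stack(list(dna = dna), xy_nm = 65, z_nm = 67)
  r2 <- surface_area_3d(st2, target_z_nm = 67)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_voxels, 10001)
})

test_that("mesh surface area of a digital ball is within 5% of 4*pi*r^2", {
  n <- 45
  cc <- 23
  r <- 20
  g <- expand.grid(y = 1:n, x = 1:n, z = 1:n)
  ball <- array(
    (g$y - cc)^2 + (g$x - cc)^2 + (g$z - cc)^2 <= r^2,
    c(n, n, n)
  )
  dna <- array(0, c(n, n, n))
  dna[ball] <- 500
  st <- image_stack(list(dna = dna), xy_nm = 67, z_nm = 67)
  res <- surface_area_3d(st, target_z_nm = 67, min_voxels = 10000)
  expect_equal(nrow(res), 1)
  truth_um2 <- 4 * pi * (r * 67 / 1000)^2
  expect_lt(abs(res$surface_area_um2 / truth_um2 - 1), 0.05)
})

test_that("surface area grows when a convex component is dilated", {
  n <- 36
  cc <- 18
  g <- expand.grid(y = 1:n, x = 1:n, z = 1:n)
  for (r in c(10, 12)) {
    ball <- array((g$y - cc)^2 + (g$x - cc)^2 + (g$z - cc)^2 <= r^2, c(n, n, n))
    dil <- mitoscale:::dilate_box(ball, 1)
    a0 <- mitoscale:::mesh_surface_area(ball, c(1, 1, 1))
    a1 <- mitoscale:::mesh_surface_area(dil, c(1, 1, 1))
    expect_gt(a1, a0)
  }
})

test_that("voxel-face area is exact for an axis-aligned box", {
  dna <- array(0, c(30, 30, 10))
  dna[5:24, 5:24, 3:8] <- 100 # 20 x 20 x 6 box
  comp <- dna > 0
  a <- mitoscale:::voxel_face_area(comp, c(1, 1, 1))
  expect_equal(a, 2 * (20 * 20) + 4 * (20 * 6))
})

test_that("foci counting applies the < 4 rule per DNA mass", {
  dim <- c(60, 60, 3)
  dna <- array(0, dim)
  dna[5:25, 5:25, 2] <- 500 # mass 1
  dna[35:55, 35:55, 2] <- 500 # mass 2
  cenpa <- array(0, dim)
  spots1 <- list(c(8, 8), c(8, 20), c(20, 8)) # 3 foci -> individualized
  spots2 <- list(c(38, 38), c(38, 52), c(52, 38), c(52, 52)) # 4 -> cluster
  for (s in spots1) cenpa[s[1] + 0:1, s[2] + 0:1, 2] <- 900
  for (s in spots2) cenpa[s[1] + 0:1, s[2] + 0:1, 2] <- 900
  st <- image_stack(list(dna = dna, cenpa = cenpa), 65, 200)
  rec <- count_cenpa_foci(st)
  rec <- rec[order(rec$mass), ]
  expect_equal(rec$n_foci, c(3L, 4L))
  expect_equal(rec$individualized, c(TRUE, FALSE))
})

test_that("close foci merge into one, mimicking the doublet convention", {
  dim <- c(40, 40, 1)
  dna <- array(0, dim)
  dna[3:38, 3:38, 1] <- 500
  cenpa <- array(0, dim)
  cenpa[10:11, 10:11, 1] <- 900
  cenpa[10:11, 13:14, 1] <- 900 # centroids 3 px apart: a doublet
  cenpa[30:31, 30:31, 1] <- 900 # a separate focus
  st <- image_stack(list(dna = dna, cenpa = cenpa), 65, 200)
  rec <- count_cenpa_foci(st, merge_radius = 3.5)
  expect_equal(rec$n_foci, 2L)
})

test_that("seven planted Gaussian foci at SNR 10 are counted exactly", {
  offs <- list(
    c(-8, -8), c(-8, 0), c(-8, 8), c(0, -4), c(0, 4), c(8, -8), c(8, 6)
  )
  foci <- tibble::tibble(
    mass = 1,
    y = 32 + vapply(offs, `[[`, 0, 1),
    x = 32 + vapply(offs, `[[`, 0, 2),
    z = 3, amplitude = 800, sigma_px = 1.2
  )
  sp <- scene_spec(
    dim = c(64, 64, 5),
    masses = list(mass_ellipsoid(c(32, 32, 3), c(14, 14, 2), intensity = 400)),
    foci = foci, noise_sd = 80, seed = 17 # SNR = 800 / 80 = 10
  )
  st <- render_scene(sp)$stack
  rec <- count_cenpa_foci(st)
  expect_equal(sum(rec$n_foci), 7L)
})

test_that("counting equals a full per-pixel oracle on small images", {
  set.seed(23)
  dim <- c(48, 48, 1)
  dna <- array(0, dim)
  dna[8:28, 8:28, 1] <- 500
  dna[32:44, 30:44, 1] <- 500
  cenpa <- array(0, dim)
  for (ctr in list(c(12, 12), c(24, 24), c(36, 36), c(40, 40))) {
    cenpa[ctr[1] + (-1:1), ctr[2] + (-1:1), 1] <- 1000
  }
  st <- image_stack(list(dna = dna, cenpa = cenpa), 65, 200)
  rec <- count_cenpa_foci(st, merge_radius = 3)
  # oracle: brute-force thresholds, flood fill, centroid membership
  dsl <- dna[, , 1]
  csl <- cenpa[, , 1]
  dmask <- dsl > oracle_otsu(dsl)
  cmask <- csl > oracle_otsu(csl)
  dlab <- oracle_flood_fill(dmask)
  clab <- oracle_flood_fill(cmask)
  counts <- integer(max(dlab))
  for (l in seq_len(max(clab))) {
    pos <- which(clab == l, arr.ind = TRUE)
    cy <- round(mean(pos[, 1]))
    cx <- round(mean(pos[, 2]))
    ml <- dlab[cy, cx]
    if (ml > 0) counts[ml] <- counts[ml] + 1L
  }
  expect_equal(sum(rec$n_foci), sum(counts))
  expect_equal(sort(rec$n_foci), sort(counts))
})

test_that("individualization frequency is the percent of < 4-foci masses", {
  rec <- tibble::tibble(
    n_foci = c(1, 2, 5, 9),
    individualized = c(TRUE, TRUE, FALSE, FALSE)
  )
  expect_equal(individualization_frequency(rec)$pct_individualized, 50)
  all_ind <- tibble::tibble(individualized = rep(TRUE, 7))
  expect_equal(individualization_frequency(all_ind)$pct_individualized, 100)
  expect_error(individualization_frequency(all_ind[0, ]), "no mass records")
  # per-replicate when replicate ids are present
  rep2 <- tibble::tibble(
    replicate = c(1, 1, 2, 2),
    individualized = c(TRUE, FALSE, TRUE, TRUE)
  )
  f <- individualization_frequency(rep2)
  expect_equal(f$pct_individualized, c(50, 100))
})
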