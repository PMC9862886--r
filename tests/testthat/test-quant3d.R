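# volumetry, surface extraction, neck-cut plane, trimming, composition

test_that("voxel volumetry: single voxel, symmetry, conservation", {
  a <- array(0L, c(4, 4, 4)); a[2, 2, 2] <- 2L
  v <- compute_volumes(make_vol(a, rep(0.8, 3)))
  expect_equal(v$necrotic_volume, 0.8^3 / 1000, tolerance = 1e-15)
  expect_equal(v$necrotic_volume, 0.000512)
  expect_equal(v$pct_necrotic_volume, 100)

  b <- array(0L, c(4, 4, 4)); b[1:2, , ] <- 1L; b[3:4, , ] <- 2L
  expect_identical(compute_volumes(make_vol(b))$pct_necrotic_volume, 50)

  vol <- std_phantom()$volume
  v <- compute_volumes(vol)
  expect_identical(v$necrotic_volume + v$unaffected_volume,
                   sum(vol$labels > 0L) * prod(vol$spacing) / 1000)
  expect_error(compute_volumes(make_vol(array(0L, c(3, 3, 3)))),
               "empty foreground")
})

test_that("surface area of a digital cube is near 600 mm^2 (voxel-face oracle exact)", {
  a <- array(0L, c(16, 16, 16)); a[4:13, 4:13, 4:13] <- 1L
  vol <- make_vol(a)
  expect_identical(voxel_face_area(vol), 600)   # independent brute-force oracle
  mesh <- extract_surface(vol)
  expect_lt(abs(sum(mesh$areas) - 600) / 600, 0.12)
})

test_that("sphere surface area is recovered within 5% and has no flat cut", {
  vol <- make_sphere_vol(R = 25)
  mesh <- extract_surface(vol)
  expect_lt(abs(sum(mesh$areas) - 4 * pi * 25^2) / (4 * pi * 25^2), 0.05)
  expect_error(fit_neck_cut_plane(mesh), "no flat neck cut")
})

test_that("face labels: lesion-free phantom has no necrotic faces; cap is labelled", {
  ph0 <- generate_phantom(phantom_spec(wedge_half_angle = 0, head_radius = 22))
  mesh0 <- extract_surface(ph0$volume)
  expect_false(any(mesh0$face_label == 2L))

  mesh <- extract_surface(std_phantom()$volume)
  nec_area <- sum(mesh$areas[mesh$face_label == 2L])
  truth_cap <- std_phantom()$truth$necrotic_surface * 100
  expect_lt(abs(nec_area - truth_cap) / truth_cap, 0.05)
})

test_that("neck-cut plane is recovered within tolerance on phantoms", {
  ph <- std_phantom()            # cut at d = 15 mm below centre, normal +z
  mesh <- extract_surface(ph$volume)
  pl <- fit_neck_cut_plane(mesh)
  ang <- acos(abs(sum(pl$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 3)
  # plane point projected on the axis sits within one voxel of z = -d
  expect_lt(abs(sum(pl$point * pl$normal) / pl$normal[3] - (-15)), 0.8)
  expect_gt(pl$inlier_fraction, 0.02)
  expect_lt(pl$rms_residual, 0.5)
})

test_that("near-ties between flat regions prefer the lower-RMS plane", {
  # two parallel square patches of equal face count at z = 0 (exact) and
  # z = 10 (jittered); both normals +z
  sq <- function(z0, jitter) {
    g <- expand.grid(x = 0:10, y = 0:10)
    vid <- function(i, j) i + 1 + 11 * j
    tris <- do.call(rbind, lapply(0:9, function(j) do.call(rbind,
      lapply(0:9, function(i) rbind(c(vid(i, j), vid(i + 1, j), vid(i, j + 1)),
                                    c(vid(i + 1, j), vid(i + 1, j + 1),
                                      vid(i, j + 1)))))))
    set.seed(9)
    V <- cbind(g$x, g$y, z0 + if (jitter) rnorm(nrow(g), 0, 0.15) else 0)
    list(V = V, F = tris)
  }
  a <- sq(0, FALSE); b <- sq(10, TRUE)
  V <- rbind(a$V, b$V); Fc <- rbind(a$F, b$F + nrow(a$V))
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(Fc)), ncol = 3)
  mesh <- fhnquant:::.new_surface_mesh(V, Fc, rep(1L, nrow(Fc)), nrm)
  pl <- fit_neck_cut_plane(mesh, min_support = 0.1)
  expect_lt(pl$rms_residual, 0.05)
  expect_lt(abs(sum(pl$point * pl$normal)), 0.5)   # the exact z = 0 plane won
})

test_that("trimming: identity far away, monotone, zone area, total-removal error", {
  mesh <- extract_surface(std_phantom()$volume)
  far <- structure(list(point = c(0, 0, -500), normal = c(0, 0, 1)),
                   class = "cut_plane")
  expect_equal(sum(trim_mesh(mesh, far, margin = 0)$areas), sum(mesh$areas))

  pl <- fit_neck_cut_plane(mesh)
  tm <- trim_mesh(mesh, pl, margin = 3)
  expect_lt(sum(tm$areas), sum(mesh$areas))
  # exact spherical-zone closed form for the remaining area:
  # 2 pi R (R + d - margin) with R = 25, d = 15, margin = 3
  zone <- 2 * pi * 25 * (25 + 15 - 3)
  expect_lt(abs(sum(tm$areas) - zone) / zone, 0.05)
  tm1 <- trim_mesh(mesh, pl, margin = 1)
  expect_gt(sum(tm1$areas), sum(tm$areas))  # smaller margin keeps more

  expect_error(trim_mesh(mesh, far, margin = 1e6), "removed all faces")
})

test_that("quantify_case composes, is deterministic, and degrades to no-trim", {
  m1 <- quantify_case(std_phantom()$volume)
  m2 <- quantify_case(std_phantom()$volume)
  expect_identical(unclass(m1)[names(m1)], unclass(m2)[names(m2)])
  expect_lte(m1$necrotic_surface, m1$head_surface)
  expect_equal(m1$pct_necrotic_surface,
               100 * m1$necrotic_surface / m1$head_surface)
  prov <- attr(m1, "provenance")
  expect_true(prov$trim)
  expect_gt(prov$untrimmed_head_surface, m1$head_surface)

  # no flat cut anywhere -> warning, untrimmed surfaces
  sph <- make_sphere_vol(R = 20)
  ms <- quantify_case(sph)
  expect_match(paste(attr(ms, "provenance")$warnings, collapse = " "),
               "no flat neck cut")
  expect_equal(ms$head_surface, attr(ms, "provenance")$untrimmed_head_surface)

  # theta = 0: no necrosis anywhere in the metrics
  m0 <- quantify_case(generate_phantom(phantom_spec(wedge_half_angle = 0,
                                                    head_radius = 22))$volume)
  expect_equal(m0$necrotic_volume, 0)
  expect_equal(m0$necrotic_surface, 0)
  expect_equal(m0$pct_necrotic_volume, 0)
  expect_equal(m0$pct_necrotic_surface, 0)
})

test_that("metrics are invariant under grid translation", {
  ph <- std_phantom()
  shifted <- label_volume(ph$volume$labels, ph$volume$spacing,
                          ph$volume$origin + c(10.3, -5.7, 2.1), "shifted")
  m1 <- quantify_case(ph$volume)
  m2 <- quantify_case(shifted)
  for (f in names(unclass(m1)))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-8)
})

test_that("anisotropic 2D grid volumetry stays within 8% of truth", {
  for (theta in c(30, 55)) {
    ph <- generate_phantom(phantom_spec(head_radius = 24,
                                        wedge_half_angle = theta,
                                        grid = "aniso2d"))
    v <- compute_volumes(ph$volume)
    expect_lt(abs(v$necrotic_volume - ph$truth$necrotic_volume) /
                ph$truth$necrotic_volume, 0.08)
  }
})
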