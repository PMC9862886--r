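#' Phantom specification
#'
#' Describes a voxel phantom of a segmented femoral head: a sphere of radius
#' `head_radius` whose necrotic lesion is a spherical sector (cone with apex
#' at the head centre) of half-angle `wedge_half_angle` about `wedge_axis`
#' (default superior), with the segmentation ending at a flat neck-cut plane
#' at distance `cut_distance` below the centre along `-wedge_axis`, plus a
#' short neck stub (cylinder of radius `neck_radius`, depth `stub_depth`)
#' kept below the cut so the plane-fit has a flat region to find. The
#' spherical-sector lesion is chosen because its volume, outer cap area and
#' per-plane arc angle all have closed forms, giving the whole pipeline an
#' analytic oracle.
#'
#' Two grid dialects are supported: `"iso3d"`, a near-isotropic 0.8 mm grid
#' emulating a high-resolution 3D sequence, and `"aniso2d"`, the fixed
#' 160 x 30 x 160 voxel grid at 0.44 x 2.4 x 0.44 mm emulating a cropped
#' coronal 2D acquisition.
#'
#' @param head_radius sphere radius R, mm (typical femoral head 20-30 mm).
#' @param wedge_half_angle lesion half-angle theta, degrees, in \[0, 90\].
#' @param wedge_axis unit direction of the lesion axis; default superior
#'   `c(0, 0, 1)`.
#' @param cut_distance distance d from head centre to the neck-cut plane
#'   along `-wedge_axis`, mm; 0 < d < R. Default 0.6 R.
#' @param neck_radius neck stub radius, mm, < R. Default 0.45 R.
#' @param stub_depth depth of the neck stub below the cut plane, mm.
#' @param grid `"iso3d"` or `"aniso2d"`.
#' @param seed integer seed (reserved for stochastic extensions; the phantom
#'   itself is deterministic).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(head_radius = 25, wedge_half_angle = 45,
                         wedge_axis = c(0, 0, 1),
                         cut_distance = 0.6 * head_radius,
                         neck_radius = 0.45 * head_radius,
                         stub_depth = 3, grid = c("iso3d", "aniso2d"),
                         seed = 1L) {
  grid <- match.arg(grid)
  stopifnot(head_radius > 0,
            wedge_half_angle >= 0, wedge_half_angle <= 90,
            cut_distance > 0, cut_distance < head_radius,
            neck_radius > 0, neck_radius < head_radius,
            stub_depth >= 0, length(wedge_axis) == 3)
  nrm <- sqrt(sum(wedge_axis^2))
  if (nrm == 0) stop("wedge_axis must be a nonzero vector")
  structure(list(head_radius = head_radius,
                 wedge_half_angle = wedge_half_angle,
                 wedge_axis = wedge_axis / nrm,
                 cut_distance = cut_distance,
                 neck_radius = neck_radius,
                 stub_depth = stub_depth,
                 grid = grid, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Closed-form ground truth for a phantom
#'
#' Computes the six quantification parameters and the Kerboul angles from the
#' generative parameters. With R the head radius (mm), theta the lesion
#' half-angle and d the cut distance:
#' \itemize{
#'   \item necrotic volume \eqn{= (2/3)\pi R^3 (1-\cos\theta)},
#'   \item necrotic surface (outer cap) \eqn{= 2\pi R^2 (1-\cos\theta)},
#'   \item head surface after the trim
#'     \eqn{= 2\pi R (R + d - \mathrm{margin})} (the spherical zone that
#'     survives removing everything within `trim_margin` of the cut plane),
#'   \item unaffected volume = above-plane sphere volume minus the lesion,
#'     plus the neck stub cylinder.
#' }
#' For an axisymmetric superior lesion the coronal and sagittal Kerboul arcs
#' are each \eqn{2\theta} and the modified angle \eqn{4\theta}; for a tilted
#' `wedge_axis` the Kerboul truths are reported as `NA`.
#'
#' @param spec a [phantom_spec()].
#' @param trim_margin trim margin used by the surface protocol, mm.
#' @return An object of class `phantom_truth`; volumes in cm^3, surfaces in
#'   cm^2, percentages on 0-100, angles in degrees.
#' @export
phantom_truth <- function(spec, trim_margin = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- spec$head_radius
  th <- spec$wedge_half_angle * pi / 180
  d <- spec$cut_distance
  vn <- 2 / 3 * pi * R^3 * (1 - cos(th))                 # mm^3
  h <- R + d                                             # above-plane cap height
  v_above <- pi * h^2 * (3 * R - h) / 3
  v_stub <- pi * spec$neck_radius^2 * spec$stub_depth
  vu <- v_above - vn + v_stub
  sn <- 2 * pi * R^2 * (1 - cos(th))                     # mm^2
  sh <- 2 * pi * R * (R + d - trim_margin)               # trimmed zone
  axisym <- isTRUE(all.equal(as.numeric(spec$wedge_axis), c(0, 0, 1),
                             tolerance = 1e-8))
  ang <- if (axisym) 2 * spec$wedge_half_angle else NA_real_
  structure(list(
    necrotic_volume = vn / 1000, unaffected_volume = vu / 1000,
    pct_necrotic_volume = 100 * vn / (vn + vu),
    necrotic_surface = sn / 100, head_surface = sh / 100,
    pct_necrotic_surface = 100 * sn / sh,
    kerboul_coronal = ang, kerboul_sagittal = ang,
    kerboul_modified = if (axisym) 4 * spec$wedge_half_angle else NA_real_),
    class = "phantom_truth")
}

.phantom_grid <- function(spec) {
  R <- spec$head_radius
  pad <- 4                       # mm of background margin around the head
  if (spec$grid == "iso3d") {
    sp <- c(0.8, 0.8, 0.8)
    n <- ceiling(2 * (R + pad) / sp) + 1
  } else {
    sp <- c(0.44, 2.4, 0.44)
    n <- c(160L, 30L, 160L)
    ext <- n * sp
    need <- 2 * (R + 1)
    if (any(ext < need))
      stop(sprintf(paste0("grid too small for head radius %.1f mm: aniso2d ",
                          "extent is %.1f x %.1f x %.1f mm, need >= %.1f mm ",
                          "per axis"), R, ext[1], ext[2], ext[3], need))
  }
  # head centre at world (0,0,0); voxel centres straddle it symmetrically
  origin <- -(n - 1) / 2 * sp
  list(n = as.integer(n), spacing = sp, origin = origin)
}

#' Generate a voxel phantom with analytic ground truth
#'
#' Voxelises the phantom described by `spec` on its grid dialect by the
#' voxel-centre membership test (no partial-volume weighting, matching binary
#' manual label maps): a voxel is necrotic iff its centre lies inside the
#' sphere, above the cut plane, and within `wedge_half_angle` of the wedge
#' axis from the head centre; it is unaffected bone iff inside the
#' sphere-above-plane (outside the lesion) or inside the neck stub cylinder
#' below the plane. The head centre sits at world (0, 0, 0).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [label_volume()]), `truth`
#'   (a [phantom_truth()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- .phantom_grid(spec)
  n <- g$n; sp <- g$spacing; or <- g$origin
  xs <- or[1] + (seq_len(n[1]) - 1) * sp[1]
  ys <- or[2] + (seq_len(n[2]) - 1) * sp[2]
  zs <- or[3] + (seq_len(n[3]) - 1) * sp[3]
  ax <- spec$wedge_axis
  R <- spec$head_radius; d <- spec$cut_distance
  if (isTRUE(all.equal(ax, c(0, 0, 1), tolerance = 1e-12))) {
    # fast path for the default superior axis: broadcast squared radii
    r2xy <- outer(xs^2, ys^2, `+`)
    r2 <- outer(r2xy, zs^2, `+`)
    dot <- array(rep(zs, each = n[1] * n[2]), dim = n)
  } else {
    X <- array(xs, dim = n)
    Y <- array(rep(ys, each = n[1]), dim = n)
    Z <- array(rep(zs, each = n[1] * n[2]), dim = n)
    r2 <- X^2 + Y^2 + Z^2
    dot <- ax[1] * X + ax[2] * Y + ax[3] * Z
  }
  inside <- r2 <= R^2
  above <- dot >= -d
  costh <- cos(spec$wedge_half_angle * pi / 180)
  wedge <- if (spec$wedge_half_angle > 0) dot >= costh * sqrt(r2) else
    array(FALSE, dim = n)
  stub <- (r2 - dot^2 <= spec$neck_radius^2) &
    dot < -d & dot >= -d - spec$stub_depth
  lab <- array(0L, dim = n)
  lab[(inside & above) | stub] <- 1L
  lab[inside & above & wedge] <- 2L
  vol <- label_volume(lab, spacing = sp, origin = or,
                      case_id = sprintf("phantom_R%g_t%g_%s", R,
                                        spec$wedge_half_angle, spec$grid))
  list(volume = vol, truth = phantom_truth(spec), spec = spec)
}

#' Segmentation-noise specification
#'
#' Target Dice levels for emulating the disagreement between a manual and an
#' automatic segmentation. Defaults are the calibration levels 0.75
#' (necrotic) and 0.91 (unaffected bone).
#'
#' @param target_dice_necrotic,target_dice_unaffected target Dice in (0, 1].
#' @param seed integer seed for the noise fields.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(target_dice_necrotic = 0.75,
                       target_dice_unaffected = 0.91, seed = 1L) {
  stopifnot(target_dice_necrotic > 0, target_dice_necrotic <= 1,
            target_dice_unaffected > 0, target_dice_unaffected <= 1)
  structure(list(target_dice_necrotic = target_dice_necrotic,
                 target_dice_unaffected = target_dice_unaffected,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

.dice_bin <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Perturb a segmentation to a target Dice level
#'
#' Emulates automatic-segmentation disagreement by displacing the foreground
#' and necrotic boundaries with a smooth random field: each boundary is
#' represented by its Gaussian-smoothed indicator, a correlated noise field
#' is added, and the 0.5 level set is re-thresholded. Changes are confined to
#' a band around the original boundary. The noise amplitudes are calibrated
#' by bisection so the achieved per-label Dice against the input is within
#' 0.05 of the targets; the perturbation is deterministic given
#' `noise$seed`. Grid geometry is never altered.
#'
#' @param vol a quantifiable [label_volume()].
#' @param noise a [noise_spec()]. Targets of exactly 1 leave the
#'   corresponding boundary untouched.
#' @return A perturbed [label_volume()] on the same grid; achieved Dice
#'   values are attached as attribute `achieved_dice`.
#' @export
perturb_segmentation <- function(vol, noise) {
  stopifnot(inherits(vol, "label_volume"), inherits(noise, "noise_spec"))
  if (!is_quantifiable(vol)) stop("volume not quantifiable")
  FG <- vol$labels > 0L
  NE <- vol$labels == 2L
  t_n <- noise$target_dice_necrotic
  t_u <- noise$target_dice_unaffected
  if (t_n == 1 && t_u == 1) {
    out <- vol
    attr(out, "achieved_dice") <- c(necrotic = 1, unaffected = 1)
    return(out)
  }
  if (t_n < 1 && !any(NE))
    stop("target Dice ", t_n, " for the necrotic label is unreachable: ",
         "volume has no necrotic voxels")
  d <- dim(vol$labels)
  calibrate <- function(sig_s) {
    # sig_s controls the boundary-band half-width; small structures may need a
    # wider band before the target Dice becomes reachable
    sm <- function(m) cpp_gaussian_smooth(m + 0, as.integer(d), rep(sig_s, 3))
    smF <- sm(FG); smN <- sm(NE)
    eta <- with_seed(noise$seed, {
      e1 <- cpp_gaussian_smooth(array(rnorm(prod(d)), d), as.integer(d), rep(2, 3))
      e2 <- cpp_gaussian_smooth(array(rnorm(prod(d)), d), as.integer(d), rep(2, 3))
      list(F = e1 / sd(e1), N = e2 / sd(e2))
    })
    bandF <- smF > 0.01 & smF < 0.99
    bandN <- smN > 0.01 & smN < 0.99
    pert <- function(mask, smoothed, band, field, a) {
      if (a == 0) return(mask)
      out <- mask
      out[band] <- (smoothed[band] + a * field[band]) > 0.5
      out
  }
  labs_for <- function(aF, aN) {
    F2 <- pert(FG, smF, bandF, eta$F, aF)
    N2 <- pert(NE, smN, bandN, eta$N, aN) & F2
    list(F = F2, N = N2)
  }
  dice_pair <- function(aF, aN) {
    m <- labs_for(aF, aN)
    c(nec = .dice_bin(NE, m$N), una = .dice_bin(FG & !NE, m$F & !m$N))
  }
  bisect <- function(f, target) {
    # f decreasing in a; find a with f(a) ~ target on [0, amax]
    lo <- 0; hi <- 4
    flo <- f(lo)
    if (flo < target - 0.05)
      stop("target Dice ", target, " unreachable (baseline already below)")
    fhi <- f(hi)
    if (fhi > target) return(hi)     # saturates above target; best effort
    for (it in 1:22) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target) < 0.005) return(mid)
      if (fm > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  aF <- 0; aN <- 0
  if (t_u < 1) aF <- bisect(function(a) dice_pair(a, 0)["una"], t_u)
  if (t_n < 1) aN <- bisect(function(a) dice_pair(aF, a)["nec"], t_n)
  if (t_u < 1) aF <- bisect(function(a) dice_pair(a, aN)["una"], t_u)
  ach <- dice_pair(aF, aN)
  list(ok = !((t_n < 1 && abs(ach["nec"] - t_n) > 0.05) ||
                (t_u < 1 && abs(ach["una"] - t_u) > 0.05)),
       masks = labs_for(aF, aN), achieved = ach)
  }
  cal <- NULL
  for (sig_s in c(2, 3.5)) {
    cal <- calibrate(sig_s)
    if (cal$ok) break
  }
  ach <- cal$achieved
  if (!cal$ok)
    stop(sprintf(paste0("could not calibrate noise to targets (%.2f, %.2f); ",
                        "achieved (%.3f, %.3f)"),
                 t_n, t_u, ach["nec"], ach["una"]))
  m <- cal$masks
  lab <- array(0L, dim = d)
  lab[m$F] <- 1L
  lab[m$N] <- 2L
  out <- label_volume(lab, spacing = vol$spacing, origin = vol$origin,
                      case_id = paste0(vol$case_id, "_auto"))
  attr(out, "achieved_dice") <- c(necrotic = unname(ach["nec"]),
                                  unaffected = unname(ach["una"]))
  out
}

#' Cohort specification
#'
#' Parameters for a synthetic early/advanced cohort. Lesion half-angles are
#' drawn uniformly within each group's range; the advanced range must
#' dominate the early range so advanced lesions are stochastically larger.
#' Default ranges (15-30 degrees early, 35-65 degrees advanced) put the
#' group median necrotic volumes near the 2 and 9 cm^3 scale of a clinical
#' early/advanced split for 20-30 mm heads. ARCO grades are allocated in the
#' proportions 2:4 (I:II) within the early group and 13:11 (IIIA:IIIB)
#' within the advanced group.
#'
#' @param n_early,n_advanced group sizes (default 6 and 24).
#' @param theta_range_early,theta_range_advanced lesion half-angle intervals,
#'   degrees.
#' @param R_range head-radius interval, mm.
#' @param grid grid dialect for the generated volumes.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_early = 6, n_advanced = 24,
                        theta_range_early = c(15, 30),
                        theta_range_advanced = c(35, 65),
                        R_range = c(20, 30),
                        grid = c("iso3d", "aniso2d"), seed = 1L) {
  grid <- match.arg(grid)
  stopifnot(n_early >= 0, n_advanced >= 0, n_early + n_advanced > 0,
            length(theta_range_early) == 2, length(theta_range_advanced) == 2,
            length(R_range) == 2,
            diff(theta_range_early) >= 0, diff(theta_range_advanced) >= 0,
            diff(R_range) >= 0)
  if (theta_range_advanced[1] < theta_range_early[1] ||
      theta_range_advanced[2] < theta_range_early[2])
    stop("theta_range_advanced must dominate theta_range_early")
  structure(list(n_early = as.integer(n_early),
                 n_advanced = as.integer(n_advanced),
                 theta_range_early = theta_range_early,
                 theta_range_advanced = theta_range_advanced,
                 R_range = R_range, grid = grid, seed = as.integer(seed)),
            class = "cohort_spec")
}

.allocate_grades <- function(n, grades, weights) {
  if (n == 0) return(character(0))
  target <- n * weights / sum(weights)
  counts <- floor(target)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(target - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  rep(grades, counts)
}

#' Generate a synthetic early/advanced cohort
#'
#' Draws one phantom per case with group-specific lesion sizes and allocates
#' ARCO grades (I/II early, IIIA/IIIB advanced) in the study-like imbalance
#' proportions. Deterministic given `cohort$seed`.
#'
#' @param cohort a [cohort_spec()].
#' @return A list of cases, each a list with `record` ([case_record()]),
#'   `volume` ([label_volume()]), `truth` ([phantom_truth()]) and `spec`
#'   ([phantom_spec()]).
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  grades <- c(.allocate_grades(cohort$n_early, c("I", "II"), c(2, 4)),
              .allocate_grades(cohort$n_advanced, c("IIIA", "IIIB"), c(13, 11)))
  n <- length(grades)
  draws <- with_seed(cohort$seed, {
    lapply(seq_len(n), function(i) {
      early <- grades[i] %in% c("I", "II")
      rng <- if (early) cohort$theta_range_early else cohort$theta_range_advanced
      list(theta = stats::runif(1, rng[1], rng[2]),
           R = stats::runif(1, cohort$R_range[1], cohort$R_range[2]))
    })
  })
  lapply(seq_len(n), function(i) {
    id <- sprintf("case%03d", i)
    spec <- phantom_spec(head_radius = draws[[i]]$R,
                         wedge_half_angle = draws[[i]]$theta,
                         grid = cohort$grid,
                         seed = cohort$seed + i)
    ph <- generate_phantom(spec)
    ph$volume$case_id <- id
    list(record = case_record(id, grades[i], "manual3d"),
         volume = ph$volume, truth = ph$truth, spec = spec)
  })
}
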