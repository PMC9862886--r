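# Modified Kerboul angle: head-sphere fit, mid-plane slice selection, and
# necrotic arc measurement at the head centre.

.surface_voxel_coords <- function(vol) {
  lab <- vol$labels
  d <- dim(lab)
  fg <- lab > 0L
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- which(fg & !nb, arr.ind = TRUE)
  sweep(sweep(surf - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Fit a sphere to the femoral head surface
#'
#' Algebraic least-squares sphere fit to the external foreground surface
#' voxels (foreground voxels with at least one 6-neighbour background
#' voxel). When a neck-cut plane is supplied, voxels within `margin` mm of
#' it are excluded so the flat cut and neck stub do not bias the fit; when
#' `plane` is `NULL` the plane is first fitted from the extracted surface
#' and the fit falls back to all surface voxels if no flat cut is found.
#'
#' @param vol a quantifiable [label_volume()].
#' @param plane optional `cut_plane`; `NULL` fits one internally.
#' @param margin exclusion margin around the plane, mm.
#' @return A `head_fit`: `center` (mm), `radius` (mm), `rms_residual` (mm)
#'   and `n_points`.
#' @export
fit_head_sphere <- function(vol, plane = NULL, margin = 3) {
  stopifnot(inherits(vol, "label_volume"))
  if (!is_quantifiable(vol)) stop("volume not quantifiable")
  P <- .surface_voxel_coords(vol)
  if (is.null(plane)) {
    plane <- tryCatch(fit_neck_cut_plane(extract_surface(vol)),
                      error = function(e) NULL)
  }
  if (!is.null(plane)) {
    n0 <- plane$normal / sqrt(sum(plane$normal^2))
    s <- abs(as.vector(P %*% n0) - sum(plane$point * n0))
    keep <- s > margin
    if (sum(keep) >= 20) P <- P[keep, , drop = FALSE]
  }
  if (nrow(P) < 10) stop("too few surface points for a sphere fit")
  sv <- svd(sweep(P, 2, colMeans(P)), nu = 0, nv = 3)
  if (sv$d[3] < 1e-6 * sv$d[1])
    stop("degenerate geometry: surface points are coplanar")
  A <- cbind(2 * P, 1)
  y <- rowSums(P^2)
  beta <- qr.coef(qr(A), y)
  ctr <- beta[1:3]
  rad <- sqrt(beta[4] + sum(ctr^2))
  dists <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  structure(list(center = unname(ctr), radius = unname(rad),
                 rms_residual = sqrt(mean((dists - rad)^2)),
                 n_points = nrow(P)),
            class = "head_fit")
}

#' Necrotic arc angle in a mid-plane slice
#'
#' Implements the per-plane arc of the modified Kerboul measurement: the
#' single slice nearest the fitted head centre is selected perpendicular to
#' the anterior-posterior axis (`"coronal"`) or the left-right axis
#' (`"sagittal"`); the external head-boundary points of that slice carrying
#' the necrotic label are collected; and the angle of the smallest circular
#' sector with vertex at the head centre containing all of them is returned.
#' Polar angles are binned at 0.5 degrees and the span is the complement of
#' the largest empty gap, with ties resolved towards the larger span. A
#' slice with no necrotic boundary points yields 0.
#'
#' @param vol a quantifiable [label_volume()].
#' @param head a `head_fit` from [fit_head_sphere()].
#' @param plane_axis `"coronal"` or `"sagittal"`.
#' @return Angle in degrees, in \[0, 360\].
#' @export
necrotic_arc_angle <- function(vol, head,
                               plane_axis = c("coronal", "sagittal")) {
  stopifnot(inherits(vol, "label_volume"), inherits(head, "head_fit"))
  plane_axis <- match.arg(plane_axis)
  d <- dim(vol$labels)
  perp <- if (plane_axis == "coronal") 2L else 1L   # AP axis vs LR axis
  idx0 <- (head$center - vol$origin) / vol$spacing  # 0-based continuous index
  if (any(idx0 < -0.5) || any(idx0 > d - 0.5))
    stop("head centre lies outside the grid")
  k <- round(idx0[perp]) + 1
  k <- min(max(k, 1), d[perp])
  inplane <- setdiff(1:3, perp)
  sl <- switch(perp, vol$labels[k, , ], vol$labels[, k, ], vol$labels[, , k])
  # external boundary in-slice: necrotic cells with a 4-neighbour background
  ds <- dim(sl)
  pad <- matrix(0L, ds[1] + 2, ds[2] + 2)
  pad[2:(ds[1] + 1), 2:(ds[2] + 1)] <- sl
  bg4 <- (pad[1:ds[1], 2:(ds[2] + 1)] == 0L) |
         (pad[3:(ds[1] + 2), 2:(ds[2] + 1)] == 0L) |
         (pad[2:(ds[1] + 1), 1:ds[2]] == 0L) |
         (pad[2:(ds[1] + 1), 3:(ds[2] + 2)] == 0L)
  pts <- which(sl == 2L & bg4, arr.ind = TRUE)
  if (nrow(pts) == 0) return(0)
  su <- vol$spacing[inplane[1]]; sv <- vol$spacing[inplane[2]]
  u <- vol$origin[inplane[1]] + (pts[, 1] - 1) * su - head$center[inplane[1]]
  v <- vol$origin[inplane[2]] + (pts[, 2] - 1) * sv - head$center[inplane[2]]
  # the lesion's in-slice extent is the union of the boundary voxels' square
  # footprints, so measure the span over each voxel's corners, not its centre
  uc <- c(u - su / 2, u + su / 2, u - su / 2, u + su / 2)
  vc <- c(v - sv / 2, v - sv / 2, v + sv / 2, v + sv / 2)
  deg <- (atan2(vc, uc) * 180 / pi) %% 360
  bins <- sort(unique(floor(deg / 0.5)))
  if (length(bins) == 1) return(0.5)
  gaps <- c(diff(bins), bins[1] + 720 - bins[length(bins)])
  span_bins <- 720 - max(gaps) + 1
  span_bins * 0.5
}

#' Modified Kerboul angle of a label volume
#'
#' Sum of the necrotic arc angles in the midcoronal and midsagittal planes,
#' measured at the fitted femoral head centre. Deterministic.
#'
#' @param vol a quantifiable [label_volume()].
#' @param margin neck-plane exclusion margin for the head-sphere fit, mm.
#' @return A `kerboul_measurement`: `coronal_angle`, `sagittal_angle`,
#'   `modified_angle` (their exact sum, degrees), plus the `head_fit` used.
#' @export
modified_kerboul <- function(vol, margin = 3) {
  head <- fit_head_sphere(vol, margin = margin)
  cor_a <- necrotic_arc_angle(vol, head, "coronal")
  sag_a <- necrotic_arc_angle(vol, head, "sagittal")
  structure(list(coronal_angle = cor_a, sagittal_angle = sag_a,
                 modified_angle = cor_a + sag_a, head = head),
            class = "kerboul_measurement")
}

#' @export
print.kerboul_measurement <- function(x, ...) {
  cat(sprintf("<kerboul> coronal %.1f + sagittal %.1f = %.1f degrees\n",
              x$coronal_angle, x$sagittal_angle, x$modified_angle))
  invisible(x)
}
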