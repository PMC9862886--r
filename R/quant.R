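# Surface-based quantification: volumetry, isosurface extraction, neck-cut
# plane fitting, 3 mm trim, and the six necrosis parameters.

#' Voxel volumetry of a label volume
#'
#' Volume per label is the voxel count times the voxel volume
#' (sx * sy * sz), reported in cm^3. The percentage is
#' 100 * necrotic / (necrotic + unaffected).
#'
#' @param vol a quantifiable [label_volume()].
#' @return A list with `necrotic_volume`, `unaffected_volume` (cm^3) and
#'   `pct_necrotic_volume`.
#' @export
compute_volumes <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  tab <- tabulate(vol$labels + 1L, nbins = 3L)
  if (tab[2] + tab[3] == 0) stop("empty foreground: nothing to quantify")
  vox_mm3 <- prod(vol$spacing)
  vn <- tab[3] * vox_mm3 / 1000
  vu <- tab[2] * vox_mm3 / 1000
  list(necrotic_volume = vn, unaffected_volume = vu,
       pct_necrotic_volume = if (vn + vu > 0) 100 * vn / (vn + vu) else 0)
}

.mesh_derived <- function(V, faces) {
  # per-face areas (mm^2) and centroids from a vertex matrix + index triples
  a <- V[faces[, 1], , drop = FALSE]
  b <- V[faces[, 2], , drop = FALSE]
  c_ <- V[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  list(areas = 0.5 * sqrt(cx^2 + cy^2 + cz^2), centroids = (a + b + c_) / 3)
}

.new_surface_mesh <- function(vertices, faces, face_label, normals,
                              spacing = NULL, warnings = character(0),
                              derived = NULL) {
  if (is.null(derived)) derived <- .mesh_derived(vertices, faces)
  structure(list(vertices = vertices, faces = faces,
                 face_label = as.integer(face_label), normals = normals,
                 areas = derived$areas, centroids = derived$centroids,
                 spacing = spacing, warnings = warnings),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d faces, total area %.1f mm^2 (necrotic %.1f)\n",
              nrow(x$faces), sum(x$areas),
              sum(x$areas[x$face_label == 2L])))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Extract the outer bone surface as a labelled triangle mesh
#'
#' Triangulates the 0.5-level isosurface of the foreground (labels > 0) in
#' world coordinates. The binary indicator is first smoothed with a small
#' Gaussian so the triangulated surface tracks
#' the true boundary rather than the voxel staircase; marching tetrahedra
#' then yields a watertight triangulation with outward normals. Each face is
#' labelled 2 iff the blurred necrotic tissue fraction holds the majority
#' just beneath it, so the
#' necrotic surface is the externally visible portion of the bone surface
#' overlying the lesion - the internal necrotic/unaffected interface is not
#' part of the mesh.
#'
#' @param vol a quantifiable [label_volume()].
#' @param smooth_vox Gaussian sigma in voxels applied per axis before
#'   isosurfacing.
#' @param attr_smooth_vox Gaussian sigma in voxels for the tissue-attribution
#'   fields; wider than `smooth_vox` so rim quantization noise averages out.
#' @return A `surface_mesh`: `vertices` (mm), `faces` (index triples),
#'   `face_label`, per-face `normals`, `areas` (mm^2) and `centroids`. A
#'   warning finding is attached when the foreground touches the grid
#'   boundary (surface may be open there).
#' @export
extract_surface <- function(vol, smooth_vox = 0.7, attr_smooth_vox = 1.8) {
  stopifnot(inherits(vol, "label_volume"))
  findings <- validate_for_quantification(vol)
  if (!isTRUE(attr(findings, "quantifiable")))
    stop("volume not quantifiable: ", paste(findings, collapse = ", "))
  d <- dim(vol$labels)
  field <- cpp_gaussian_smooth((vol$labels > 0L) + 0, as.integer(d),
                               rep(smooth_vox, 3))
  mt <- cpp_march_tets(field, as.integer(d), vol$spacing, vol$origin, 0.5)
  nf <- nrow(mt$normals)
  if (nf == 0) stop("isosurface extraction produced no faces")
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  md <- list(areas = mt$areas, centroids = mt$centroids)
  # soft sub-voxel attribution: probe half a voxel inside the surface and
  # call a face necrotic where the blurred necrotic indicator holds the
  # majority of the blurred foreground - unbiased at the lesion rim (the
  # tissue interface meets the outer surface orthogonally), unlike a hard
  # nearest-voxel lookup on the staircase crust. The attribution blur is
  # wider than the isosurface blur so rim staircase noise averages out.
  depth <- 0.5 * abs(mt$normals) %*% vol$spacing
  probes <- md$centroids - mt$normals * as.vector(depth)
  fg_attr <- cpp_gaussian_smooth((vol$labels > 0L) + 0, as.integer(d),
                                 rep(attr_smooth_vox, 3))
  ne_attr <- cpp_gaussian_smooth((vol$labels == 2L) + 0, as.integer(d),
                                 rep(attr_smooth_vox, 3))
  fg_at <- cpp_sample_field(fg_attr, as.integer(d), vol$spacing, vol$origin,
                            probes)
  ne_at <- cpp_sample_field(ne_attr, as.integer(d), vol$spacing, vol$origin,
                            probes)
  lab <- ifelse(ne_at > 0.5 * pmax(fg_at, 1e-12), 2L, 1L)
  warn <- if ("foreground_touches_boundary" %in% findings)
    "foreground touches grid boundary; surface may be open there" else
      character(0)
  .new_surface_mesh(mt$vertices, faces, lab, mt$normals,
                    spacing = vol$spacing, warnings = warn, derived = md)
}

#' Fit the neck-cut plane of a femoral head mesh
#'
#' Finds the flat portion where the segmentation ends in the femoral neck by
#' a seeded consensus (RANSAC-style) search: candidate planes are seeded
#' from randomly chosen faces, and a face is an inlier when its normal
#' agrees with the candidate normal within `normal_tol_deg` and its centroid
#' is coplanar within `dist_tol`. The largest consensus cluster is refined
#' by a total-least-squares plane through its vertices; near-ties on support
#' are broken by lower RMS residual, then by larger supporting area. The
#' returned normal points towards the head side of the mesh.
#'
#' @param mesh a `surface_mesh` from [extract_surface()] (or built in code).
#' @param normal_tol_deg angular tolerance for normal agreement, degrees.
#' @param dist_tol coplanarity tolerance, mm; default 0.75 x max voxel
#'   spacing when the mesh carries spacing, else 0.6 mm.
#' @param min_support minimum fraction of faces the flat cluster must reach;
#'   below it the fit errors with "no flat neck cut found".
#' @param iters number of consensus draws.
#' @param seed seed for the (deterministic) candidate sampling.
#' @return A `cut_plane`: `point`, unit `normal`, `inlier_fraction`,
#'   `rms_residual` (mm) and `support_area` (mm^2).
#' @export
fit_neck_cut_plane <- function(mesh, normal_tol_deg = 10, dist_tol = NULL,
                               min_support = 0.02, iters = 100, seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nf <- nrow(mesh$faces)
  if (nf == 0) stop("empty mesh")
  if (is.null(dist_tol))
    dist_tol <- if (!is.null(mesh$spacing)) 0.75 * max(mesh$spacing) else 0.6
  cosmin <- cos(normal_tol_deg * pi / 180)
  C <- mesh$centroids; Nrm <- mesh$normals
  rng <- with_seed(seed, list(
    cand = sample.int(nf, size = min(iters, nf), replace = nf < iters),
    sub = if (nf > 30000L) sample.int(nf, 12000L) else seq_len(nf)))
  cand_idx <- rng$cand
  score <- function(p0, n0) {
    ndot <- Nrm %*% n0
    dd <- (C %*% n0) - sum(p0 * n0)
    which(ndot >= cosmin & abs(dd) <= dist_tol)
  }
  # candidate scoring runs on a face subsample for speed; refinement below
  # always uses the full mesh
  counts <- cpp_plane_score(C[rng$sub, , drop = FALSE],
                            Nrm[rng$sub, , drop = FALSE],
                            C[cand_idx, , drop = FALSE],
                            Nrm[cand_idx, , drop = FALSE], cosmin, dist_tol)
  counts <- counts * (nf / length(rng$sub))
  best <- max(counts)
  if (best < min_support * nf) stop("no flat neck cut found")
  refine <- function(fi) {
    inl <- score(C[fi, ], Nrm[fi, ])
    vid <- as.vector(mesh$faces[inl, , drop = FALSE])
    P <- mesh$vertices[vid, , drop = FALSE]
    fitp <- function(P) {
      ctr <- colMeans(P)
      Pc <- sweep(P, 2, ctr)
      # total-least-squares plane: smallest eigenvector of the 3x3 scatter
      n <- eigen(crossprod(Pc), symmetric = TRUE)$vectors[, 3]
      list(ctr = ctr, n = n, res = as.vector(Pc %*% n))
    }
    f1 <- fitp(P)
    n0 <- f1$n; ctr <- f1$ctr
    if (sum(n0 * Nrm[fi, ]) < 0) n0 <- -n0  # eigenvector sign is arbitrary
    inl2 <- score(ctr, n0)
    if (length(inl2) == 0) inl2 <- inl
    vid2 <- as.vector(mesh$faces[inl2, , drop = FALSE])
    P2 <- mesh$vertices[vid2, , drop = FALSE]
    f2 <- fitp(P2)
    ctr2 <- f2$ctr; n2 <- f2$n; res <- f2$res
    list(point = ctr2, normal = n2,
         count = length(inl2),
         rms = sqrt(mean(res^2)),
         area = sum(mesh$areas[inl2]),
         inlier_fraction = length(inl2) / nf)
  }
  # refine all candidates whose raw support is near the maximum, then pick by
  # (support desc within 2 %, rms asc, area desc)
  top <- which(counts >= 0.98 * best)
  top <- top[!duplicated(round(C[cand_idx[top], , drop = FALSE] %*%
                                 rep(1, 3) / dist_tol))]
  fits <- lapply(cand_idx[utils::head(top, 5)], refine)
  cmax <- max(vapply(fits, `[[`, 0, "count"))
  fits <- Filter(function(f) f$count >= 0.98 * cmax, fits)
  ord <- order(vapply(fits, `[[`, 0, "rms"),
               -vapply(fits, `[[`, 0, "area"))
  f <- fits[[ord[1]]]
  if (f$count < min_support * nf) stop("no flat neck cut found")
  # orient the normal towards the bulk (head side) of the mesh
  s <- as.vector((C %*% f$normal) - sum(f$point * f$normal))
  if (sum(mesh$areas[s > 0]) < sum(mesh$areas[s < 0])) f$normal <- -f$normal
  structure(list(point = f$point, normal = f$normal,
                 inlier_fraction = f$inlier_fraction,
                 rms_residual = f$rms, support_area = f$area),
            class = "cut_plane")
}

#' Trim a mesh at the neck-cut plane
#'
#' Removes every face whose centroid lies within `margin` mm of the plane
#' (unsigned distance) and every face strictly on the neck side, i.e. only
#' faces beyond `margin` on the head side survive. Face labels are
#' preserved. The head side is taken as the side holding the larger total
#' face area.
#'
#' @param mesh a `surface_mesh`.
#' @param plane a `cut_plane` from [fit_neck_cut_plane()].
#' @param margin trim margin, mm (default 3, the measurement protocol's
#'   value).
#' @return The trimmed `surface_mesh`.
#' @export
trim_mesh <- function(mesh, plane, margin = 3) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(plane, "cut_plane"),
            margin >= 0)
  n0 <- plane$normal / sqrt(sum(plane$normal^2))
  s <- as.vector((mesh$centroids %*% n0) - sum(plane$point * n0))
  if (sum(mesh$areas[s > margin]) < sum(mesh$areas[s < -margin])) s <- -s
  keep <- s > margin
  if (!any(keep)) stop("trimming removed all faces")
  .new_surface_mesh(mesh$vertices, mesh$faces[keep, , drop = FALSE],
                    mesh$face_label[keep], mesh$normals[keep, , drop = FALSE],
                    spacing = mesh$spacing, warnings = mesh$warnings,
                    derived = list(areas = mesh$areas[keep],
                                   centroids = mesh$centroids[keep, ,
                                                              drop = FALSE]))
}

#' Quantify one case: the six necrosis parameters
#'
#' Composes [compute_volumes()], [extract_surface()],
#' [fit_neck_cut_plane()] and [trim_mesh()]: the head surface is the total
#' area of the trimmed mesh, the necrotic surface the trimmed area of faces
#' overlying necrosis, and the two percentages follow. When no flat neck cut
#' is found the case degrades to no-trim mode with a recorded warning
#' instead of failing.
#'
#' @param vol a quantifiable [label_volume()].
#' @param margin trim margin, mm.
#' @param trim set `FALSE` to skip plane fitting and trimming entirely.
#' @param smooth_vox passed to [extract_surface()].
#' @return A `necrosis_metrics` object: `necrotic_volume`,
#'   `unaffected_volume` (cm^3), `pct_necrotic_volume`, `necrotic_surface`,
#'   `head_surface` (cm^2), `pct_necrotic_surface`; provenance (cut plane,
#'   untrimmed areas, the unaffected-only surface reading, warnings) in
#'   attribute `provenance`.
#' @export
quantify_case <- function(vol, margin = 3, trim = TRUE, smooth_vox = 0.7) {
  vols <- compute_volumes(vol)
  mesh <- extract_surface(vol, smooth_vox = smooth_vox)
  warnings <- mesh$warnings
  plane <- NULL
  untrimmed_total <- sum(mesh$areas)
  untrimmed_necrotic <- sum(mesh$areas[mesh$face_label == 2L])
  if (trim) {
    plane <- tryCatch(fit_neck_cut_plane(mesh), error = function(e) {
      if (grepl("no flat neck cut", conditionMessage(e))) NULL else stop(e)
    })
    if (is.null(plane))
      warnings <- c(warnings,
                    "no flat neck cut found; surfaces computed without trim")
    else mesh <- trim_mesh(mesh, plane, margin = margin)
  }
  head_mm2 <- sum(mesh$areas)
  nec_mm2 <- sum(mesh$areas[mesh$face_label == 2L])
  metrics <- structure(list(
    necrotic_volume = vols$necrotic_volume,
    unaffected_volume = vols$unaffected_volume,
    pct_necrotic_volume = vols$pct_necrotic_volume,
    necrotic_surface = nec_mm2 / 100,
    head_surface = head_mm2 / 100,
    pct_necrotic_surface = if (head_mm2 > 0) 100 * nec_mm2 / head_mm2 else 0),
    class = "necrosis_metrics")
  attr(metrics, "provenance") <- list(
    case_id = vol$case_id, margin = margin, trim = trim && !is.null(plane),
    plane = if (!is.null(plane)) plane[c("point", "normal", "inlier_fraction",
                                         "rms_residual")],
    untrimmed_head_surface = untrimmed_total / 100,
    untrimmed_necrotic_surface = untrimmed_necrotic / 100,
    unaffected_only_surface = (head_mm2 - nec_mm2) / 100,
    warnings = warnings)
  metrics
}

#' @export
print.necrosis_metrics <- function(x, ...) {
  cat(sprintf(paste0("<necrosis_metrics> Vn %.2f cm^3 | Vu %.2f cm^3 | ",
                     "%%Vn %.1f%% | Sn %.2f cm^2 | Sh %.2f cm^2 | %%Sn %.1f%%\n"),
              x$necrotic_volume, x$unaffected_volume, x$pct_necrotic_volume,
              x$necrotic_surface, x$head_surface, x$pct_necrotic_surface))
  w <- attr(x, "provenance")$warnings
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}
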