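#' Segmentation label volume
#'
#' The universal input container: a 3D integer label grid with voxel spacing
#' and world origin. Labels are fixed as 0 = background, 1 = unaffected
#' femoral bone, 2 = necrotic bone; files using other codings must be
#' remapped by the caller. World coordinates are millimetres with the
#' voxel-centre convention; `origin` is the world position of the centre of
#' voxel `[1, 1, 1]`. Axis 1 is left-to-right, axis 2 posterior-to-anterior,
#' axis 3 inferior-to-superior.
#'
#' @param labels 3D array of integers in \{0, 1, 2\}.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm; world position of the first voxel
#'   centre.
#' @param case_id character scalar identifying the case.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0),
                         case_id = "case") {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (is.double(labels)) {
    if (any(labels != round(labels), na.rm = TRUE))
      stop("non-integer voxel values in label volume")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) stop("`labels` must be integer-valued")
  if (anyNA(labels)) stop("NA voxel values in label volume")
  bad <- setdiff(unique(as.vector(labels)), 0:2)
  if (length(bad))
    stop("voxel values outside {0,1,2}: {", paste(sort(bad), collapse = ", "),
         "}")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(case_id = as.character(case_id)[1], labels = labels,
                 spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume '%s'> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("  background %d | unaffected %d | necrotic %d voxels\n",
              tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Validate a label volume for quantification
#'
#' Screens a volume for conditions that block or complicate quantification.
#' Returns findings rather than raising errors: an empty result means the
#' volume is quantifiable with no caveats.
#'
#' Findings:
#' \describe{
#'   \item{`no_foreground`}{no voxel is labelled 1 or 2; not quantifiable.}
#'   \item{`no_necrotic_voxels`}{quantifiable; all necrosis metrics will be 0.}
#'   \item{`foreground_touches_boundary`}{foreground reaches more than one
#'     face of the grid; neck-cut detection may be ambiguous (warning only).}
#' }
#'
#' @param vol a [label_volume()].
#' @return A character vector of finding codes with attribute `quantifiable`
#'   (logical).
#' @export
validate_for_quantification <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  lab <- vol$labels
  findings <- character(0)
  nfg <- sum(lab > 0L)
  if (nfg == 0L) {
    findings <- "no_foreground"
    attr(findings, "quantifiable") <- FALSE
    return(findings)
  }
  if (!any(lab == 2L)) findings <- c(findings, "no_necrotic_voxels")
  d <- dim(lab)
  faces <- c(any(lab[1, , ] > 0), any(lab[d[1], , ] > 0),
             any(lab[, 1, ] > 0), any(lab[, d[2], ] > 0),
             any(lab[, , 1] > 0), any(lab[, , d[3]] > 0))
  if (sum(faces) > 1L)
    findings <- c(findings, "foreground_touches_boundary")
  attr(findings, "quantifiable") <- TRUE
  findings
}

#' @rdname validate_for_quantification
#' @export
is_quantifiable <- function(vol) {
  isTRUE(attr(validate_for_quantification(vol), "quantifiable"))
}

#' Per-case clinical metadata record
#'
#' Holds the case identifier, ARCO grade, and segmentation source. The
#' early/advanced group is a pure function of the grade: grades I and II are
#' "early", IIIA and IIIB (post-collapse) are "advanced".
#'
#' @param case_id character scalar.
#' @param arco_grade one of `"I"`, `"II"`, `"IIIA"`, `"IIIB"`.
#' @param source one of `"manual3d"`, `"manual2d"`, `"auto2d"`.
#' @return An object of class `case_record` with derived field `group`.
#' @export
case_record <- function(case_id, arco_grade, source = "manual3d") {
  arco_grade <- match.arg(arco_grade, c("I", "II", "IIIA", "IIIB"))
  source <- match.arg(source, c("manual3d", "manual2d", "auto2d"))
  structure(list(case_id = as.character(case_id)[1],
                 arco_grade = arco_grade,
                 group = if (arco_grade %in% c("I", "II")) "early" else "advanced",
                 source = source),
            class = "case_record")
}
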