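# label-volume container, NIfTI round trips, validation, case records

test_that("label_volume validates values, spacing and shape", {
  expect_s3_class(make_vol(array(0L, c(2, 2, 2))), "label_volume")
  expect_error(label_volume(array(0L, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(make_vol(array(c(0, 1, 2, 3), c(1, 2, 2))), "\\{3\\}")
  expect_error(label_volume(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "non-integer")
  expect_error(label_volume(array(0L, c(2, 2, 2)), c(1, -1, 1)), "spacing")
})

test_that("validation findings cover empty, lesion-free and boundary cases", {
  f <- validate_for_quantification(make_vol(array(0L, c(4, 4, 4))))
  expect_identical(as.character(f), "no_foreground")
  expect_false(attr(f, "quantifiable"))

  nolesion <- generate_phantom(phantom_spec(wedge_half_angle = 0,
                                            head_radius = 20))$volume
  f <- validate_for_quantification(nolesion)
  expect_true("no_necrotic_voxels" %in% f)
  expect_true(attr(f, "quantifiable"))

  expect_identical(as.character(validate_for_quantification(std_phantom()$volume)),
                   character(0))
  expect_true(is_quantifiable(std_phantom()$volume))

  a <- array(0L, c(4, 4, 4)); a[1, , ] <- 1L; a[4, , ] <- 1L
  expect_true("foreground_touches_boundary" %in%
                validate_for_quantification(make_vol(a)))
})

test_that("write/read round trip is the identity on labels, spacing, origin", {
  # includes the anisotropic 2D-grid geometry (downsampled in-plane for speed)
  cases <- list(
    list(dim = c(7, 5, 6), sp = c(0.5, 1, 2), or = c(-3, 4, 5), gz = FALSE),
    list(dim = c(40, 30, 40), sp = c(0.44, 2.4, 0.44), or = c(-35, -36, -35),
         gz = TRUE),
    list(dim = c(4, 4, 4), sp = c(0.8, 0.8, 0.8), or = c(0, 0, 0), gz = TRUE))
  set.seed(42)
  for (cs in cases) {
    v <- make_vol(array(sample(0:2, prod(cs$dim), TRUE), cs$dim), cs$sp, cs$or)
    f <- tempfile(fileext = if (cs$gz) ".nii.gz" else ".nii")
    write_label_volume(v, f)
    v2 <- read_label_volume(f)
    expect_identical(v2$labels, v$labels)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, v$origin, tolerance = 1e-5)
    unlink(f)
  }
})

test_that("seeded phantoms round trip exactly through NIfTI", {
  for (seed in 1:5) {
    spec <- phantom_spec(head_radius = 20 + seed,
                                      wedge_half_angle = 10 * seed,
                                      grid = if (seed %% 2) "iso3d" else "aniso2d")
    v <- generate_phantom(spec)$volume
    f <- tempfile(fileext = ".nii.gz")
    write_label_volume(v, f)
    v2 <- read_label_volume(f)
    expect_identical(v2$labels, v$labels)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    unlink(f)
  }
})

test_that("out-of-range voxel values in a file raise a validation error", {
  v <- make_vol(array(1L, c(3, 3, 3)))
  f <- tempfile(fileext = ".nii")
  write_label_volume(v, f)
  # patch one data byte (offset 352) to the illegal label 3
  con <- file(f, "r+b")
  seek(con, 352, rw = "write")
  writeBin(as.raw(3L), con)
  close(con)
  expect_error(read_label_volume(f), "\\{3\\}")
  unlink(f)
})

test_that("nibabel-written volumes read back identically, incl. reorientation", {
  py <- Sys.which("python")
  expect_true(nzchar(py))  # python ships in the runtime environment
  f1 <- tempfile(fileext = ".nii.gz"); f2 <- tempfile(fileext = ".nii.gz")
  csv1 <- tempfile(fileext = ".csv")
  script <- sprintf('
import nibabel as nib, numpy as np
rng = np.random.default_rng(5)
data = rng.integers(0, 3, size=(7, 6, 5)).astype(np.uint8)
aff = np.diag([0.5, 1.0, 2.0, 1.0]); aff[:3, 3] = [-3, 4, 5]
nib.save(nib.Nifti1Image(data, aff), "%s")
# permuted + flipped orientation of the same data
aff2 = np.array([[0,0,1.2,3.0],[-0.7,0,0,2.0],[0,1.5,0,-1.0],[0,0,0,1.0]])
nib.save(nib.Nifti1Image(data, aff2), "%s")
np.savetxt("%s", data.reshape(-1, order="F")[None, :], fmt="%%d", delimiter=",")
', f1, f2, csv1)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  expect_equal(system2(py, sf, stdout = TRUE, stderr = TRUE), character(0))
  ref <- as.integer(read.csv(csv1, header = FALSE)[1, ])
  v1 <- read_label_volume(f1)
  expect_identical(as.vector(v1$labels), ref)
  expect_equal(v1$spacing, c(0.5, 1, 2), tolerance = 1e-6)
  expect_equal(v1$origin, c(-3, 4, 5), tolerance = 1e-5)
  # reoriented read preserves the per-label voxel multiset and world geometry
  v2 <- read_label_volume(f2)
  expect_identical(dim(v2$labels), c(5L, 7L, 6L))
  expect_identical(tabulate(v2$labels + 1L, 3), tabulate(v1$labels + 1L, 3))
  expect_equal(v2$spacing, c(1.2, 0.7, 1.5), tolerance = 1e-6)
  expect_equal(v2$origin, c(3, -2.2, -1), tolerance = 1e-5)
  unlink(c(f1, f2, csv1, sf))
})

test_that("case records derive the group from the ARCO grade", {
  for (g in c("I", "II"))
    expect_identical(case_record("c", g)$group, "early")
  for (g in c("IIIA", "IIIB"))
    expect_identical(case_record("c", g)$group, "advanced")
  expect_error(case_record("c", "IV"))
  r <- case_record("hip01", "IIIA", "auto2d")
  f <- tempfile(fileext = ".json")
  write_case_record(r, f)
  expect_identical(read_case_record(f)[c("case_id", "arco_grade", "group",
                                         "source")],
                   r[c("case_id", "arco_grade", "group", "source")])
  unlink(f)
})
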