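# Shared fixtures and independent oracles. Heavy phantom results are computed
# once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the 20-phantom oracle suite: theta in [15, 75] deg, R in [20, 30] mm,
# d = 0.6 R, 0.8 mm isotropic grid
suite_specs <- function() {
  theta <- seq(15, 75, length.out = 20)
  R <- rep(c(20, 22.5, 25, 27.5, 30), 4)
  lapply(seq_len(20), function(i)
    phantom_spec(head_radius = R[i], wedge_half_angle = theta[i],
                 seed = 100L + i))
}

suite_phantoms <- function() cached("suite_phantoms",
  lapply(suite_specs(), generate_phantom))

suite_results <- function() cached("suite_results",
  lapply(suite_phantoms(), function(ph) {
    list(spec = ph$spec, truth = ph$truth,
         metrics = quantify_case(ph$volume),
         kerboul = modified_kerboul(ph$volume))
  }))

# single mid-suite phantom used by several desk tests
std_phantom <- function() cached("std_phantom",
  generate_phantom(phantom_spec(head_radius = 25, wedge_half_angle = 45)))

make_vol <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     case_id = "fixture") {
  label_volume(array(as.integer(arr), dim = dim(arr)), spacing, origin,
               case_id)
}

# solid sphere label volume (no cut, no neck), centred in the grid
make_sphere_vol <- function(R = 25, spacing = 0.8, label = 1L) {
  n <- ceiling(2 * (R + 4) / spacing) + 1
  or <- -(n - 1) / 2 * spacing
  xs <- or + (seq_len(n) - 1) * spacing
  r2 <- outer(outer(xs^2, xs^2, `+`), xs^2, `+`)
  make_vol((r2 <= R^2) * label, rep(spacing, 3), rep(or, 3), "sphere")
}

# independent oracle: exact exposed-voxel-face surface area (mm^2)
voxel_face_area <- function(vol) {
  fg <- vol$labels > 0L
  d <- dim(fg)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  sp <- vol$spacing
  fa <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  cnt1 <- sum(fg & !pad[1:d[1], 2:(d[2]+1), 2:(d[3]+1)]) +
          sum(fg & !pad[3:(d[1]+2), 2:(d[2]+1), 2:(d[3]+1)])
  cnt2 <- sum(fg & !pad[2:(d[1]+1), 1:d[2], 2:(d[3]+1)]) +
          sum(fg & !pad[2:(d[1]+1), 3:(d[2]+2), 2:(d[3]+1)])
  cnt3 <- sum(fg & !pad[2:(d[1]+1), 2:(d[2]+1), 1:d[3]]) +
          sum(fg & !pad[2:(d[1]+1), 2:(d[2]+1), 3:(d[3]+2)])
  cnt1 * fa[1] + cnt2 * fa[2] + cnt3 * fa[3]
}

# independent oracle: brute-force exact two-sided Mann-Whitney p by
# enumerating every assignment of the pooled values to the two groups
brute_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  stopifnot(!anyDuplicated(pool))
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n1 + n2, n1, u_of)
  umin <- min(u_obs, n1 * n2 - u_obs)
  umax <- max(u_obs, n1 * n2 - u_obs)
  min(1, (sum(us <= umin) + sum(us >= umax)) / length(us))
}
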