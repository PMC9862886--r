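# Dice, paired comparisons, Mann-Whitney, correlations, report tables

test_that("Dice: identity, disjoint, hand-computed fixture, conventions", {
  a <- array(0L, c(4, 4, 2)); a[1:2, 1:2, 1] <- 2L       # |A| = 4
  b <- array(0L, c(4, 4, 2))                              # |B| = 6, |A n B| = 3
  b[cbind(c(1, 2, 1, 3, 3, 3), c(1, 1, 2, 1, 2, 3), 1)] <- 2L
  va <- make_vol(a); vb <- make_vol(b)
  expect_equal(sum(va$labels == 2), 4)
  expect_equal(sum(vb$labels == 2), 6)
  expect_equal(sum(va$labels == 2 & vb$labels == 2), 3)
  expect_equal(dice(va, vb)$dice_necrotic, 0.6)     # 2*3/(4+6), by hand

  expect_equal(dice(va, va), list(dice_necrotic = 1, dice_unaffected = 1))
  dis <- make_vol(array(c(rep(2L, 8), rep(0L, 24)), c(4, 4, 2)))
  dis2 <- make_vol(array(c(rep(0L, 24), rep(2L, 8)), c(4, 4, 2)))
  expect_equal(dice(dis, dis2)$dice_necrotic, 0)
  # empty-vs-empty convention and shape guard
  z <- make_vol(array(0L, c(2, 2, 2)))
  expect_equal(dice(z, z), list(dice_necrotic = 1, dice_unaffected = 1))
  expect_error(dice(va, z), "shape mismatch")
})

test_that("Dice is symmetric on random volumes", {
  set.seed(31)
  for (i in 1:5) {
    a <- make_vol(array(sample(0:2, 125, TRUE), c(5, 5, 5)))
    b <- make_vol(array(sample(0:2, 125, TRUE), c(5, 5, 5)))
    expect_identical(dice(a, b), dice(b, a))
  }
})

test_that("paired comparison matches stats::t.test and cor.test to 1e-10", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 10, 3); y <- x + rnorm(n, 0.5, 1)
    pc <- paired_comparison(x, y)
    tt <- t.test(x, y, paired = TRUE)
    expect_equal(pc$mean_diff, unname(tt$estimate), tolerance = 1e-10)
    expect_equal(pc$ci95, as.vector(tt$conf.int), tolerance = 1e-10)
    expect_equal(pc$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(pc$p_t, tt$p.value, tolerance = 1e-10)
    ct <- cor.test(x, y)
    expect_equal(pc$pearson_r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(pc$p_r, ct$p.value, tolerance = 1e-10)
  }
})

test_that("paired comparison degenerate and edge cases", {
  x <- c(1, 2, 3, 4, 5)
  pc <- paired_comparison(x, x)
  expect_equal(pc$mean_diff, 0); expect_equal(pc$sd_diff, 0)
  expect_equal(pc$p_t, 1); expect_equal(pc$ci95, c(0, 0))
  expect_equal(pc$pearson_r, 1)

  d <- c(1, -1, 2, -2, 0, 0)                 # hand computation
  pc2 <- paired_comparison(d, rep(0, 6))
  expect_equal(pc2$mean_diff, 0)
  expect_equal(pc2$sd_diff, sqrt(2))
  expect_equal(pc2$t_stat, 0)
  expect_equal(pc2$p_t, 1)

  expect_error(paired_comparison(1:2, 2:3), "at least 3")
  # nonzero constant difference is flagged degenerate
  pc3 <- paired_comparison(c(2, 3, 4), c(1, 2, 3))
  expect_true(pc3$degenerate); expect_true(is.na(pc3$p_t))
})

test_that("Pearson r is invariant under affine rescaling", {
  set.seed(13)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- paired_comparison(x, y)$pearson_r
  expect_equal(paired_comparison(3.2 * x - 7, y)$pearson_r, r0,
               tolerance = 1e-12)
  expect_equal(paired_comparison(x, 0.04 * y + 100)$pearson_r, r0,
               tolerance = 1e-12)
})

test_that("reconstructed difference vectors have exact moments", {
  d <- reconstruct_paired_diff(30, 0.08, 2.8)
  expect_equal(mean(d), 0.08, tolerance = 1e-12)
  expect_equal(sd(d), 2.8, tolerance = 1e-12)
})

test_that("exact Mann-Whitney matches brute-force enumeration (sizes <= 6)", {
  set.seed(17)
  sizes <- list(c(2, 3), c(3, 3), c(3, 5), c(4, 4), c(5, 6), c(6, 6))
  for (sz in sizes) {
    x <- round(rnorm(sz[1], 0.3, 1), 6)
    y <- round(rnorm(sz[2], 0, 1), 6)
    gc_ <- group_comparison(c(x, y), rep(c("early", "advanced"), sz))
    expect_identical(gc_$method, "exact")
    expect_equal(gc_$p_u, brute_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney examples: separated groups and identical groups", {
  g <- rep(c("early", "advanced"), each = 3)
  gc1 <- group_comparison(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(gc1$u_stat, 0)
  expect_equal(gc1$p_u, 0.1)                     # 2/20, enumerated by hand
  gc2 <- group_comparison(c(1.5, 2.5, 3.5, 1.5, 2.5, 3.5), g)  # ties -> approx
  expect_gt(gc2$p_u, 0.9)
  expect_error(group_comparison(1:3, rep("early", 3)), "nonempty")
})

test_that("tied/large samples use the corrected normal approximation (wilcox.test oracle)", {
  set.seed(23)
  x <- round(rnorm(15, 0.8), 1); y <- round(rnorm(20), 1)  # ties by rounding
  gc_ <- group_comparison(c(x, y), rep(c("early", "advanced"), c(15, 20)))
  expect_identical(gc_$method, "normal_approx")
  wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
  expect_equal(gc_$p_u, wt$p.value, tolerance = 1e-10)
  expect_equal(gc_$u_stat, unname(wt$statistic))
})

test_that("group medians and IQRs use linear-interpolation quantiles", {
  x <- c(1, 4, 6, 10); y <- c(2, 3, 8, 20, 21)
  gc_ <- group_comparison(c(x, y), rep(c("early", "advanced"), c(4, 5)))
  expect_equal(gc_$median_early, median(x))
  expect_equal(gc_$iqr_early, unname(diff(quantile(x, c(.25, .75)))))
  expect_equal(gc_$iqr_advanced, unname(diff(quantile(y, c(.25, .75)))))
})

test_that("correlation table: perfect linear and anti-linear relations", {
  kb <- data.frame(case_id = sprintf("c%d", 1:8),
                   modified_angle = c(60, 90, 120, 150, 180, 210, 240, 270))
  met <- data.frame(case_id = kb$case_id, source = "manual3d",
                    necrotic_volume = 0.05 * kb$modified_angle - 1,
                    pct_necrotic_volume = -0.1 * kb$modified_angle + 40,
                    necrotic_surface = 2 + 0.1 * kb$modified_angle,
                    pct_necrotic_surface = 0.2 * kb$modified_angle)
  tab <- correlation_table(met, kb)
  r <- setNames(tab$r, tab$parameter)
  expect_equal(unname(r["necrotic_volume"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["pct_necrotic_volume"]), -1, tolerance = 1e-12)
  expect_error(correlation_table(met[1:2, ], kb), "fewer than 3")
})

test_that("report tables: single case flags, completeness, determinism", {
  mk <- function(ids, src, grp) {
    i <- seq_along(ids)
    data.frame(
      case_id = ids, source = src, group = grp,
      necrotic_volume = i + 1, unaffected_volume = 40 - i,
      pct_necrotic_volume = 10 + i %% 3, necrotic_surface = 5 + 0.5 * i,
      head_surface = 55 + i %% 4, pct_necrotic_surface = 9 + 0.7 * i,
      modified_angle = 150 + 5 * i)
  }

  # one case only: summary appears, paired tables are flagged
  d1 <- tempfile(); rep1 <- build_report(mk("c1", "manual3d", "advanced"), d1)
  expect_true(file.exists(file.path(d1, "summary.csv")))
  expect_true(all(rep1$paired$note == "insufficient_n"))

  # full synthetic: all four tables, no empty cells
  ids <- sprintf("c%02d", 1:8)
  grp <- rep(c("early", "advanced"), each = 4)
  met <- rbind(mk(ids, "manual3d", grp), mk(ids, "manual2d", grp),
               mk(ids, "auto2d", grp))
  met$necrotic_volume <- met$necrotic_volume + ifelse(grp == "advanced", 6, 0)
  d2 <- tempfile(); build_report(met, d2)
  for (f in c("summary.csv", "paired_comparisons.csv", "group_comparison.csv",
              "kerboul_correlations.csv")) {
    tab <- read.csv(file.path(d2, f))
    expect_gt(nrow(tab), 0)
    expect_false(any(is.na(tab[setdiff(names(tab), "note")])))
  }
  # byte-identical re-run
  d3 <- tempfile(); build_report(met, d3)
  for (f in list.files(d2))
    expect_identical(unname(tools::md5sum(file.path(d2, f))),
                     unname(tools::md5sum(file.path(d3, f))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
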