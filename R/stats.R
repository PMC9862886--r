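# Statistical battery: Dice agreement, paired mean-difference tests with
# 95% CIs and Pearson correlations, Mann-Whitney U group comparisons with an
# exact small-sample null, and the report tables. All tests are two-sided at
# alpha = 0.05; no multiple-testing correction is applied (deliberately).

#' Dice coefficients between two label volumes
#'
#' Per-label overlap 2|A n B| / (|A| + |B|) for the unaffected (1) and
#' necrotic (2) labels. When a label is empty in both volumes its Dice is 1;
#' when it is empty in exactly one, 0. Symmetric in its arguments.
#'
#' @param a,b [label_volume()]s on identical grid shapes.
#' @return A list with `dice_necrotic` and `dice_unaffected`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("grid shape mismatch: ", paste(dim(a$labels), collapse = "x"),
         " vs ", paste(dim(b$labels), collapse = "x"))
  one <- function(lab) {
    A <- a$labels == lab; B <- b$labels == lab
    sa <- sum(A); sb <- sum(B)
    if (sa + sb == 0) return(1)
    2 * sum(A & B) / (sa + sb)
  }
  list(dice_necrotic = one(2L), dice_unaffected = one(1L))
}

#' Paired comparison of two per-case metric series
#'
#' Computes the paired difference d = x - y and reports its mean, sample SD
#' (n - 1 denominator), the two-sided 95% confidence interval
#' mean +/- t(0.975, n-1) * SD / sqrt(n), the paired t-test p-value, and
#' the Pearson correlation between x and y with its t-based two-sided
#' p-value. With a zero-SD difference the CI collapses to the mean and the
#' p-value is reported as exactly 1 when the mean is 0, otherwise the result
#' is flagged degenerate (`p_t = NA`).
#'
#' @param x,y equal-length numeric vectors (n >= 3), aligned by case.
#' @return A `paired_comparison` with fields `n`, `mean_diff`, `sd_diff`,
#'   `ci95`, `t_stat`, `p_t`, `pearson_r`, `p_r`, `degenerate`.
#' @export
paired_comparison <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs, got ", n)
  d <- x - y
  m <- mean(d); s <- sd(d)
  degenerate <- FALSE
  if (s == 0) {
    ci <- c(m, m)
    t_stat <- if (m == 0) 0 else Inf * sign(m)
    p_t <- if (m == 0) 1 else { degenerate <- TRUE; NA_real_ }
  } else {
    se <- s / sqrt(n)
    t_stat <- m / se
    p_t <- 2 * pt(-abs(t_stat), df = n - 1)
    ci <- m + c(-1, 1) * qt(0.975, df = n - 1) * se
  }
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_; p_r <- NA_real_
  } else {
    r <- cor(x, y)
    if (abs(r) >= 1) {
      p_r <- 0
    } else {
      tr <- r * sqrt((n - 2) / (1 - r^2))
      p_r <- 2 * pt(-abs(tr), df = n - 2)
    }
  }
  structure(list(n = n, mean_diff = m, sd_diff = s, ci95 = ci,
                 t_stat = t_stat, p_t = p_t, pearson_r = r, p_r = p_r,
                 degenerate = degenerate),
            class = "paired_comparison")
}

#' Reconstruct a difference vector with exact moments
#'
#' Builds a length-`n` numeric vector whose sample mean and sample SD
#' (n - 1 denominator) equal the given values exactly - useful for checking
#' confidence-interval arithmetic against published mean +/- SD summaries.
#'
#' @param n length.
#' @param mean,sd target sample moments.
#' @return Numeric vector of length `n`.
#' @export
reconstruct_paired_diff <- function(n, mean, sd) {
  stopifnot(n >= 2)
  v <- seq_len(n)
  mean + sd * (v - base::mean(v)) / stats::sd(v)
}

# exact null distribution of the Mann-Whitney U statistic (no ties):
# count partitions via the standard recursion; returns P(U = 0..n1*n2)
.mw_null_freq <- function(n1, n2) {
  # f[[i]][u+1] = number of ways to place i group-1 ranks with U = u
  # counts c(i, j, u) of rank interleavings of i group-1 and j group-2
  # observations with U = u obey c(i,j,u) = c(i-1,j,u-j) + c(i,j-1,u)
  maxu <- n1 * n2
  prev <- matrix(0, nrow = n2 + 1, ncol = maxu + 1)  # i = 0 layer
  prev[, 1] <- 1
  for (i in seq_len(n1)) {
    cur <- matrix(0, nrow = n2 + 1, ncol = maxu + 1)
    cur[1, 1] <- 1                                   # j = 0
    for (j in seq_len(n2)) {
      shifted <- c(rep(0, j), prev[j + 1, seq_len(maxu + 1 - j)])
      cur[j + 1, ] <- shifted + cur[j, ]
    }
    prev <- cur
  }
  prev[n2 + 1, ] / choose(n1 + n2, n1)
}

#' Mann-Whitney U group comparison with medians and IQRs
#'
#' Two-sided Mann-Whitney U test of `values` between the `"early"` and
#' `"advanced"` groups, with per-group medians and interquartile ranges
#' (Q3 - Q1, linear-interpolation quantiles, `type = 7`). The exact null
#' distribution is used when `min(n1, n2) <= 8` and the data are tie-free;
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param values numeric per-case metric.
#' @param groups character/factor of `"early"` / `"advanced"`, same length.
#' @return A `group_comparison` with `median_early`, `iqr_early`,
#'   `median_advanced`, `iqr_advanced`, `u_stat`, `p_u`, `method`.
#' @export
group_comparison <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  if (!all(groups %in% c("early", "advanced")))
    stop("groups must be 'early' or 'advanced'")
  x <- values[groups == "early"]
  y <- values[groups == "advanced"]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(c(x, y)) > 0
  if (min(n1, n2) <= 8 && !ties) {
    pf <- .mw_null_freq(n1, n2)
    umin <- min(u1, u2)
    p <- min(1, 2 * sum(pf[seq_len(floor(umin) + 1)]))
    method <- "exact"
  } else {
    n <- n1 + n2
    tt <- table(c(x, y))
    tiecor <- sum(tt^3 - tt) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tiecor))
    mu <- n1 * n2 / 2
    z <- (abs(u1 - mu) - 0.5) / sigma
    z <- max(z, 0)
    p <- 2 * pnorm(-z)
    method <- "normal_approx"
  }
  structure(list(
    median_early = median(x), iqr_early = unname(diff(quantile(x, c(.25, .75)))),
    median_advanced = median(y),
    iqr_advanced = unname(diff(quantile(y, c(.25, .75)))),
    n_early = n1, n_advanced = n2,
    u_stat = u1, p_u = p, method = method),
    class = "group_comparison")
}

#' Correlations of the six parameters against the modified Kerboul angle
#'
#' Pearson r and two-sided p for each (segmentation source, parameter) pair
#' against the per-case modified Kerboul angle, in the layout of a
#' source-by-parameter correlation table.
#'
#' @param metrics data frame with columns `case_id`, `source`, and the
#'   parameter columns.
#' @param kerboul data frame with columns `case_id`, `modified_angle`.
#' @param parameters parameter column names to correlate.
#' @return A data frame with columns `source`, `parameter`, `n`, `r`, `p`.
#' @export
correlation_table <- function(metrics, kerboul,
                              parameters = c("necrotic_volume",
                                             "pct_necrotic_volume",
                                             "necrotic_surface",
                                             "pct_necrotic_surface")) {
  stopifnot(all(c("case_id", "source") %in% names(metrics)),
            all(c("case_id", "modified_angle") %in% names(kerboul)))
  out <- list()
  for (src in unique(metrics$source)) {
    ms <- metrics[metrics$source == src, ]
    mm <- merge(ms, kerboul, by = "case_id")
    if (nrow(mm) < 3)
      stop("fewer than 3 aligned cases for source ", src)
    for (p in parameters) {
      pc <- paired_comparison(mm[[p]], mm$modified_angle)  # reuse r machinery
      out[[length(out) + 1]] <- data.frame(
        source = src, parameter = p, n = nrow(mm),
        r = pc$pearson_r, p = pc$p_r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.param_cols <- c("necrotic_volume", "unaffected_volume", "pct_necrotic_volume",
                 "necrotic_surface", "head_surface", "pct_necrotic_surface")

#' Build the cohort report tables
#'
#' Emits the four CSV report tables from a long-format per-case metrics
#' table: per-source summaries (mean +/- SD and range), paired comparisons
#' between segmentation sources, early-versus-advanced group comparisons,
#' and correlations against the modified Kerboul angle; plus a
#' full-precision JSON with the same content and the Dice table when
#' provided. Cases missing a source for a paired table are reported in the
#' JSON as excluded, never dropped silently. Pairings with fewer than 3
#' complete cases are flagged `insufficient_n` instead of tested.
#'
#' @param metrics long data frame: `case_id`, `source`, `group`, the six
#'   parameter columns, and optionally `modified_angle`.
#' @param dir output directory (created if needed).
#' @param dice_table optional data frame of per-case Dice results.
#' @param pairings list of 2-vectors of sources to compare pairwise.
#' @return Invisibly, a list of the tables written.
#' @export
build_report <- function(metrics, dir, dice_table = NULL,
                         pairings = list(c("manual3d", "manual2d"),
                                         c("manual2d", "auto2d"))) {
  stopifnot(is.data.frame(metrics))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- intersect(.param_cols, names(metrics))

  summary_tab <- do.call(rbind, lapply(split(metrics, metrics$source),
    function(ms) do.call(rbind, lapply(params, function(p) data.frame(
      source = ms$source[1], parameter = p, n = nrow(ms),
      mean = mean(ms[[p]]), sd = if (nrow(ms) > 1) sd(ms[[p]]) else NA_real_,
      min = min(ms[[p]]), max = max(ms[[p]]), stringsAsFactors = FALSE)))))
  rownames(summary_tab) <- NULL

  excluded <- list(); paired_rows <- list()
  for (pr in pairings) {
    a <- metrics[metrics$source == pr[1], c("case_id", params)]
    b <- metrics[metrics$source == pr[2], c("case_id", params)]
    mm <- merge(a, b, by = "case_id", suffixes = c(".a", ".b"))
    miss <- setdiff(union(a$case_id, b$case_id), mm$case_id)
    if (length(miss))
      excluded[[paste(pr, collapse = "_vs_")]] <- miss
    for (p in params) {
      if (nrow(mm) < 3) {
        paired_rows[[length(paired_rows) + 1]] <- data.frame(
          comparison = paste(pr, collapse = "_vs_"), parameter = p,
          n = nrow(mm), mean_diff = NA, sd_diff = NA, ci_lo = NA, ci_hi = NA,
          p_t = NA, r = NA, p_r = NA, note = "insufficient_n",
          stringsAsFactors = FALSE)
      } else {
        pc <- paired_comparison(mm[[paste0(p, ".a")]], mm[[paste0(p, ".b")]])
        paired_rows[[length(paired_rows) + 1]] <- data.frame(
          comparison = paste(pr, collapse = "_vs_"), parameter = p,
          n = pc$n, mean_diff = pc$mean_diff, sd_diff = pc$sd_diff,
          ci_lo = pc$ci95[1], ci_hi = pc$ci95[2], p_t = pc$p_t,
          r = pc$pearson_r, p_r = pc$p_r, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  paired_tab <- do.call(rbind, paired_rows)

  group_rows <- list()
  gparams <- c(params, intersect("modified_angle", names(metrics)))
  for (src in unique(metrics$source)) {
    ms <- metrics[metrics$source == src, ]
    if (!all(c("early", "advanced") %in% ms$group)) next
    for (p in gparams) {
      gc <- group_comparison(ms[[p]], ms$group)
      group_rows[[length(group_rows) + 1]] <- data.frame(
        source = src, parameter = p,
        median_early = gc$median_early, iqr_early = gc$iqr_early,
        median_advanced = gc$median_advanced, iqr_advanced = gc$iqr_advanced,
        u_stat = gc$u_stat, p_u = gc$p_u, method = gc$method,
        stringsAsFactors = FALSE)
    }
  }
  group_tab <- if (length(group_rows)) do.call(rbind, group_rows) else
    data.frame(note = "group comparison skipped: a group is empty")

  corr_tab <- if ("modified_angle" %in% names(metrics)) {
    kb <- unique(metrics[metrics$source == metrics$source[1],
                         c("case_id", "modified_angle")])
    tryCatch(correlation_table(metrics, kb), error = function(e)
      data.frame(note = paste("insufficient_n:", conditionMessage(e))))
  } else data.frame(note = "no Kerboul angles supplied")

  wcsv <- function(tab, f) write.csv(tab, file.path(dir, f), row.names = FALSE)
  wcsv(summary_tab, "summary.csv")
  wcsv(paired_tab, "paired_comparisons.csv")
  wcsv(group_tab, "group_comparison.csv")
  wcsv(corr_tab, "kerboul_correlations.csv")
  if (!is.null(dice_table)) wcsv(dice_table, "dice.csv")
  report <- list(summary = summary_tab, paired = paired_tab,
                 group = group_tab, correlations = corr_tab,
                 dice = dice_table, excluded_cases = excluded,
                 conventions = list(alpha = 0.05, sided = "two-sided",
                                    iqr_quantile_type = 7,
                                    empty_vs_empty_dice = 1,
                                    multiple_testing_correction = "none"))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
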