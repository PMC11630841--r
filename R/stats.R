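#' Paired one-sided Wilcoxon signed-rank test
#'
#' Tests whether `y` tends to exceed `x` (or the reverse) on paired
#' observations. Zero differences are dropped; ties in `|d|` receive
#' midranks. The reported statistic is `W+`, the rank sum of positive
#' differences of `y - x`. For n <= 25 pairs the p-value is exact,
#' computed by dynamic programming over the (doubled) midranks across
#' all `2^n` sign assignments -- so exactness survives ties; beyond
#' that a normal approximation with continuity and tie correction is
#' used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"greater"` tests y > x, `"less"` tests y < x.
#' @return List with `statistic` (W+), `p_value`, `n` (pairs retained)
#'   and `method` (`"exact"` or `"normal"`).
#' @export
paired_wilcoxon_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- y - x
  d <- d[d != 0]
  if (!length(d))
    stopf("all paired differences are zero; the signed-rank test is degenerate")
  n <- length(d)
  if (n < 5L) stopf("need at least 5 nonzero paired differences, got %d", n)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  p <- if (n <= 25L) {
    exact_signed_rank_p(r, w_plus, alternative)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    if (alternative == "greater")
      pnorm((w_plus - mu - 0.5) / sigma, lower.tail = FALSE)
    else pnorm((w_plus - mu + 0.5) / sigma)
  }
  list(statistic = w_plus, p_value = min(p, 1), n = n,
       method = if (n <= 25L) "exact" else "normal")
}

# Exact null distribution of W+ for possibly tied (midrank) data: double
# the ranks to make them integers and convolve subset counts.
exact_signed_rank_p <- function(r, w_plus, alternative) {
  d2 <- as.integer(round(2 * r))
  total <- sum(d2)
  counts <- numeric(total + 1L)   # counts[s + 1] = #subsets with doubled sum s
  counts[1L] <- 1
  for (v in d2) {
    shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w_plus)
  if (alternative == "greater")
    sum(counts[(w2 + 1L):(total + 1L)]) / 2^length(d2)
  else sum(counts[1L:(w2 + 1L)]) / 2^length(d2)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the exact t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero
#'   variance).
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stopf("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("zero variance: Pearson correlation is undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Summary statistics over rescue records
#'
#' Computes the pipeline's headline numbers from a table of rescue
#' records: cohort counts, per-mode mean and SD of the plDDT change
#' against baseline over the low-baseline subset (baseline mean plDDT
#' below `low_threshold`), one-sided paired Wilcoxon tests (each
#' template mode and the best pick against baseline, and
#' template+single-sequence against template+MSA), and Pearson
#' correlations between closest-template identity and the per-mode
#' plDDT change. Comparisons whose paired differences are all zero (a
#' possibility under a null backend) are reported with p = 1 and a
#' `degenerate` flag rather than an error: identical paired values are
#' no evidence for a one-sided increase.
#'
#' @param records Data frame of rescue records (rows from
#'   [run_rescue]).
#' @param low_threshold Baseline confidence cutoff defining the rescue
#'   arm (default 70).
#' @return A `rescue_summary` list: `n_total`, `n_low_baseline`,
#'   `n_rescued`, `mean_delta`, `sd_delta` (named by mode), `wilcoxon`
#'   and `pearson` result lists.
#' @export
summarize_rescue <- function(records, low_threshold = 70) {
  if (!nrow(records)) stopf("no rescue records to summarize")
  records <- records[order(records$protein_id), , drop = FALSE]
  low <- records[!is.na(records$baseline_plddt) &
                 records$baseline_plddt < low_threshold, , drop = FALSE]
  if (!nrow(low)) warnf("no low-baseline records; partial summary")
  modes <- c(template_msa = "template_msa_plddt",
             template_single = "template_single_plddt",
             best_pick = "best_pick_plddt")
  deltas <- lapply(modes, function(col) low[[col]] - low$baseline_plddt)
  safe_wilcoxon <- function(x, y) {
    tryCatch(c(paired_wilcoxon_one_sided(x, y, "greater"),
               list(degenerate = FALSE)),
             error = function(e) list(statistic = NA_real_, p_value = 1,
                                      n = length(x), method = "degenerate",
                                      degenerate = TRUE))
  }
  wilcoxon <- if (nrow(low)) list(
    template_msa_vs_baseline = safe_wilcoxon(low$baseline_plddt,
                                             low$template_msa_plddt),
    template_single_vs_baseline = safe_wilcoxon(low$baseline_plddt,
                                                low$template_single_plddt),
    best_pick_vs_baseline = safe_wilcoxon(low$baseline_plddt,
                                          low$best_pick_plddt),
    template_single_vs_template_msa = safe_wilcoxon(low$template_msa_plddt,
                                                    low$template_single_plddt)
  ) else list()
  safe_pearson <- function(x, y) {
    tryCatch(pearson_cor(x, y),
             error = function(e) list(r = NA_real_, p_value = NA_real_,
                                      n = sum(stats::complete.cases(x, y))))
  }
  pearson <- if (nrow(low)) list(
    identity_vs_delta_template_msa =
      safe_pearson(low$closest_template_identity_pct, deltas$template_msa),
    identity_vs_delta_template_single =
      safe_pearson(low$closest_template_identity_pct, deltas$template_single)
  ) else list()
  structure(list(
    n_total = nrow(records),
    n_low_baseline = nrow(low),
    n_rescued = sum(records$rescued, na.rm = TRUE),
    mean_delta = vapply(deltas, function(d) mean(d, na.rm = TRUE), numeric(1)),
    sd_delta = vapply(deltas, function(d) sd(d, na.rm = TRUE), numeric(1)),
    wilcoxon = wilcoxon, pearson = pearson,
    low_threshold = low_threshold), class = "rescue_summary")
}

#' @export
print.rescue_summary <- function(x, ...) {
  cat(sprintf("<rescue_summary> %d proteins, %d with baseline plDDT < %g, %d rescued\n",
              x$n_total, x$n_low_baseline, x$low_threshold, x$n_rescued))
  for (m in names(x$mean_delta))
    cat(sprintf("  delta plDDT %-16s %6.2f +/- %.2f\n", m,
                x$mean_delta[[m]], x$sd_delta[[m]]))
  for (w in names(x$wilcoxon))
    cat(sprintf("  wilcoxon %-28s W+=%8.1f  p=%.3g\n", w,
                x$wilcoxon[[w]]$statistic, x$wilcoxon[[w]]$p_value))
  for (p in names(x$pearson))
    cat(sprintf("  pearson %-32s r=%.3f  p=%.3g\n", p,
                x$pearson[[p]]$r, x$pearson[[p]]$p_value))
  invisible(x)
}
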