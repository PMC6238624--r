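#' Median-of-ratios size factors
#'
#' Library-size normalization for sparse per-position 5'-end counts. For
#' each position i the geometric mean g_i across libraries is the
#' pseudo-reference; library j's size factor is the median of K_ij / g_i
#' over positions with g_i > 0.
#'
#' @param table A `position_table` or a bare count matrix.
#' @return Named numeric vector of positive size factors, one per library.
#' @export
estimate_size_factors <- function(table) {
  counts <- if (inherits(table, "position_table")) table$counts else table
  if (!nrow(counts)) stop("empty count table")
  loggeo <- rowMeans(log(counts))          # -Inf where any count is 0
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no position with positive counts in every library; ",
         "cannot form the median-of-ratios reference set")
  sf <- apply(counts[use, , drop = FALSE], 2, function(k)
    exp(stats::median(log(k) - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf
}

normalized_counts <- function(counts, size_factors) {
  sweep(counts, 2, size_factors, "/")
}

#' Per-position dispersion estimation
#'
#' A documented simplification of the shrinkage estimators used by count
#' based differential-expression tools: a method-of-moments raw dispersion
#' per position, a mean-dispersion trend alpha(mu) = a0 + a1/mu fitted by
#' least squares, and a fixed-weight combination of the two.
#'
#' The raw estimate uses the grand mean m_i of normalized counts and the
#' replicate-df-weighted pooled within-condition variance v_i:
#' alpha_i = max(0, (v_i - m_i) / m_i^2). The trend is fitted over positions
#' with m_i > 0 and alpha_i > 0; the shrunk value is
#' w * trend(m_i) + (1 - w) * alpha_i, floored at 1e-8.
#'
#' @param table A `position_table` or count matrix.
#' @param size_factors Output of [estimate_size_factors()].
#' @param condition Condition label per library (taken from the table when
#'   omitted).
#' @param weight Trend weight w in `[0, 1]`; default 0.5.
#' @return A `dispersion_model` list: `alpha_raw`, `trend` (a0, a1),
#'   `alpha` (shrunk, the values used downstream), `mean`.
#' @export
estimate_dispersions <- function(table, size_factors, condition = NULL,
                                 weight = 0.5) {
  counts <- if (inherits(table, "position_table")) table$counts else table
  if (is.null(condition)) {
    if (!inherits(table, "position_table"))
      stop("`condition` required when passing a bare matrix")
    condition <- table$libraries$condition
  }
  tabc <- table(condition)
  if (length(tabc) != 2L || any(tabc < 2L))
    stop("need two conditions with >= 2 replicates each ",
         "(the design has three replicates per strain)")
  norm <- normalized_counts(counts, size_factors)
  m <- rowMeans(norm)
  # pooled within-condition variance, weighted by replicate df
  v <- rep(0, nrow(counts)); df_tot <- 0
  for (cc in names(tabc)) {
    sel <- condition == cc
    nc <- sum(sel)
    vc <- apply(norm[, sel, drop = FALSE], 1, stats::var)
    v <- v + (nc - 1) * vc
    df_tot <- df_tot + (nc - 1)
  }
  v <- v / df_tot
  alpha_raw <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)

  fit_sel <- m > 0 & alpha_raw > 0
  if (sum(fit_sel) >= 2L) {
    fit <- stats::lm.fit(cbind(1, 1 / m[fit_sel]), alpha_raw[fit_sel])
    trend <- stats::setNames(fit$coefficients, c("a0", "a1"))
  } else {
    # degenerate input (e.g. near-Poisson toy tables): flat fallback trend
    a0 <- if (any(fit_sel)) stats::median(alpha_raw[fit_sel]) else 0.01
    trend <- c(a0 = a0, a1 = 0)
  }
  trend_val <- pmax(0, trend["a0"] + trend["a1"] / pmax(m, 1e-12))
  alpha <- pmax(weight * trend_val + (1 - weight) * alpha_raw, 1e-8)
  alpha[m == 0] <- 1e-8
  structure(list(alpha_raw = alpha_raw, trend = trend, alpha = alpha,
                 mean = m, weight = weight),
            class = "dispersion_model")
}

#' Per-position Wald test of wild-type vs mutant 5'-end signal
#'
#' For each position the log2 fold change is
#' log2(mean normalized WT / mean normalized mutant); a pseudocount of 0.5
#' is added to both means only when either is zero, so positions detected in
#' a single strain keep a finite fold change. The standard error comes from
#' the NB delta method: Var(K_j/s_j) = mu/s_j + alpha mu^2 per library,
#' propagated through the log ratio; the p-value is two-sided normal on
#' log2fc / se. Orientation is WT over mutant, so genuine cleavage products
#' (depleted when the nuclease is inactivated) get positive log2fc.
#'
#' @param counts Count matrix (rows = positions) or `position_table`.
#' @param condition Condition per library.
#' @param size_factors Per-library size factors.
#' @param alpha Shrunk dispersion per position (recycled if length 1).
#' @param pseudocount Added to both condition means when either is 0.
#' @return Data frame: `base_mean`, `log2fc`, `se`, `p_value`,
#'   `pseudocount_used` (logical).
#' @export
wald_test <- function(counts, condition, size_factors, alpha,
                      pseudocount = 0.5) {
  if (inherits(counts, "position_table")) {
    condition <- counts$libraries$condition
    counts <- counts$counts
  }
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("dispersions must be finite and non-negative")
  alpha <- rep_len(alpha, nrow(counts))
  wt <- condition == "wild_type"; mut <- condition == "mutant"
  if (sum(wt) < 2L || sum(mut) < 2L)
    stop("need >= 2 libraries per condition")
  norm <- normalized_counts(counts, size_factors)
  base_mean <- rowMeans(norm)
  m_wt <- rowMeans(norm[, wt, drop = FALSE])
  m_mut <- rowMeans(norm[, mut, drop = FALSE])
  needs_pc <- m_wt == 0 | m_mut == 0
  a_wt <- m_wt + pseudocount * needs_pc
  a_mut <- m_mut + pseudocount * needs_pc
  log2fc <- log2(a_wt / a_mut)

  # delta-method variance of log2(condition mean) under NB(mu s_j, alpha)
  var_log2_mean <- function(mu, sel) {
    inv_s <- sum(1 / size_factors[sel])
    n <- sum(sel)
    var_mean <- (mu * inv_s + alpha * n * mu^2) / n^2
    var_mean / (mu^2 * log(2)^2)
  }
  se <- sqrt(var_log2_mean(a_wt, wt) + var_log2_mean(a_mut, mut))
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(base_mean = base_mean, log2fc = log2fc, se = se,
             p_value = p, pseudocount_used = needs_pc)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' padj_(k) = min over l >= k of m * p_(l) / l, capped at 1, mapped back to
#' the input order. Applied jointly across all filtered positions of all
#' replicons.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  padj_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  padj <- numeric(m)
  padj[o] <- padj_sorted
  padj
}

#' MA-table classification
#'
#' Attaches the significance class used for MA-plot coloring:
#' `wt_enriched` (log2fc >= log2(fc_min), padj < alpha — candidate cleavage
#' products), `mut_enriched` (log2fc <= -log2(fc_min), padj < alpha —
#' candidate stabilized 5' ends) or `ns`.
#'
#' @param results Data frame with `base_mean`, `log2fc`, `padj`.
#' @param fc_min Minimum fold change (linear scale), default 2.
#' @param alpha Adjusted p-value cutoff, default 0.05.
#' @return `results` with a `class` factor column appended.
#' @export
ma_table <- function(results, fc_min = 2, alpha = 0.05) {
  lfc <- log2(fc_min)
  cls <- rep("ns", nrow(results))
  sig <- results$padj < alpha
  cls[sig & results$log2fc >= lfc] <- "wt_enriched"
  cls[sig & results$log2fc <= -lfc] <- "mut_enriched"
  results$class <- factor(cls, levels = c("wt_enriched", "mut_enriched", "ns"))
  results
}

#' Full per-position differential enrichment analysis
#'
#' Convenience wrapper running [estimate_size_factors()],
#' [estimate_dispersions()], [wald_test()] and [adjust_bh()] on a (already
#' coverage-filtered) position table, returning one row per position.
#'
#' @param table A `position_table`.
#' @param fc_min,alpha Passed to [ma_table()].
#' @param dispersion_weight Passed to [estimate_dispersions()].
#' @return A `test_result` data frame: key columns, `base_mean`, `log2fc`,
#'   `se`, `p_value`, `padj`, `class`; size factors and the dispersion model
#'   are attached as attributes.
#' @export
run_difftest <- function(table, fc_min = 2, alpha = 0.05,
                         dispersion_weight = 0.5) {
  sf <- estimate_size_factors(table)
  disp <- estimate_dispersions(table, sf, weight = dispersion_weight)
  res <- wald_test(table$counts, table$libraries$condition, sf, disp$alpha)
  res$padj <- adjust_bh(res$p_value)
  res <- ma_table(res, fc_min = fc_min, alpha = alpha)
  out <- cbind(table$key, res)
  attr(out, "size_factors") <- sf
  attr(out, "dispersion_model") <- disp
  class(out) <- c("test_result", "data.frame")
  out
}

#' Write differential test results as TSV
#' @param results A `test_result` data frame from [run_difftest()].
#' @param path Output path.
#' @export
write_test_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
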