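# In-package count statistics: median-of-ratios size factors, a
# negative-binomial Wald test for differential expression, a relative-usage
# (feature share within group) test, BH adjustment and the 2x2 chi-square /
# odds-ratio association statistic.
#
# This engine is a deliberate simplification of the large DE frameworks:
# per-feature method-of-moments dispersion (no cross-feature shrinkage), raw
# log2 fold changes (no posterior shrinkage). Classifications downstream
# threshold effect size and adjusted p, which this engine reproduces on
# synthetic data with known ground truth.

#' Build a two-condition design
#'
#' @param samples ordered sample identifiers.
#' @param condition vector of "control"/"treatment" per sample.
#' @return data.frame with class `tetrap_design`.
#' @export
make_design <- function(samples, condition) {
  stopifnot(length(samples) == length(condition))
  condition <- as.character(condition)
  if (!all(sort(unique(condition)) == c("control", "treatment")))
    stop_input("design needs both conditions 'control' and 'treatment'")
  structure(data.frame(sample = as.character(samples), condition = condition,
                       stringsAsFactors = FALSE),
            class = c("tetrap_design", "data.frame"))
}

design_split <- function(counts, design) {
  stopifnot(all(design$sample %in% colnames(counts)))
  list(control = counts[, design$sample[design$condition == "control"],
                        drop = FALSE],
       treatment = counts[, design$sample[design$condition == "treatment"],
                          drop = FALSE])
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over all-positive features of the ratio between
#' the sample's count and the feature's geometric mean across samples.
#'
#' @param counts feature x sample matrix of non-negative counts.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_input("negative counts")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_input(paste("no feature has positive counts in every sample;",
                     "supply size factors explicitly or add features"))
  gm <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  sf <- apply(counts[pos, , drop = FALSE], 2,
              function(col) median(col / gm))
  stopifnot(all(sf > 0))
  sf
}

# Method-of-moments NB dispersion from normalized counts, condition-wise
# residuals. "pooled" (default): one cohort-level estimate, the ratio of
# the summed moment numerators (v - mu) to the summed denominators (mu^2)
# over all features and both conditions; nearly unbiased at small
# replicate numbers, where per-feature estimates are too noisy to keep the
# Wald test calibrated. "per_feature": the classical per-feature ratio
# with a pooled fallback when a feature's variance falls below its mean.
mom_dispersion <- function(norm_control, norm_treatment,
                           mode = c("pooled", "per_feature"),
                           floor_ = 1e-8) {
  mode <- match.arg(mode)
  per_cond <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    list(num = (v - mu) * (ncol(m) - 1), den = mu^2 * (ncol(m) - 1))
  }
  a <- per_cond(norm_control); b <- per_cond(norm_treatment)
  num <- a$num + b$num; den <- a$den + b$den
  pooled <- max(floor_, sum(num[is.finite(num)]) / sum(den[is.finite(num)]))
  if (mode == "pooled") return(rep(pooled, nrow(norm_control)))
  disp <- num / den
  disp[!is.finite(disp) | disp < 0] <- pooled
  pmax(disp, floor_)
}

#' Negative-binomial Wald test for differential expression
#'
#' Features with fewer than `min_total` raw reads summed over all samples
#' are discarded before testing. Counts are normalized by size factors;
#' per-condition NB means and a method-of-moments dispersion give a Wald
#' statistic for the log2 fold change (two-sided normal reference). With
#' `lfc_threshold > 0` the null is |log2FC| <= threshold (composite, as
#' used for differential-gene calling); with 0 it is the point null. The
#' default cohort-pooled dispersion keeps the test both calibrated and
#' powered at small replicate numbers; `disp_mode = "per_feature"` selects
#' the classical noisy per-feature estimator instead.
#'
#' @param counts feature x sample matrix of raw counts.
#' @param design a [make_design()] object; >= 2 replicates per condition.
#' @param sf size factors (default: computed from `counts`).
#' @param lfc_threshold log2 fold-change null threshold (default 0).
#' @param min_total minimum raw total per feature (default 10).
#' @param pseudo_count added to normalized condition means for finite
#'   log fold changes at zero counts (default 0.5).
#' @param disp_mode "pooled" (default) or "per_feature" dispersion.
#' @return data.frame (feature_id, base_mean, log2fc, se, stat, p, padj).
#' @export
nb_wald_test <- function(counts, design, sf = NULL, lfc_threshold = 0,
                         min_total = 10, pseudo_count = 0.5,
                         disp_mode = c("pooled", "per_feature")) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  tab <- table(design$condition)
  if (any(tab < 2)) stop_input("each condition needs >= 2 replicates")
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0)
    return(data.frame(feature_id = character(), base_mean = numeric(),
                      log2fc = numeric(), se = numeric(), stat = numeric(),
                      p = numeric(), padj = numeric()))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts[, design$sample, drop = FALSE], 2,
                sf[design$sample], "/")
  sp <- design_split(norm, design)
  n_c <- ncol(sp$control); n_t <- ncol(sp$treatment)
  mu_c <- rowMeans(sp$control); mu_t <- rowMeans(sp$treatment)
  disp <- mom_dispersion(sp$control, sp$treatment, mode = disp_mode)
  lfc <- log2((mu_t + pseudo_count) / (mu_c + pseudo_count))
  # delta-method variance of log mean under NB: Var(log mu_hat) ~
  # (1/mu + alpha)/n per condition
  v_log <- (1 / (mu_c + pseudo_count) + disp) / n_c +
           (1 / (mu_t + pseudo_count) + disp) / n_t
  se <- sqrt(v_log) / log(2)
  if (lfc_threshold > 0) {
    stat <- (abs(lfc) - lfc_threshold) / se
    p <- pmin(1, 2 * pnorm(stat, lower.tail = FALSE))
  } else {
    stat <- lfc / se
    p <- 2 * pnorm(abs(stat), lower.tail = FALSE)
  }
  data.frame(feature_id = rownames(counts),
             base_mean = rowMeans(norm), log2fc = lfc, se = se, stat = stat,
             p = p, padj = bh_adjust(p), row.names = NULL)
}

#' Differential relative usage of a feature within its group
#'
#' Tests whether a feature's share of its group total (e.g. one intronic
#' peak or splice junction within its host gene) differs between
#' conditions. Shares are computed on size-factor-normalized counts with a
#' 0.5 pseudo-count; the effect is the difference of mean log2 shares
#' (log2 treatment share / control share), and the Wald variance combines
#' the empirical variance of per-sample log shares with an NB-propagated
#' floor so that features with no replicate scatter are not reported with
#' zero uncertainty.
#'
#' @param feature_counts feature x sample matrix.
#' @param group_total_counts matrix of the same shape: per feature, the
#'   group total (including the feature itself) in each sample.
#' @param design a [make_design()] object.
#' @param sf size factors (default: computed from `group_total_counts` when
#'   possible, else 1).
#' @param pseudo_count share pseudo-count (default 0.5).
#' @return data.frame (feature_id, base_mean, log2fc, se, stat, p, padj,
#'   filtered).
#' @export
relative_usage_test <- function(feature_counts, group_total_counts, design,
                                sf = NULL, pseudo_count = 0.5) {
  k <- as.matrix(feature_counts)
  tot <- as.matrix(group_total_counts)
  stopifnot(all(dim(k) == dim(tot)))
  if (any(k > tot + 1e-9)) stop_input("feature count exceeds its group total")
  if (is.null(rownames(k))) rownames(k) <- paste0("f", seq_len(nrow(k)))
  if (is.null(sf))
    sf <- tryCatch(size_factors(tot), error = function(e)
      setNames(rep(1, ncol(k)), colnames(k)))
  k <- sweep(k[, design$sample, drop = FALSE], 2, sf[design$sample], "/")
  tot <- sweep(tot[, design$sample, drop = FALSE], 2, sf[design$sample], "/")
  share <- (k + pseudo_count) / (tot + pseudo_count)
  ls <- log2(share)
  spl <- design_split(ls, design)
  kc <- design_split(k, design); totc <- design_split(tot, design)
  n_c <- ncol(spl$control); n_t <- ncol(spl$treatment)
  # a condition whose group total is zero in all samples leaves the share
  # undefined: filter the feature
  filtered <- rowSums(totc$control) == 0 | rowSums(totc$treatment) == 0
  m_c <- rowMeans(spl$control); m_t <- rowMeans(spl$treatment)
  lfc <- m_t - m_c
  # NB-propagated variance floor of a log2 share (binomial-style with NB
  # overdispersion), averaged over samples per condition
  vfloor <- function(kk, tt) {
    s <- (kk + pseudo_count) / (tt + pseudo_count)
    v <- (1 - s) / (kk + pseudo_count)
    rowMeans(v) / log(2)^2
  }
  v_c <- pmax(apply(spl$control, 1, var), vfloor(kc$control, totc$control))
  v_t <- pmax(apply(spl$treatment, 1, var),
              vfloor(kc$treatment, totc$treatment))
  se <- sqrt(v_c / n_c + v_t / n_t)
  stat <- lfc / se
  p <- 2 * pnorm(abs(stat), lower.tail = FALSE)
  p[filtered] <- NA
  padj <- rep(NA_real_, length(p))
  padj[!filtered] <- bh_adjust(p[!filtered])
  data.frame(feature_id = rownames(ls), base_mean = rowMeans(k),
             log2fc = ifelse(filtered, NA, lfc), se = se, stat = stat,
             p = p, padj = padj, filtered = filtered, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps the standard implementation after
#' validating the input).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Chi-square and odds ratio of a 2x2 table
#'
#' Pearson chi-square (no continuity correction by default) with 1 df, and
#' the cross-product odds ratio. A zero cell triggers the
#' Haldane-Anscombe 0.5 correction for the odds ratio (flagged); a zero
#' margin leaves the chi-square undefined (error).
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return list(chi2, p, odds_ratio, haldane_corrected).
#' @export
chi2_odds_ratio <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop_input("zero margin: chi-square undefined")
  dev <- abs(a * d - b * c_)
  if (correct) dev <- max(0, dev - n / 2)
  chi2 <- n * dev^2 / prod(margins)
  haldane <- any(tab == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       odds_ratio = (a * d) / (b * c_), haldane_corrected = haldane)
}
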