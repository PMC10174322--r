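# Wet-lab-style validation statistics: qRT-PCR relative quantification
# by the 2^-ddCt method and ROC/AUC biomarker evaluation with DeLong (or
# bootstrap) confidence intervals.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale per sample, then
#' `dCt = target_ct - reference_ct`, `ddCt = dCt - mean dCt of the
#' calibrator group`, and relative expression is `2^-ddCt`. Rows lacking
#' a reference measurement are dropped with a warning. Adding a constant
#' to every Ct value leaves the result unchanged.
#'
#' @param ct data frame with columns `sample_id`, `group`, `target_ct`,
#'   `reference_ct` (one row per technical replicate).
#' @param calibrator_group group label used as the calibrator (e.g. the
#'   sinus-rhythm controls).
#' @return data frame with one row per sample: `sample_id`, `group`,
#'   `dct`, `ddct`, `rel_expr`.
#' @export
ddct <- function(ct, calibrator_group) {
  stopifnot(all(c("sample_id", "group", "target_ct", "reference_ct")
                %in% names(ct)))
  bad <- !is.finite(ct$target_ct) | !is.finite(ct$reference_ct)
  if (any(bad)) {
    warning(sum(bad), " row(s) without a usable Ct measurement dropped")
    ct <- ct[!bad, , drop = FALSE]
  }
  if (!calibrator_group %in% ct$group)
    stop("calibrator group not present in the table")
  tc <- tapply(ct$target_ct, ct$sample_id, mean)
  rc <- tapply(ct$reference_ct, ct$sample_id, mean)
  grp <- ct$group[match(names(tc), ct$sample_id)]
  dct <- tc - rc
  ddct_v <- dct - mean(dct[grp == calibrator_group])
  out <- data.frame(sample_id = names(tc), group = grp,
                    dct = as.numeric(dct), ddct = as.numeric(ddct_v),
                    rel_expr = 2^(-as.numeric(ddct_v)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.roc_check <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores))
    stop("scores and labels differ in length")
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' Computed as the normalized rank-sum statistic with midranks for ties:
#' the probability that a random positive outranks a random negative,
#' counting ties as one half.
#'
#' @param scores numeric marker values (higher = more case-like).
#' @param labels logical (or 0/1): TRUE for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .roc_check(scores, labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components: for each positive the mean win rate over
# negatives, and vice versa
.delong_se <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  psi <- outer(pos, neg, function(x, y)
    ifelse(x > y, 1, ifelse(x == y, 0.5, 0)))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  sqrt(stats::var(v10) / length(pos) + stats::var(v01) / length(neg))
}

#' AUC with confidence interval and test against 0.5
#'
#' The default variance estimator is DeLong's structural-components
#' method; `method = "bootstrap"` resamples cases and controls
#' independently (stratified, fixed number of resamples). When the
#' DeLong variance degenerates (AUC of 0 or 1), the bootstrap fallback
#' is used automatically. The CI is `auc +/- z * SE` truncated to
#' `[0, 1]`, and `p_vs_half` is the two-sided normal-approximation
#' p-value against AUC = 0.5.
#'
#' @param scores,labels as in [roc_auc()]; at least 2 per class.
#' @param level confidence level (default 0.95).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (default 2000).
#' @param boot_seed RNG seed for the bootstrap.
#' @return list of class `roc_result`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `p_vs_half`, `n_pos`, `n_neg`, `method`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"), n_boot = 2000L,
                   boot_seed = 20L) {
  method <- match.arg(method)
  labels <- .roc_check(scores, labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 observations per class")
  auc <- roc_auc(scores, labels)
  se <- if (method == "delong") .delong_se(scores, labels) else NA_real_
  if (method == "bootstrap" || !is.finite(se) || se == 0) {
    if (method == "delong")
      message("degenerate DeLong variance; falling back to bootstrap")
    pos <- scores[labels]; neg <- scores[!labels]
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(boot_seed)
    reps <- vapply(seq_len(n_boot), function(i) {
      sp <- sample(pos, replace = TRUE)
      sn <- sample(neg, replace = TRUE)
      roc_auc(c(sp, sn), rep(c(TRUE, FALSE), c(length(sp), length(sn))))
    }, 0)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    se <- stats::sd(reps)
    method <- "bootstrap"
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se),
                 p_vs_half = p, n_pos = sum(labels), n_neg = sum(!labels),
                 method = method, level = level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f [%d%% CI %.3f-%.3f; p = %.3g vs 0.5] (%s, %d pos / %d neg)\n",
    x$auc, round(100 * x$level), x$ci_low, x$ci_high, x$p_vs_half,
    x$method, x$n_pos, x$n_neg))
  invisible(x)
}
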