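# Differential expression on count matrices: median-of-ratios
# normalization, method-of-moments dispersions with a 1/mu trend, and a
# conditional negative-binomial exact test per gene, followed by the
# p <= 0.05 & |log2FC| > 1 screen. Fold changes are oriented case/reference
# (second group level over first), so FC > 1 means up in the case group.

#' Median-of-ratios size factors
#'
#' `s_j = median_g counts[g, j] / geomean_g` over genes whose geometric
#' mean across all samples is positive (genes with any zero count carry no
#' ratio). Optionally rescaled so the geometric mean of the size factors
#' is 1, which fixes the overall scale without changing ratios.
#'
#' @param cm a [count_matrix] or plain counts matrix.
#' @param rescale rescale size factors to geometric mean 1 (default TRUE).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(cm, rescale = TRUE) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  loggeo <- rowMeans(log(k))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has positive counts in every sample; ",
         "consider a pseudo-reference on filtered genes")
  sf <- apply(k[use, , drop = FALSE], 2L,
              function(col) stats::median(exp(log(col) - loggeo[use])))
  if (rescale) sf <- sf / exp(mean(log(sf)))
  sf
}

#' Method-of-moments dispersions with a fitted 1/mu trend
#'
#' Per gene, on size-factor-normalized counts pooled within groups:
#' `alpha_hat = max(0, (v - xi * mu) / mu^2)` where `v` is the pooled
#' within-group variance, `mu` the normalized mean and
#' `xi = mean(1/s_j)` the Poisson (shot-noise) correction. A parametric
#' trend `alpha(mu) = a0 + a1/mu` is fitted by least squares over genes
#' with positive `alpha_hat`, and the final per-gene dispersion is the
#' maximum of the gene-wise estimate and the trend value (the conservative
#' sharing mode).
#'
#' @param cm a [count_matrix].
#' @param sf size factors from [estimate_size_factors()].
#' @return list with `alpha` (final per-gene dispersion), `alpha_gene`
#'   (raw gene-wise estimates), `trend` (coefficients `a0`, `a1`) and
#'   `base_mean` (normalized mean per gene).
#' @export
estimate_dispersions <- function(cm, sf) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- table(cm$group)
  if (any(tab < 2L))
    stop("need at least 2 replicates per group to estimate dispersion")
  z <- sweep(cm$counts, 2L, sf, "/")
  mu <- rowMeans(z)
  groups <- levels(cm$group)
  ssq <- 0
  for (g in groups) {
    zg <- z[, cm$group == g, drop = FALSE]
    ssq <- ssq + rowSums((zg - rowMeans(zg))^2)
  }
  v <- ssq / (ncol(z) - length(groups))
  xi <- mean(1 / sf)
  alpha_gene <- pmax(0, (v - xi * mu) / mu^2)
  alpha_gene[!is.finite(alpha_gene)] <- 0
  pos <- alpha_gene > 0 & mu > 0
  if (sum(pos) >= 2L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[pos]), alpha_gene[pos])
    a0 <- max(0, fit$coefficients[1L])
    a1 <- max(0, fit$coefficients[2L])
  } else {
    a0 <- 0; a1 <- 0
  }
  trend_val <- ifelse(mu > 0, a0 + a1 / mu, 0)
  list(alpha = pmax(alpha_gene, trend_val),
       alpha_gene = alpha_gene,
       trend = c(a0 = a0, a1 = a1),
       base_mean = mu)
}

#' Conditional negative-binomial exact test for one gene
#'
#' Tests equality of the two group means given the gene's total count
#' `K = sum(kA) + sum(kB)`. All splits `(a, K - a)` are enumerated;
#' `P(a) = f_A(a) * f_B(K - a)` where `f_A`, `f_B` are NB mass functions
#' with means `q0 * S_X` (pooled rate `q0 = K / (S_A + S_B)` times the
#' group's summed size factors) and variances
#' `mu_X + alpha * q0^2 * sum_{j in X} s_j^2`. The p-value is the total
#' probability of splits no more likely than the observed one, normalized
#' over all splits. `alpha = 0` reduces each `f` to Poisson, in which case
#' the test is equivalent to a binomial enumeration conditional on `K`.
#'
#' @param kA,kB integer count vectors for the reference and case group.
#' @param sfA,sfB size factors for the corresponding samples.
#' @param alpha gene dispersion (>= 0).
#' @return two-sided p-value in (0, 1]; `K = 0` returns 1 by convention.
#' @export
nbinom_exact_test <- function(kA, kB, sfA, sfB, alpha = 0) {
  stopifnot(alpha >= 0, length(kA) == length(sfA),
            length(kB) == length(sfB))
  K <- sum(kA) + sum(kB)
  if (K == 0) return(1)
  SA <- sum(sfA); SB <- sum(sfB)
  q0 <- K / (SA + SB)
  a <- 0:K
  dens <- function(x, S, ssq) {
    mu <- q0 * S
    extra <- alpha * q0^2 * ssq
    if (extra <= 0) stats::dpois(x, mu)
    else stats::dnbinom(x, mu = mu, size = mu^2 / extra)
  }
  p_all <- dens(a, SA, sum(sfA^2)) * dens(K - a, SB, sum(sfB^2))
  p_obs <- p_all[sum(kA) + 1L]
  tot <- sum(p_all)
  if (tot <= 0) return(1)
  # tolerance guards against ties lost to floating-point rounding
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]) / tot)
}

#' Label differential-expression calls
#'
#' Applies the screen `p <= p_max` and `|log2FC| > lfc_min`: `Up` needs
#' `log2FC > lfc_min`, `Down` needs `log2FC < -lfc_min`, everything else
#' is `NS`. Benjamini-Hochberg q-values are (re)computed over all tested
#' genes and reported alongside; the screen itself gates on the raw
#' p-value.
#'
#' @param results data frame with at least `log2FC` and `pValue` columns.
#' @param p_max,lfc_min screen thresholds.
#' @return `results` with `qValue` and `Regulation` columns set; the
#'   attribute `"n_called"` holds the Up/Down/NS tally.
#' @export
call_de <- function(results, p_max = 0.05, lfc_min = 1.0) {
  stopifnot(all(c("log2FC", "pValue") %in% names(results)))
  results$qValue <- stats::p.adjust(results$pValue, method = "BH")
  reg <- rep("NS", nrow(results))
  reg[results$pValue <= p_max & results$log2FC > lfc_min] <- "Up"
  reg[results$pValue <= p_max & results$log2FC < -lfc_min] <- "Down"
  results$Regulation <- reg
  attr(results, "n_called") <- c(Up = sum(reg == "Up"),
                                 Down = sum(reg == "Down"),
                                 NS = sum(reg == "NS"))
  results
}

#' Differential expression for a whole count matrix
#'
#' Full pipeline: size factors, dispersions, one exact test per gene,
#' fold changes of normalized group means (case over reference, i.e.
#' second group level over first), BH q-values and the Up/Down/NS screen.
#' Genes with zero counts in every sample have no defined fold change and
#' are dropped; their number is recorded in the `"n_dropped"` attribute.
#'
#' @param cm a [count_matrix]; the first group level is the reference.
#' @param p_max,lfc_min screen thresholds passed to [call_de()].
#' @return data frame with columns `id`, `mean_A`, `mean_B`, `FC`,
#'   `log2FC`, `pValue`, `qValue`, `Regulation`, in input gene order.
#' @export
run_diffexp <- function(cm, p_max = 0.05, lfc_min = 1.0) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cm$counts) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) with all-zero counts dropped")
  k <- cm$counts[keep, , drop = FALSE]
  cmk <- count_matrix(k, cm$group)
  sf <- estimate_size_factors(cmk)
  disp <- estimate_dispersions(cmk, sf)
  idxA <- cm$group == levels(cm$group)[1L]
  z <- sweep(k, 2L, sf, "/")
  mean_A <- rowMeans(z[, idxA, drop = FALSE])
  mean_B <- rowMeans(z[, !idxA, drop = FALSE])
  pv <- vapply(seq_len(nrow(k)), function(g)
    nbinom_exact_test(k[g, idxA], k[g, !idxA], sf[idxA], sf[!idxA],
                      disp$alpha[g]), 0)
  res <- data.frame(id = rownames(k),
                    mean_A = mean_A, mean_B = mean_B,
                    FC = mean_B / mean_A,
                    log2FC = log2(mean_B) - log2(mean_A),
                    pValue = pv,
                    stringsAsFactors = FALSE)
  res <- call_de(res, p_max = p_max, lfc_min = lfc_min)
  attr(res, "n_dropped") <- n_dropped
  attr(res, "size_factors") <- sf
  attr(res, "dispersion_trend") <- disp$trend
  rownames(res) <- NULL
  res
}

#' Write a differential-expression results table
#'
#' @param res result of [run_diffexp()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
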