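# Independent brute-force oracles used to validate the package's
# implementations on small instances.

# Conditional binomial enumeration: two-sided exact p for an observed
# split a of total K with success probability prob, summing outcomes no
# more likely than the observed one (relative tie tolerance implements
# exact rational ties in floating point).
binom_enum_oracle <- function(a_obs, K, prob) {
  p_all <- dbinom(0:K, K, prob)
  p_obs <- p_all[a_obs + 1L]
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]) / sum(p_all))
}

# Upper-tail hypergeometric by direct summation over outcomes with
# choose(), independent of phyper.
hyper_enum_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# AUC by brute-force pair counting with half-credit for ties.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# Benjamini-Hochberg step-up applied literally to sorted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive local alignment oracle with affine gaps and seed weighting:
# enumerates every pair of subsequence alignments recursively. Only
# feasible for tiny sequences; gaps allowed everywhere (compare with
# allow_seed_gaps = TRUE).
local_align_oracle <- function(mi, tx, params) {
  miv <- strsplit(mi, "", fixed = TRUE)[[1L]]
  txv <- strsplit(tx, "", fixed = TRUE)[[1L]]
  Lm <- length(miv)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  sub_score <- function(qi, tj) {
    m <- miv[Lm + 1L - qi]; t <- txv[tj]
    s <- if (t == wc[[m]]) params$match_score
         else if ((m == "G" && t == "U") || (m == "U" && t == "G"))
           params$wobble_score
         else params$mismatch
    mip <- Lm + 1L - qi
    if (mip >= params$seed_span[1L] && mip <= params$seed_span[2L])
      s * params$seed_weight else s
  }
  best <- 0
  max_col <- params$match_score * params$seed_weight
  # state: last consumed (i, j), score, gap state (0 none, 1 in-mi, 2 in-tx)
  recurse <- function(i, j, score, gap) {
    best <<- max(best, score)
    # bound: no extension can beat the incumbent
    if (score + max_col * min(Lm - i, length(txv) - j) <= best) return()
    if (i < Lm && j < length(txv))
      recurse(i + 1L, j + 1L, score + sub_score(i + 1L, j + 1L), 0L)
    if (i < Lm)
      recurse(i + 1L, j, score +
                (if (gap == 1L) params$gap_extend else params$gap_open), 1L)
    if (j < length(txv))
      recurse(i, j + 1L, score +
                (if (gap == 2L) params$gap_extend else params$gap_open), 2L)
  }
  for (i0 in seq_len(Lm)) for (j0 in seq_along(txv))
    recurse(i0, j0, sub_score(i0, j0), 0L)
  best
}

# small toy count matrix used across diffexp tests
toy_counts <- function(k, n_per_group = NULL) {
  k <- as.matrix(k)
  if (is.null(n_per_group)) n_per_group <- ncol(k) / 2
  rownames(k) <- sprintf("g%d", seq_len(nrow(k)))
  colnames(k) <- sprintf("s%d", seq_len(ncol(k)))
  count_matrix(k, rep(c("A", "B"), c(n_per_group, ncol(k) - n_per_group)))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), "")
}
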