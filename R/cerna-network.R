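# ceRNA network construction: sign-constrained Pearson coexpression
# screens on log2(normalized + 1) expression, MuTaME-style shared-MRE
# scoring of candidate lncRNA-mRNA sponge pairs, intersection into
# lncRNA-miRNA-mRNA triplets and export in Cytoscape-loadable formats.

#' Screening thresholds for the ceRNA network
#'
#' @param r_min minimum absolute Pearson correlation for an edge.
#' @param p_max maximum correlation p-value.
#' @param score_min minimum normalized MuTaME score (0-100 scale) for a
#'   retained pair. The default 0 disables the gate: the score is min-max
#'   normalized within each run, so an absolute cutoff is
#'   composition-dependent and the score is best used for ranking (see
#'   [top_axes()]); raise `score_min` to gate explicitly.
#' @param require_hyper additionally require the shared-miRNA
#'   hypergeometric test to pass.
#' @param hyper_p_max threshold for that test.
#' @return list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(r_min = 0.7, p_max = 0.05, score_min = 0,
                              require_hyper = FALSE, hyper_p_max = 0.05) {
  if (r_min <= 0 || r_min > 1) stop("r_min must be in (0, 1]")
  if (p_max <= 0 || p_max >= 1) stop("p_max must be in (0, 1)")
  if (score_min < 0 || score_min > 100) stop("score_min must be in [0, 100]")
  structure(list(r_min = r_min, p_max = p_max, score_min = score_min,
                 require_hyper = isTRUE(require_hyper),
                 hyper_p_max = hyper_p_max),
            class = "screen_thresholds")
}

#' log2(normalized count + 1) expression
#'
#' @param cm a [count_matrix].
#' @param sf size factors; estimated by [estimate_size_factors()] when
#'   missing.
#' @return matrix of log2(count/sf + 1) values.
#' @export
log_normalized <- function(cm, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  log2(sweep(cm$counts, 2L, sf, "/") + 1)
}

#' Sign-constrained Pearson coexpression edges between two layers
#'
#' Computes all pairwise Pearson correlations between the rows of `X` and
#' the rows of `Y` (same sample columns), with p-values from the
#' t-distribution (`t = r * sqrt((n-2)/(1-r^2))`, n-2 df, two-sided), and
#' keeps edges with the required sign, `|r| >= r_min` and `p <= p_max`.
#' Zero-variance features cannot be correlated and are skipped; their
#' number is recorded in the `"n_skipped"` attribute.
#'
#' @param X,Y numeric matrices (features x samples), e.g. from
#'   [log_normalized()]; identical sample columns required.
#' @param sign `"negative"` or `"positive"`: which correlations to keep.
#' @param th a [screen_thresholds()].
#' @return data frame with columns `id_a` (row of X), `id_b` (row of Y),
#'   `r`, `p`, `n`.
#' @export
pearson_edges <- function(X, Y, sign = c("negative", "positive"),
                          th = screen_thresholds()) {
  sign <- match.arg(sign)
  if (ncol(X) != ncol(Y) ||
      (!is.null(colnames(X)) && !is.null(colnames(Y)) &&
       !identical(colnames(X), colnames(Y))))
    stop("X and Y must share the same sample columns")
  n <- ncol(X)
  if (n < 3L) stop("need at least 3 samples for a correlation edge")
  okx <- apply(X, 1L, stats::sd) > 0
  oky <- apply(Y, 1L, stats::sd) > 0
  n_skipped <- sum(!okx) + sum(!oky)
  Xu <- X[okx, , drop = FALSE]; Yu <- Y[oky, , drop = FALSE]
  out <- data.frame(id_a = character(0), id_b = character(0),
                    r = numeric(0), p = numeric(0), n = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(Xu) > 0 && nrow(Yu) > 0) {
    R <- stats::cor(t(Xu), t(Yu))
    keep_sign <- if (sign == "negative") R < 0 else R > 0
    r2 <- pmin(R^2, 1 - 1e-15)
    tt <- abs(R) * sqrt((n - 2) / (1 - r2))
    P <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
    sel <- which(keep_sign & abs(R) >= th$r_min & P <= th$p_max,
                 arr.ind = TRUE)
    if (nrow(sel) > 0) {
      out <- data.frame(id_a = rownames(Xu)[sel[, 1L]],
                        id_b = rownames(Yu)[sel[, 2L]],
                        r = R[sel], p = P[sel], n = n,
                        stringsAsFactors = FALSE)
      out <- out[order(out$id_a, out$id_b), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

# per-miRNA site statistics on one transcript: density and spread
.site_stats <- function(starts, tx_len, w = 7) {
  n <- length(starts)
  if (n >= 2L) {
    starts <- sort(starts)
    gaps <- diff(starts)
    list(d = n / (starts[n] - starts[1L] + w),
         e = min(gaps) / mean(gaps))
  } else {
    list(d = 1 / tx_len, e = 1)
  }
}

#' MuTaME-style ceRNA score for candidate lncRNA-mRNA pairs
#'
#' For each pair (A = lncRNA, B = mRNA) with shared miRNA set `M` (miRNAs
#' hitting both transcripts), four components are combined:
#' \describe{
#'   \item{S1}{`|M|^2 / (|M_A| * |M_B|)` — fraction of each transcript's
#'     targeting miRNAs that is shared.}
#'   \item{S2}{mean over shared miRNAs and the two transcripts of the
#'     site density `n / (span + 7)` (single-site transcripts contribute
#'     `1/length`).}
#'   \item{S3}{mean of the site-spread ratio `min(gap)/mean(gap)` (1 for
#'     fewer than two sites).}
#'   \item{S4}{shared-miRNA hits as a fraction of all hits on the pair.}
#' }
#' `raw = ln S1 + ln S2 + ln S3 + ln S4` (components floored at 1e-12)
#' and the reported `score` is `raw` min-max normalized to 0-100 across
#' all evaluated pairs (a single pair, or all-equal raws, scores 100).
#' Pairs with no shared miRNA are excluded.
#'
#' @param pairs data frame with columns `lnc_id`, `mrna_id`.
#' @param hits MRE hit table from [predict_targets()], already restricted
#'   to the miRNAs of interest (e.g. DE miRNAs).
#' @param de_mirnas character vector: the miRNA universe whose hits count.
#' @param tx_len named vector of transcript lengths (nt).
#' @return data frame with `lnc_id`, `mrna_id`, `n_shared`, `s1`-`s4`,
#'   `raw`, `score`, `shared_mirnas` (comma-separated ids).
#' @export
mutame_score <- function(pairs, hits, de_mirnas, tx_len) {
  hits <- hits[hits$mirna_id %in% de_mirnas, , drop = FALSE]
  empty <- data.frame(lnc_id = character(0), mrna_id = character(0),
                      n_shared = integer(0), n_mi_lnc = integer(0),
                      n_mi_mrna = integer(0), s1 = numeric(0),
                      s2 = numeric(0), s3 = numeric(0), s4 = numeric(0),
                      raw = numeric(0), score = numeric(0),
                      shared_mirnas = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || nrow(hits) == 0L) return(empty)
  bytx <- split(hits, hits$transcript_id)
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    A <- pairs$lnc_id[r]; B <- pairs$mrna_id[r]
    hA <- bytx[[A]]; hB <- bytx[[B]]
    if (is.null(hA) || is.null(hB)) next
    MA <- unique(hA$mirna_id); MB <- unique(hB$mirna_id)
    M <- intersect(MA, MB)
    if (length(M) == 0L) next
    s1 <- length(M)^2 / (length(MA) * length(MB))
    d_k <- e_k <- numeric(length(M))
    n_shared_hits <- 0L
    for (i in seq_along(M)) {
      stA <- .site_stats(hA$start[hA$mirna_id == M[i]], tx_len[[A]])
      stB <- .site_stats(hB$start[hB$mirna_id == M[i]], tx_len[[B]])
      d_k[i] <- (stA$d + stB$d) / 2
      e_k[i] <- (stA$e + stB$e) / 2
      n_shared_hits <- n_shared_hits + sum(hA$mirna_id == M[i]) +
        sum(hB$mirna_id == M[i])
    }
    s2 <- mean(d_k); s3 <- mean(e_k)
    s4 <- n_shared_hits / (nrow(hA) + nrow(hB))
    raw <- sum(log(pmax(c(s1, s2, s3, s4), 1e-12)))
    rows[[length(rows) + 1L]] <-
      data.frame(lnc_id = A, mrna_id = B, n_shared = length(M),
                 n_mi_lnc = length(MA), n_mi_mrna = length(MB),
                 s1 = s1, s2 = s2, s3 = s3, s4 = s4, raw = raw,
                 score = NA_real_,
                 shared_mirnas = paste(sort(M), collapse = ","),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rng <- range(out$raw)
  out$score <- if (diff(rng) > 0)
    100 * (out$raw - rng[1L]) / diff(rng) else rep(100, nrow(out))
  rownames(out) <- NULL
  out
}

#' Hypergeometric test for shared-miRNA enrichment of a ceRNA pair
#'
#' Probability of an overlap at least as large as observed when `n_b`
#' miRNAs are drawn without replacement from a universe of `n_universe`
#' containing `n_a` "successes" (the partner's miRNAs).
#'
#' @param n_shared observed shared-miRNA count `|M|`.
#' @param n_a,n_b per-transcript targeting miRNA counts `|M_A|`, `|M_B|`.
#' @param n_universe number of miRNAs in the universe (e.g. all DE
#'   miRNAs).
#' @return upper-tail p-value; `n_shared = 0` gives 1.
#' @export
shared_mirna_test <- function(n_shared, n_a, n_b, n_universe) {
  if (n_a > n_universe || n_b > n_universe ||
      n_shared > min(n_a, n_b) || min(n_shared, n_a, n_b) < 0)
    stop("inconsistent set sizes for the hypergeometric test")
  if (n_shared == 0) return(1)
  stats::phyper(n_shared - 1L, n_a, n_universe - n_a, n_b,
                lower.tail = FALSE)
}

#' Assemble lncRNA-miRNA-mRNA triplets and the ceRNA network
#'
#' A triplet (L, k, G) is emitted iff the miRNA k is negatively
#' correlated with both L and G, L and G are positively correlated, k is
#' among the pair's shared MRE miRNAs, the pair's MuTaME score passes
#' `th$score_min`, and (optionally) the shared-miRNA hypergeometric test
#' passes. Every emitted triplet therefore satisfies the ceRNA sign
#' pattern (-, -, +).
#'
#' @param neg_mi_lnc,neg_mi_mrna negative-correlation edge tables from
#'   [pearson_edges()] with miRNAs in `id_a`.
#' @param pos_lnc_mrna positive-correlation edge table with lncRNAs in
#'   `id_a`, mRNAs in `id_b`.
#' @param pairs scored pair table from [mutame_score()].
#' @param th a [screen_thresholds()].
#' @param n_mirna_universe universe size for the optional hypergeometric
#'   gate (required when `th$require_hyper`).
#' @return list of class `cerna_network`: `triplets` (one row per
#'   triplet, with the three correlation values and pair score), `nodes`
#'   (id, type), `edges` (source, target, relation, r, p, score).
#' @export
assemble_network <- function(neg_mi_lnc, neg_mi_mrna, pos_lnc_mrna,
                             pairs, th = screen_thresholds(),
                             n_mirna_universe = NULL) {
  pairs_kept <- pairs[pairs$score >= th$score_min, , drop = FALSE]
  trip <- list()
  if (nrow(pairs_kept) > 0 && nrow(pos_lnc_mrna) > 0) {
    key_lg <- paste(pos_lnc_mrna$id_a, pos_lnc_mrna$id_b)
    key_ml <- paste(neg_mi_lnc$id_a, neg_mi_lnc$id_b)
    key_mg <- paste(neg_mi_mrna$id_a, neg_mi_mrna$id_b)
    for (r in seq_len(nrow(pairs_kept))) {
      L <- pairs_kept$lnc_id[r]; G <- pairs_kept$mrna_id[r]
      i_lg <- match(paste(L, G), key_lg)
      if (is.na(i_lg)) next
      M <- strsplit(pairs_kept$shared_mirnas[r], ",", fixed = TRUE)[[1L]]
      if (th$require_hyper) {
        if (is.null(n_mirna_universe))
          stop("n_mirna_universe required when require_hyper is set")
        hp <- shared_mirna_test(pairs_kept$n_shared[r],
                                pairs_kept$n_mi_lnc[r],
                                pairs_kept$n_mi_mrna[r],
                                n_mirna_universe)
        if (hp > th$hyper_p_max) next
      }
      for (k in M) {
        i_ml <- match(paste(k, L), key_ml)
        i_mg <- match(paste(k, G), key_mg)
        if (is.na(i_ml) || is.na(i_mg)) next
        trip[[length(trip) + 1L]] <- data.frame(
          lnc_id = L, mi_id = k, mrna_id = G,
          r_mi_lnc = neg_mi_lnc$r[i_ml], r_mi_mrna = neg_mi_mrna$r[i_mg],
          r_lnc_mrna = pos_lnc_mrna$r[i_lg],
          p_mi_lnc = neg_mi_lnc$p[i_ml], p_mi_mrna = neg_mi_mrna$p[i_mg],
          p_lnc_mrna = pos_lnc_mrna$p[i_lg],
          score = pairs_kept$score[r], raw = pairs_kept$raw[r],
          stringsAsFactors = FALSE)
      }
    }
  }
  triplets <- if (length(trip)) do.call(rbind, trip) else
    data.frame(lnc_id = character(0), mi_id = character(0),
               mrna_id = character(0), r_mi_lnc = numeric(0),
               r_mi_mrna = numeric(0), r_lnc_mrna = numeric(0),
               p_mi_lnc = numeric(0), p_mi_mrna = numeric(0),
               p_lnc_mrna = numeric(0), score = numeric(0),
               raw = numeric(0), stringsAsFactors = FALSE)
  triplets <- triplets[order(triplets$lnc_id, triplets$mi_id,
                             triplets$mrna_id), , drop = FALSE]
  rownames(triplets) <- NULL
  stopifnot(all(triplets$r_mi_lnc < 0), all(triplets$r_mi_mrna < 0),
            all(triplets$r_lnc_mrna > 0))
  node_df <- function(ids, type)
    data.frame(id = ids, type = rep(type, length(ids)),
               stringsAsFactors = FALSE)
  nodes <- rbind(node_df(unique(triplets$lnc_id), "lncRNA"),
                 node_df(unique(triplets$mi_id), "miRNA"),
                 node_df(unique(triplets$mrna_id), "mRNA"))
  edge_df <- function(src, tgt, relation, r, p, score)
    data.frame(source = src, target = tgt,
               relation = rep(relation, length(src)), r = r, p = p,
               score = score, stringsAsFactors = FALSE)
  edges <- unique(rbind(
    edge_df(triplets$mi_id, triplets$lnc_id, "mi_lnc",
            triplets$r_mi_lnc, triplets$p_mi_lnc,
            rep(NA_real_, nrow(triplets))),
    edge_df(triplets$mi_id, triplets$mrna_id, "mi_mrna",
            triplets$r_mi_mrna, triplets$p_mi_mrna,
            rep(NA_real_, nrow(triplets))),
    edge_df(triplets$lnc_id, triplets$mrna_id, "lnc_mrna",
            triplets$r_lnc_mrna, triplets$p_lnc_mrna, triplets$score)))
  edges <- edges[order(edges$relation, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(triplets = triplets, nodes = nodes, edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(factor(x$nodes$type, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "ceRNA network: %d triplets; %d lncRNAs, %d miRNAs, %d mRNAs; %d edges\n",
    nrow(x$triplets), tt[["lncRNA"]], tt[["miRNA"]], tt[["mRNA"]],
    nrow(x$edges)))
  invisible(x)
}

#' Top-N ceRNA axes
#'
#' Sorts triplets by pair score (descending), then `|r(lnc, mRNA)|`
#' (descending), then lexicographically by (lnc, miRNA, mRNA), and
#' returns the first `n`. Deterministic under permutation of the input.
#'
#' @param triplets triplet table from [assemble_network()].
#' @param n number of axes to keep (default 200).
#' @return the sorted head of the triplet table.
#' @export
top_axes <- function(triplets, n = 200L) {
  if (n <= 0) stop("n must be positive")
  ord <- order(-triplets$score, -abs(triplets$r_lnc_mrna),
               triplets$lnc_id, triplets$mi_id, triplets$mrna_id)
  out <- triplets[ord, , drop = FALSE][seq_len(min(n, nrow(triplets))), ,
                                       drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a ceRNA network as SIF plus attribute tables
#'
#' Writes `network.sif` (lines `source relation target`), `nodes.tsv` and
#' `edges.tsv`, all Cytoscape-loadable and byte-stable for a fixed
#' network.
#'
#' @param net a `cerna_network`.
#' @param dir output directory (created if missing).
#' @param node_attrs optional data frame keyed by `id` (e.g. log2FC,
#'   Regulation) merged into the node table.
#' @return character vector of the three file paths, invisibly.
#' @export
export_network <- function(net, dir, node_attrs = NULL) {
  stopifnot(inherits(net, "cerna_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(dir, "network.sif")
  writeLines(paste(net$edges$source, net$edges$relation, net$edges$target),
             sif)
  nodes <- net$nodes
  if (!is.null(node_attrs))
    nodes <- merge(nodes, node_attrs, by = "id", all.x = TRUE, sort = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  nf <- file.path(dir, "nodes.tsv")
  utils::write.table(nodes, nf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ef <- file.path(dir, "edges.tsv")
  utils::write.table(net$edges, ef, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sif, nf, ef))
}
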