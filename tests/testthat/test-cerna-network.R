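mk_expr <- function(m, prefix) {
  rownames(m) <- sprintf("%s%d", prefix, seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

test_that("pearson edges keep the requested sign at the hand-worked value", {
  x <- mk_expr(rbind(c(1, 2, 3, 4)), "x")
  y <- mk_expr(rbind(c(2, 4, 6, 9), -c(1, 2, 3, 4) + 10), "y")
  th <- screen_thresholds(r_min = 0.7, p_max = 0.05)
  pos <- pearson_edges(x, y, "positive", th)
  expect_equal(nrow(pos), 1)
  # hand value: cov 11.5 / sqrt(5 * 26.75)
  expect_equal(pos$r, 11.5 / sqrt(5 * 26.75), tolerance = 1e-9)
  expect_equal(pos$r, 0.9944, tolerance = 1e-4)
  neg <- pearson_edges(x, y, "negative", th)
  expect_equal(neg$id_b, "y2")
  expect_equal(neg$r, -1)
  # zero-variance features are skipped, not propagated as NA
  y2 <- rbind(y, y3 = rep(5, 4))
  out <- pearson_edges(x, y2, "positive", th)
  expect_equal(attr(out, "n_skipped"), 1)
  expect_error(pearson_edges(x, y[, 1:3, drop = FALSE], "positive", th),
               "sample")
})

test_that("null retention of the correlation screen matches theory", {
  # P(|r| >= 0.7 at n = 8) ~ 0.053 under independence; the one-sided
  # positive screen keeps half of that
  set.seed(41)
  n_rep <- 4000
  x <- matrix(rnorm(8 * n_rep), n_rep)
  y <- matrix(rnorm(8 * n_rep), n_rep)
  r <- vapply(seq_len(n_rep), function(i) cor(x[i, ], y[i, ]), 0)
  p_theory <- 0.053
  expect_lt(abs(mean(abs(r) >= 0.7) - p_theory), 0.015)
})

test_that("MuTaME components reproduce the hand-worked toy pair", {
  hits <- data.frame(
    mirna_id = "k", transcript_id = c("A", "A", "B", "B", "B"),
    start = c(10, 50, 20, 90, 160), end = c(17, 57, 27, 97, 167),
    score = 150, seed_class = "8mer", stringsAsFactors = FALSE)
  ps <- mutame_score(data.frame(lnc_id = "A", mrna_id = "B"),
                     hits, "k", c(A = 100, B = 200))
  expect_equal(ps$s1, 1)
  expect_equal(ps$s2, (2 / 47 + 3 / 147) / 2, tolerance = 1e-9)
  expect_equal(ps$s3, 1)   # single gap on A; equal gaps 70,70 on B
  expect_equal(ps$s4, 1)
  expect_equal(ps$raw, -3.4585, tolerance = 1e-4)
  expect_equal(ps$score, 100)  # single evaluated pair
})

test_that("MuTaME scores are bounded and min-max normalized", {
  set.seed(51)
  # several pairs with varying site layouts
  mk_hits <- function(tx, starts, mi = "k1")
    data.frame(mirna_id = mi, transcript_id = tx, start = starts,
               end = starts + 7, score = 150, seed_class = "8mer",
               stringsAsFactors = FALSE)
  hits <- rbind(mk_hits("L1", c(5, 40)), mk_hits("G1", c(10, 300)),
                mk_hits("L2", c(5, 12)), mk_hits("G2", c(10, 20)),
                mk_hits("L3", 77), mk_hits("G3", c(15, 400, 700)),
                mk_hits("L3", 200, "k2"), mk_hits("G3", 100, "k2"))
  pairs <- data.frame(lnc_id = c("L1", "L2", "L3"),
                      mrna_id = c("G1", "G2", "G3"))
  lens <- c(L1 = 500, G1 = 800, L2 = 500, G2 = 500, L3 = 600, G3 = 900)
  ps <- mutame_score(pairs, hits, c("k1", "k2"), lens)
  expect_true(all(ps$s1 > 0 & ps$s1 <= 1))
  expect_true(all(ps$s3 > 0 & ps$s3 <= 1))
  expect_true(all(ps$s4 > 0 & ps$s4 <= 1))
  expect_true(all(ps$score >= 0 & ps$score <= 100))
  expect_equal(ps$score[which.max(ps$raw)], 100)
  expect_equal(ps$score[which.min(ps$raw)], 0)
  # normalization is invariant under affine transforms of raw
  rescaled <- 100 * (2 * ps$raw + 7 - min(2 * ps$raw + 7)) /
    (diff(range(2 * ps$raw + 7)))
  expect_equal(ps$score, rescaled)
  # a pair without shared miRNAs is excluded
  ps2 <- mutame_score(data.frame(lnc_id = "L1", mrna_id = "G2"),
                      hits, c("k1", "k2"), lens)
  expect_equal(nrow(ps2), 1)  # k1 hits both L1 and G2 -> still shared
  ps3 <- mutame_score(data.frame(lnc_id = "L1", mrna_id = "XX"),
                      hits, c("k1", "k2"), lens)
  expect_equal(nrow(ps3), 0)
})

test_that("shared-miRNA hypergeometric test matches enumeration", {
  expect_equal(shared_mirna_test(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(shared_mirna_test(0, 4, 4, 10), 1)
  for (N in c(6, 9, 12)) for (na in 0:N) for (nb in 0:N) {
    k <- max(0, na + nb - N):min(na, nb)
    for (kk in k)
      expect_equal(shared_mirna_test(kk, na, nb, N),
                   hyper_enum_oracle(kk, na, nb, N), tolerance = 1e-12)
  }
  expect_error(shared_mirna_test(3, 2, 5, 10), "inconsistent")
})

test_that("triplet assembly enforces intersection semantics and signs", {
  neg_ml <- data.frame(id_a = "k1", id_b = "L1", r = -0.9, p = 0.001,
                       n = 10)
  neg_mg <- data.frame(id_a = "k1", id_b = "G1", r = -0.85, p = 0.002,
                       n = 10)
  pos_lg <- data.frame(id_a = "L1", id_b = "G1", r = 0.92, p = 0.001,
                       n = 10)
  pairs <- data.frame(lnc_id = "L1", mrna_id = "G1", n_shared = 1L,
                      n_mi_lnc = 1L, n_mi_mrna = 1L, s1 = 1, s2 = 0.05,
                      s3 = 1, s4 = 1, raw = -3, score = 100,
                      shared_mirnas = "k1", stringsAsFactors = FALSE)
  net <- assemble_network(neg_ml, neg_mg, pos_lg, pairs)
  expect_equal(nrow(net$triplets), 1)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes$type, c("lncRNA", "miRNA", "mRNA"))
  # dropping the positive lnc-mRNA edge removes the triplet
  net2 <- assemble_network(neg_ml, neg_mg, pos_lg[0, ], pairs)
  expect_equal(nrow(net2$triplets), 0)
  # a miRNA not among the shared set does not form a triplet
  neg_ml2 <- transform(neg_ml, id_a = "k2")
  net3 <- assemble_network(neg_ml2, neg_mg, pos_lg, pairs)
  expect_equal(nrow(net3$triplets), 0)
  # empty pair list -> empty network
  net4 <- assemble_network(neg_ml, neg_mg, pos_lg, pairs[0, ])
  expect_equal(nrow(net4$triplets), 0)
  expect_equal(nrow(net4$nodes), 0)
  # optional hypergeometric gate: 1 shared of 1x1 in a universe of 25 is
  # significant at 0.05 (p = 1/25)
  th_h <- screen_thresholds(require_hyper = TRUE)
  net5 <- assemble_network(neg_ml, neg_mg, pos_lg, pairs, th_h,
                           n_mirna_universe = 25)
  expect_equal(nrow(net5$triplets), 1)
  net6 <- assemble_network(neg_ml, neg_mg, pos_lg, pairs, th_h,
                           n_mirna_universe = 10)
  expect_equal(nrow(net6$triplets), 0)  # p = 1/10 > 0.05
})

test_that("top axes ranking is deterministic with documented tie-breaks", {
  tr <- data.frame(
    lnc_id = c("L2", "L1", "L1", "L3"),
    mi_id = c("k1", "k1", "k2", "k1"),
    mrna_id = c("G1", "G1", "G2", "G3"),
    r_mi_lnc = -0.9, r_mi_mrna = -0.9,
    r_lnc_mrna = c(0.8, 0.8, 0.95, 0.9),
    p_mi_lnc = 0.01, p_mi_mrna = 0.01, p_lnc_mrna = 0.01,
    score = c(70, 70, 70, 90), raw = 0, stringsAsFactors = FALSE)
  top <- top_axes(tr, 3)
  # highest score first; then |r|; then lexicographic (L1 before L2)
  expect_equal(top$lnc_id, c("L3", "L1", "L1"))
  expect_equal(top$mi_id[2:3], c("k2", "k1"))
  # permutation invariance and N larger than the table
  expect_equal(top_axes(tr[c(3, 1, 4, 2), ], 3), top)
  expect_equal(nrow(top_axes(tr, 100)), 4)
  expect_error(top_axes(tr, 0), "positive")
})

test_that("network export writes byte-stable Cytoscape files", {
  neg_ml <- data.frame(id_a = "k1", id_b = "L1", r = -0.9, p = 0.001, n = 10)
  neg_mg <- data.frame(id_a = "k1", id_b = c("G1", "G2"), r = -0.85,
                       p = 0.002, n = 10)
  pos_lg <- data.frame(id_a = "L1", id_b = c("G1", "G2"), r = 0.92,
                       p = 0.001, n = 10)
  pairs <- data.frame(lnc_id = "L1", mrna_id = c("G1", "G2"),
                      n_shared = 1L, n_mi_lnc = 1L, n_mi_mrna = 1L,
                      s1 = 1, s2 = 0.05, s3 = 1, s4 = 1, raw = -3,
                      score = 100, shared_mirnas = "k1",
                      stringsAsFactors = FALSE)
  net <- assemble_network(neg_ml, neg_mg, pos_lg, pairs)
  # two triplets share the mi-lnc edge: 5 unique edges, 6 SIF-able rows
  expect_equal(nrow(net$triplets), 2)
  expect_equal(nrow(net$edges), 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_network(net, d1)
  export_network(net, d2)
  expect_equal(length(readLines(file.path(d1, "network.sif"))), 5)
  for (f in c("network.sif", "nodes.tsv", "edges.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("tightening thresholds yields nested networks on synthetic data", {
  cfg <- synthetic_config(n_per_group = 12, n_lnc = 25, n_mi = 22,
                          n_mrna = 30, n_triplets = 12, coupling = 0.8,
                          seed = 61)
  ds <- simulate_ce_dataset(cfg)
  key <- function(net) paste(net$triplets$lnc_id, net$triplets$mi_id,
                             net$triplets$mrna_id)
  b_loose <- planted_triplet_benchmark(ds, screen_thresholds(r_min = 0.6))
  b_tight <- planted_triplet_benchmark(ds, screen_thresholds(r_min = 0.9))
  expect_true(all(key(b_tight$result$network) %in%
                  key(b_loose$result$network)))
})
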