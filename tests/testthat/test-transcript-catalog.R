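rec <- function(id, len, exons, biotype = "lncRNA_candidate",
                annotated = FALSE, chrom = "chr1", strand = "+",
                start = 1000, end = start + len - 1) {
  data.frame(id = id, chrom = chrom, strand = strand, start = start,
             end = end, exon_count = exons, biotype = biotype,
             length = len, annotated = annotated,
             stringsAsFactors = FALSE)
}

test_that("lncRNA candidate filter applies the length and exon rules", {
  records <- rbind(
    rec("short_multi", 150, 3),          # too short
    rec("boundary", 201, 2),             # exactly at the boundary: kept
    rec("at200", 200, 2),                # 200 nt is not > 200
    rec("long_single_novel", 5000, 1),   # novel single-exon: dropped
    rec("long_single_known", 5000, 1, annotated = TRUE),  # known: kept
    rec("coding", 900, 4, biotype = "protein_coding"))
  out <- filter_lncrna_candidates(records)
  expect_setequal(out$id, c("boundary", "long_single_known"))
  # idempotent
  expect_identical(filter_lncrna_candidates(out), out)
  expect_equal(nrow(filter_lncrna_candidates(records[0, ])), 0)
})

test_that("orientation classification follows overlap, strand and tie rules", {
  lnc <- rbind(rec("l_anti", 401, 2, strand = "+", start = 100, end = 500),
               rec("l_none", 401, 2, strand = "+", start = 10000,
                   end = 10400),
               rec("l_tie", 401, 2, strand = "+", start = 100, end = 500))
  coding <- rbind(
    rec("c_minus", 601, 5, biotype = "protein_coding", strand = "-",
        start = 300, end = 900),
    # same overlap span as c_minus but on + strand: antisense wins ties
    rec("c_plus", 601, 5, biotype = "protein_coding", strand = "+",
        start = 300, end = 900))
  out <- classify_orientation(lnc, coding)
  expect_equal(out$class[out$id == "l_anti"], "antisense")
  expect_equal(out$partner[out$id == "l_anti"], "c_minus")
  expect_equal(out$class[out$id == "l_none"], "unclassified")
  expect_equal(out$overlap[out$id == "l_anti"], 201L)
  # permutation invariance
  out2 <- classify_orientation(lnc[c(3, 1, 2), ], coding[2:1, ])
  expect_equal(out2[order(out2$id), ]$class, out[order(out$id), ]$class)
  expect_error(classify_orientation(transform(lnc, strand = "*"), coding),
               "strand")
})

test_that("orientation classes are exhaustive and the share arithmetic holds", {
  expect_equal(antisense_share_pct(19894, 9171), 68.45)
  lnc <- do.call(rbind, lapply(1:20, function(i)
    rec(sprintf("l%02d", i), 300, 2, start = i * 1000, end = i * 1000 + 299,
        strand = sample(c("+", "-"), 1))))
  coding <- rec("c1", 5001, 10, biotype = "protein_coding", start = 1000,
                end = 6000)
  out <- classify_orientation(lnc, coding)
  s <- catalog_summary(lnc, orientation = out)
  expect_equal(s$n_sense + s$n_antisense + s$n_unclassified, s$n_total)
  expect_equal(sum(s$length_histogram), s$n_total)
  expect_equal(sum(s$exon_histogram), s$n_total)
})

test_that("FPKM follows the definition and its invariances", {
  k <- matrix(c(10, 0, 37, 5, 2, 8), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  # unit case: count 10, length 1000, library 10^6 reads
  k1 <- matrix(c(10, 1e6 - 10), 2, 1,
               dimnames = list(c("a", "filler"), "s"))
  f1 <- compute_fpkm(k1, c(a = 1000, filler = 1000))
  expect_equal(f1["a", "s"], 10)
  # hand-computed: 37 * 1e9 / (2500 * 3.2e6) = 4.625
  k2 <- matrix(c(37, 3.2e6 - 37), 2, 1,
               dimnames = list(c("x", "filler"), "s"))
  expect_equal(compute_fpkm(k2, c(x = 2500, filler = 1000))["x", "s"],
               4.625)
  # zero count -> 0, and log transform maps it to 0
  f <- compute_fpkm(k, c(a = 500, b = 800, c = 1200))
  expect_equal(f["b", "s1"], 0)
  expect_equal(log10_fpkm1(f)["b", "s1"], 0)
  # doubling a sample's counts leaves its FPKM unchanged
  k3 <- k; k3[, 2] <- k3[, 2] * 2
  f3 <- compute_fpkm(k3, c(a = 500, b = 800, c = 1200))
  expect_equal(f3[, 2], f[, 2])
  expect_error(compute_fpkm(k, c(a = 0, b = 800, c = 1200)), "positive")
})

test_that("sample PCA matches the closed-form 2x2 eigen decomposition", {
  x <- matrix(c(1, 3, 2, 5), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  p <- pca_samples(x)
  expect_equal(sum(p$var_frac), 1)
  # 2 samples, gene-centered -> rank 1: PC1 carries everything
  expect_equal(p$var_frac[1], 1)
  # coordinates reproduce the centered matrix through the loadings
  expect_equal(p$loadings %*% t(p$coords), x - rowMeans(x),
               ignore_attr = TRUE)
  # identical samples get identical coordinates
  x2 <- cbind(x, s3 = x[, 2])
  p2 <- pca_samples(x2)
  expect_equal(p2$coords["s2", ], p2$coords["s3", ])
  expect_warning(pca_samples(matrix(1, 3, 3,
                                    dimnames = list(letters[1:3],
                                                    LETTERS[1:3]))),
                 "constant")
})
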