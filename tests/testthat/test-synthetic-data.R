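test_that("generator honours the config and is deterministic", {
  cfg <- synthetic_config(n_per_group = 4, n_lnc = 20, n_mi = 10,
                          n_mrna = 1000, frac_de = 0.1, n_triplets = 0,
                          seed = 42)
  g1 <- generate_counts(cfg)
  g2 <- generate_counts(cfg)
  expect_identical(g1$layers$mrna$counts, g2$layers$mrna$counts)
  expect_identical(g1$truth$de, g2$truth$de)
  # frac_de * n planted DE features, exactly
  expect_equal(nrow(g1$truth$de$mrna), 100)
  expect_true(all(g1$truth$de$mrna$id %in% rownames(g1$layers$mrna$counts)))
  # no planted effects when frac_de = 0
  g0 <- generate_counts(synthetic_config(frac_de = 0, n_triplets = 0,
                                         seed = 1))
  expect_true(all(vapply(g0$truth$de, nrow, 0L) == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_per_group = 2), "n_per_group")
  expect_error(synthetic_config(frac_de = 1.2), "frac_de")
  expect_error(synthetic_config(coupling = 0), "coupling")
  expect_error(synthetic_config(n_lnc = 5, n_mi = 5, n_mrna = 5,
                                n_triplets = 6), "n_triplets")
  expect_error(synthetic_config(seq_len_range = c(10, 20)),
               "seq_len_range")
})

test_that("planted triplets carry the ceRNA correlation sign pattern", {
  cfg <- synthetic_config(n_per_group = 50, n_lnc = 110, n_mi = 105,
                          n_mrna = 120, n_triplets = 100, coupling = 1,
                          frac_de = 0, seed = 7)
  g <- generate_counts(cfg)
  g <- generate_triplets(cfg, g$layers, g$truth)
  expr <- lapply(g$layers, log_normalized)
  tr <- g$truth$triplets
  r_lg <- r_ml <- r_mg <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    el <- expr$lnc[tr$lnc_id[i], ]
    em <- expr$mi[tr$mi_id[i], ]
    eg <- expr$mrna[tr$mrna_id[i], ]
    r_lg[i] <- cor(el, eg); r_ml[i] <- cor(em, el); r_mg[i] <- cor(em, eg)
  }
  expect_gt(mean(r_lg), 0.5)
  expect_gte(mean(r_ml < 0 & r_mg < 0 & r_lg > 0), 0.9)
})

test_that("near-zero coupling leaves triplets indistinguishable from null", {
  cfg <- synthetic_config(n_per_group = 10, n_lnc = 60, n_mi = 55,
                          n_mrna = 60, n_triplets = 50, coupling = 1e-3,
                          frac_de = 0, seed = 8)
  g <- generate_counts(cfg)
  g <- generate_triplets(cfg, g$layers, g$truth)
  expr <- lapply(g$layers, log_normalized)
  tr <- g$truth$triplets
  ns <- vapply(seq_len(nrow(tr)), function(i) {
    p <- cor.test(expr$lnc[tr$lnc_id[i], ],
                  expr$mrna[tr$mrna_id[i], ])$p.value
    p > 0.05
  }, TRUE)
  expect_gte(mean(ns), 0.9)
})

test_that("zero triplets means untouched counts", {
  cfg <- synthetic_config(n_triplets = 0, n_lnc = 10, n_mi = 5,
                          n_mrna = 10, seed = 3)
  g <- generate_counts(cfg)
  g2 <- generate_triplets(cfg, g$layers, g$truth)
  expect_identical(g$layers$mrna$counts, g2$layers$mrna$counts)
})

test_that("sequences carry planted sites exactly where recorded", {
  cfg <- synthetic_config(n_lnc = 10, n_mi = 6, n_mrna = 10,
                          n_triplets = 4, site_per_pair = 3, seed = 5)
  ds <- simulate_ce_dataset(cfg)
  ps <- ds$truth$planted_sites
  # site_per_pair sites on each of the two partner transcripts per triplet
  expect_equal(nrow(ps), 4 * 2 * 3)
  for (r in seq_len(nrow(ps))) {
    mi8 <- substr(ds$mirnas[[ps$mi_id[r]]], 1, 8)
    expect_identical(substr(ds$transcripts[[ps$transcript_id[r]]],
                            ps$start[r], ps$start[r] + 7),
                     rna_revcomp(mi8))
  }
  # sites on the same transcript do not overlap
  for (tx in unique(ps$transcript_id)) {
    st <- sort(ps$start[ps$transcript_id == tx])
    if (length(st) > 1) expect_true(all(diff(st) >= 8))
  }
  # miRNAs follow the 5' U convention the 8mer class relies on
  expect_true(all(substr(ds$mirnas, 1, 1) == "U"))
})

test_that("datasets round-trip through the plain-text writers", {
  cfg <- synthetic_config(n_per_group = 3, n_lnc = 6, n_mi = 5,
                          n_mrna = 8, n_triplets = 2, seed = 2)
  ds <- simulate_ce_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_setequal(list.files(dir),
                  c("counts_lnc.tsv", "counts_mi.tsv", "counts_mrna.tsv",
                    "transcripts.fa", "mirnas.fa", "annotation.tsv",
                    "truth.json"))
  ds2 <- read_dataset(dir)
  for (layer in names(ds$layers)) {
    expect_identical(ds$layers[[layer]]$counts, ds2$layers[[layer]]$counts)
    expect_identical(as.character(ds$layers[[layer]]$group),
                     as.character(ds2$layers[[layer]]$group))
  }
  expect_identical(ds$transcripts, ds2$transcripts)
  expect_identical(ds$mirnas, ds2$mirnas)
  expect_equal(ds2$truth$triplets, ds$truth$triplets)
  expect_equal(ds2$truth$planted_sites, ds$truth$planted_sites)
  expect_equal(ds2$truth$de$mrna$id, ds$truth$de$mrna$id)
})

test_that("an empty layer still writes a valid header-only TSV", {
  m <- matrix(numeric(0), 0, 4,
              dimnames = list(character(0), paste0("s", 1:4)))
  cm <- count_matrix(m, rep(c("A", "B"), each = 2))
  f <- withr::local_tempfile()
  write_counts_tsv(cm, f)
  cm2 <- read_counts_tsv(f)
  expect_equal(dim(cm2$counts), c(0L, 4L))
  expect_identical(colnames(cm2$counts), colnames(m))
})
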