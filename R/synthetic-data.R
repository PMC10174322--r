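#' Configuration for the synthetic ceRNA benchmark generator
#'
#' Describes a two-group (reference vs case, e.g. sinus rhythm vs atrial
#' fibrillation) multi-layer RNA-seq experiment with planted differential
#' expression and planted ceRNA triplets. Defaults emulate a small
#' case/control tissue study: 4 samples per group, negative-binomial counts
#' with a decreasing mean-dispersion trend, ~10% differentially expressed
#' features at |log2FC| around 2, and a modest number of planted
#' lncRNA-miRNA-mRNA triplets.
#'
#' @param n_per_group samples per group (>= 3).
#' @param n_lnc,n_mi,n_mrna number of features in the lncRNA, miRNA and
#'   mRNA layers.
#' @param frac_de fraction of features per layer with a planted fold
#'   change, in `[0, 1]`.
#' @param lfc_mean,lfc_sd mean and sd of the planted `|log2FC|`
#'   distribution (half-normal around `lfc_mean`); signs are random.
#' @param dispersion_a0,dispersion_a1 coefficients of the dispersion trend
#'   `alpha(mu) = a0 + a1/mu` (`a0 >= 0`).
#' @param n_triplets number of planted ceRNA triplets; each uses distinct
#'   features, so it must not exceed any layer size.
#' @param coupling strength of the latent sponge-activity factor shared by
#'   each triplet, in `(0, 1]`; at 1 the shared factor moves the lncRNA and
#'   mRNA means by a log2-sd of 2.5 (and the miRNA oppositely).
#' @param base_mean median baseline expected count of a feature.
#' @param seed integer RNG seed; all stages derive sub-streams from it by
#'   fixed offsets, so outputs are fully reproducible.
#' @param seq_len_range integer pair: transcript length range (nt).
#' @param site_per_pair number of planted miRNA sites on each partner
#'   transcript of a triplet.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 4L,
                             n_lnc = 150L, n_mi = 40L, n_mrna = 400L,
                             frac_de = 0.1,
                             lfc_mean = 2, lfc_sd = 0.5,
                             dispersion_a0 = 0.05, dispersion_a1 = 3,
                             n_triplets = 20L,
                             coupling = 0.8,
                             base_mean = 100,
                             seed = 1L,
                             seq_len_range = c(300L, 1000L),
                             site_per_pair = 2L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_lnc = as.integer(n_lnc), n_mi = as.integer(n_mi),
              n_mrna = as.integer(n_mrna),
              frac_de = frac_de, lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
              n_triplets = as.integer(n_triplets), coupling = coupling,
              base_mean = base_mean, seed = as.integer(seed),
              seq_len_range = as.integer(seq_len_range),
              site_per_pair = as.integer(site_per_pair))
  if (cfg$n_per_group < 3L) stop("n_per_group must be >= 3")
  if (any(c(cfg$n_lnc, cfg$n_mi, cfg$n_mrna) <= 0L))
    stop("layer sizes must be positive")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("frac_de must be in [0,1]")
  if (cfg$dispersion_a0 < 0) stop("dispersion_a0 must be >= 0")
  if (cfg$coupling <= 0 || cfg$coupling > 1)
    stop("coupling must be in (0, 1]")
  if (cfg$n_triplets < 0L) stop("n_triplets must be >= 0")
  if (cfg$n_triplets > min(cfg$n_lnc, cfg$n_mi, cfg$n_mrna))
    stop("n_triplets exceeds a layer size")
  if (length(cfg$seq_len_range) != 2L || diff(cfg$seq_len_range) < 0 ||
      cfg$seq_len_range[1L] < 16L * max(1L, cfg$site_per_pair))
    stop("seq_len_range too short for the requested planted sites")
  class(cfg) <- "synthetic_config"
  cfg
}

# log2-sd of the latent triplet factor at coupling = 1
LATENT_AMPLITUDE <- 2.5

# fixed seed offsets per stage: adding a later stage never reshuffles an
# earlier one
.seed_offset <- c(counts = 1L, triplets = 2L, sequences = 3L,
                  annotation = 4L)

.layer_ids <- function(cfg) {
  list(lnc  = sprintf("LNC%04d",  seq_len(cfg$n_lnc)),
       mi   = sprintf("MIR%04d",  seq_len(cfg$n_mi)),
       mrna = sprintf("MRNA%04d", seq_len(cfg$n_mrna)))
}

.sample_ids <- function(cfg) {
  c(sprintf("SR%02d", seq_len(cfg$n_per_group)),
    sprintf("AF%02d", seq_len(cfg$n_per_group)))
}

.rnb <- function(n, mu, alpha) {
  # NB with variance mu + alpha*mu^2; alpha == 0 degenerates to Poisson
  ifelse(rep(alpha, length.out = n) <= 0,
         stats::rpois(n, mu),
         stats::rnbinom(n, mu = mu, size = 1 / pmax(alpha, 1e-12)))
}

#' Generate negative-binomial count matrices with planted fold changes
#'
#' Counts for each layer are drawn as
#' `NB(mean = s_j * q_g * 2^(beta_g * x_j), dispersion = a0 + a1/q_g)`
#' where `x_j` is the group indicator, `q_g` a log-normal baseline,
#' `s_j` log-uniform size factors in `[0.5, 2]`, and `beta_g` is zero for
#' non-DE features. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `layers` (named list of [count_matrix], layers
#'   `lnc`, `mi`, `mrna`) and `truth` (planted-truth record with per-layer
#'   DE ids and log2FC).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + .seed_offset[["counts"]])
  ids <- .layer_ids(config)
  samples <- .sample_ids(config)
  n <- 2L * config$n_per_group
  x <- rep(c(0, 1), each = config$n_per_group)
  group <- factor(rep(c("SR", "AF"), each = config$n_per_group),
                  levels = c("SR", "AF"))
  layers <- list()
  de <- list()
  for (layer in names(ids)) {
    g <- length(ids[[layer]])
    q <- stats::rlnorm(g, meanlog = log(config$base_mean), sdlog = 1)
    sf <- exp(stats::runif(n, log(0.5), log(2)))
    n_de <- round(config$frac_de * g)
    beta <- numeric(g)
    de_idx <- if (n_de > 0) sample.int(g, n_de) else integer(0)
    if (n_de > 0) {
      mag <- abs(stats::rnorm(n_de, config$lfc_mean, config$lfc_sd))
      beta[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }
    alpha <- config$dispersion_a0 + config$dispersion_a1 / q
    mu <- outer(q, sf) * 2^(beta %o% x)
    k <- matrix(.rnb(length(mu), as.vector(mu), rep(alpha, n)),
                nrow = g, dimnames = list(ids[[layer]], samples))
    cm <- count_matrix(k, group)
    attr(cm, "sim_pars") <- list(q = q, sf = sf, beta = beta, alpha = alpha,
                                 x = x)
    layers[[layer]] <- cm
    de[[layer]] <- data.frame(id = ids[[layer]][de_idx],
                              log2fc = beta[de_idx],
                              stringsAsFactors = FALSE)
  }
  truth <- list(ids = ids, de = de,
                triplets = data.frame(lnc_id = character(0),
                                      mi_id = character(0),
                                      mrna_id = character(0),
                                      stringsAsFactors = FALSE),
                planted_sites = data.frame(mi_id = character(0),
                                           transcript_id = character(0),
                                           start = integer(0),
                                           seed_class = character(0),
                                           stringsAsFactors = FALSE))
  list(layers = layers, truth = truth)
}

#' Plant ceRNA triplets by a shared latent factor
#'
#' For each triplet a per-sample latent factor `z_j ~ N(0,1)` multiplies the
#' lncRNA and mRNA means by `2^(+coupling * 2.5 * z_j)` and the miRNA mean
#' by `2^(-coupling * 2.5 * z_j)`, then redraws those rows from the same NB
#' model. This yields the ceRNA sign pattern in expectation: miRNA
#' anti-correlated with both partners, lncRNA and mRNA positively
#' correlated, with magnitude increasing in `coupling`. Triplet members are
#' drawn without replacement, so each feature belongs to at most one
#' triplet.
#'
#' @param config a [synthetic_config()].
#' @param layers named list of per-layer [count_matrix] from
#'   [generate_counts()].
#' @param truth the planted-truth record from [generate_counts()].
#' @return list with modified `layers` and updated `truth` (`$triplets`
#'   filled in).
#' @export
generate_triplets <- function(config, layers, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_triplets == 0L) return(list(layers = layers, truth = truth))
  set.seed(config$seed + .seed_offset[["triplets"]])
  n <- 2L * config$n_per_group
  amp <- config$coupling * LATENT_AMPLITUDE
  pick <- lapply(truth$ids, function(v) sample(v, config$n_triplets))
  triplets <- data.frame(lnc_id = pick$lnc, mi_id = pick$mi,
                         mrna_id = pick$mrna, stringsAsFactors = FALSE)
  for (t in seq_len(config$n_triplets)) {
    z <- stats::rnorm(n)
    for (layer in c("lnc", "mi", "mrna")) {
      cm <- layers[[layer]]
      pars <- attr(cm, "sim_pars")
      id <- triplets[[paste0(layer, "_id")]][t]
      gi <- match(id, rownames(cm$counts))
      sgn <- if (layer == "mi") -1 else 1
      mu <- pars$sf * pars$q[gi] * 2^(pars$beta[gi] * pars$x) *
        2^(sgn * amp * z)
      cm$counts[gi, ] <- .rnb(n, mu, pars$alpha[gi])
      layers[[layer]] <- cm
    }
  }
  truth$triplets <- triplets
  list(layers = layers, truth = truth)
}

#' Generate transcript and miRNA sequences with planted seed sites
#'
#' Background transcripts are uniform A/C/G/U at lengths drawn from
#' `seq_len_range`; miRNAs are 22 nt with a 5' U (the dominant convention
#' for mature miRNAs). For every planted triplet, `site_per_pair` copies of
#' the exact reverse complement of miRNA positions 1-8 are written at
#' recorded non-overlapping positions into both partner transcripts; decoy
#' transcripts carry no planted sites.
#'
#' @param config a [synthetic_config()].
#' @param truth planted-truth record (with `$triplets` filled in).
#' @return list with `transcripts` and `mirnas` (named character vectors)
#'   and updated `truth` (`$planted_sites` filled in).
#' @export
generate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + .seed_offset[["sequences"]])
  tx_ids <- c(truth$ids$lnc, truth$ids$mrna)
  lens <- sample(seq(config$seq_len_range[1L], config$seq_len_range[2L]),
                 length(tx_ids), replace = TRUE)
  names(lens) <- tx_ids
  transcripts <- vapply(lens, function(L)
    paste(sample(RNA_BASES, L, replace = TRUE), collapse = ""), "")
  names(transcripts) <- tx_ids
  mirnas <- vapply(seq_along(truth$ids$mi), function(i)
    paste(c("U", sample(RNA_BASES, 21L, replace = TRUE)), collapse = ""), "")
  names(mirnas) <- truth$ids$mi

  sites <- list()
  if (nrow(truth$triplets) > 0) {
    for (t in seq_len(nrow(truth$triplets))) {
      mi <- truth$triplets$mi_id[t]
      site8 <- rna_revcomp(substr(mirnas[[mi]], 1L, 8L))
      for (tx in c(truth$triplets$lnc_id[t], truth$triplets$mrna_id[t])) {
        L <- lens[[tx]]
        if (L < 16L * config$site_per_pair)
          stop("transcript ", tx, " too short for requested sites")
        starts <- integer(0)
        tries <- 0L
        while (length(starts) < config$site_per_pair) {
          p <- sample.int(L - 7L, 1L)
          if (all(abs(p - starts) >= 8L)) starts <- c(starts, p)
          tries <- tries + 1L
          if (tries > 10000L)
            stop("could not place non-overlapping sites on ", tx)
        }
        s <- transcripts[[tx]]
        for (p in starts) substr(s, p, p + 7L) <- site8
        transcripts[[tx]] <- s
        sites[[length(sites) + 1L]] <-
          data.frame(mi_id = mi, transcript_id = tx, start = sort(starts),
                     seed_class = "8mer", stringsAsFactors = FALSE)
      }
    }
    truth$planted_sites <- do.call(rbind, sites)
    rownames(truth$planted_sites) <- NULL
  }
  list(transcripts = transcripts, mirnas = mirnas, truth = truth)
}

.generate_annotation <- function(config, truth, tx_len) {
  set.seed(config$seed + .seed_offset[["annotation"]])
  ids <- c(truth$ids$lnc, truth$ids$mrna)
  n <- length(ids)
  chrom <- sample(paste0("chr", c(1:22, "X")), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- sample.int(5e6L, n)
  len <- unname(tx_len[ids])
  data.frame(id = ids, chrom = chrom, strand = strand,
             start = start, end = start + len - 1L,
             exon_count = sample(1:12, n, replace = TRUE),
             biotype = rep(c("lncRNA_candidate", "protein_coding"),
                           c(config$n_lnc, config$n_mrna)),
             length = len,
             annotated = c(stats::runif(config$n_lnc) < 0.3,
                           rep(TRUE, config$n_mrna)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic ceRNA dataset
#'
#' Runs [generate_counts()], [generate_triplets()] and
#' [generate_sequences()] and adds a transcript annotation table. The
#' result carries everything the downstream pipeline consumes plus the
#' planted ground truth for benchmarking.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `layers`
#'   (per-layer [count_matrix]), `transcripts`, `mirnas` (named RNA
#'   character vectors), `annotation` (data frame) and `truth`.
#' @export
simulate_ce_dataset <- function(config) {
  g <- generate_counts(config)
  g <- generate_triplets(config, g$layers, g$truth)
  s <- generate_sequences(config, g$truth)
  ann <- .generate_annotation(config, s$truth, nchar(s$transcripts))
  structure(list(layers = g$layers, transcripts = s$transcripts,
                 mirnas = s$mirnas, annotation = ann, truth = s$truth,
                 config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits one counts TSV per layer (`counts_<layer>.tsv`), transcript and
#' miRNA FASTA, a tab-delimited annotation table and the planted truth as
#' JSON. The file set round-trips losslessly through [read_dataset()].
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in names(ds$layers))
    write_counts_tsv(ds$layers[[layer]],
                     file.path(dir, paste0("counts_", layer, ".tsv")))
  write_fasta_rna(ds$transcripts, file.path(dir, "transcripts.fa"))
  write_fasta_rna(ds$mirnas, file.path(dir, "mirnas.fa"))
  utils::write.table(ds$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

.as_truth <- function(x) {
  fix_df <- function(d, cols, int_cols = character(0)) {
    d <- as.data.frame(lapply(d, unlist), stringsAsFactors = FALSE)
    if (nrow(d) == 0 || length(d) == 0)
      d <- as.data.frame(stats::setNames(
        lapply(cols, function(cc)
          if (cc %in% int_cols) integer(0) else character(0)), cols),
        stringsAsFactors = FALSE)
    for (cc in int_cols) d[[cc]] <- as.integer(d[[cc]])
    d[cols]
  }
  list(ids = lapply(x$ids, unlist),
       de = lapply(x$de, function(d) {
         d <- fix_df(d, c("id", "log2fc"))
         d$log2fc <- as.numeric(d$log2fc)
         d
       }),
       triplets = fix_df(x$triplets, c("lnc_id", "mi_id", "mrna_id")),
       planted_sites = fix_df(x$planted_sites,
                              c("mi_id", "transcript_id", "start",
                                "seed_class"), int_cols = "start"))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory produced by [write_dataset()].
#' @return A `synthetic_dataset` (without the generator's internal
#'   simulation parameters).
#' @export
read_dataset <- function(dir) {
  layers <- list()
  for (layer in c("lnc", "mi", "mrna")) {
    f <- file.path(dir, paste0("counts_", layer, ".tsv"))
    if (file.exists(f)) layers[[layer]] <- read_counts_tsv(f)
  }
  truth <- .as_truth(jsonlite::read_json(file.path(dir, "truth.json"),
                                         simplifyVector = TRUE))
  structure(list(layers = layers,
                 transcripts = read_fasta_rna(file.path(dir, "transcripts.fa")),
                 mirnas = read_fasta_rna(file.path(dir, "mirnas.fa")),
                 annotation = utils::read.delim(file.path(dir, "annotation.tsv"),
                                                stringsAsFactors = FALSE),
                 truth = truth),
            class = "synthetic_dataset")
}
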