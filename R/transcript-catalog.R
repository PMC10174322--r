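# Transcript catalog: lncRNA candidate filtering, orientation relative to
# protein-coding transcripts, FPKM and sample-level PCA.
#
# Transcript records are plain data frames with columns
#   id, chrom, strand (+/-), start, end (1-based closed), exon_count,
#   biotype (lncRNA_candidate / protein_coding / other), length (spliced nt)
# and optionally `annotated` (logical; defaults to FALSE = novel).

.check_records <- function(records) {
  need <- c("id", "chrom", "strand", "start", "end", "exon_count",
            "biotype", "length")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("transcript records lack columns: ", paste(miss, collapse = ", "))
  if (!all(records$strand %in% c("+", "-")))
    stop("unknown strand symbol (must be '+' or '-')")
  if (any(records$start > records$end)) stop("start > end in records")
  if (any(records$length < 1) || any(records$exon_count < 1))
    stop("length and exon_count must be >= 1")
  invisible(records)
}

#' Filter lncRNA candidate transcripts
#'
#' Keeps candidate transcripts longer than 200 nt (`length >= min_len`,
#' default 201) with at least `min_exons` exons. The exon rule applies to
#' unannotated (novel) candidates only: transcripts flagged `annotated`
#' are known lncRNAs and bypass it, which is why a filtered catalog can
#' still contain a minority of single-exon entries.
#'
#' @param records transcript record data frame (see file header).
#' @param min_len minimum spliced length in nt (201 = "longer than 200 bp").
#' @param min_exons minimum exon count for unannotated candidates.
#' @return the filtered data frame (idempotent: re-filtering is a no-op).
#' @export
filter_lncrna_candidates <- function(records, min_len = 201L,
                                     min_exons = 2L) {
  if (nrow(records) == 0) return(records)
  .check_records(records)
  annotated <- if ("annotated" %in% names(records)) records$annotated
               else rep(FALSE, nrow(records))
  keep <- records$biotype == "lncRNA_candidate" &
    records$length >= min_len &
    (annotated | records$exon_count >= min_exons)
  records[keep, , drop = FALSE]
}

#' Classify lncRNAs as sense or antisense relative to coding transcripts
#'
#' A lncRNA whose genomic interval intersects a protein-coding transcript
#' on the same chromosome is classified `sense` if the best-overlapping
#' coding transcript lies on the same strand and `antisense` otherwise;
#' lncRNAs with no coding overlap are `unclassified`. Ties among
#' overlapping coding transcripts are broken by largest overlap length,
#' then antisense over sense, then lowest coding id.
#'
#' @param lnc,coding transcript record data frames on the same coordinate
#'   system.
#' @return data frame with columns `id`, `class`
#'   (sense/antisense/unclassified), `partner` (coding id or NA),
#'   `overlap` (nt, 0 if none), one row per lncRNA, in input order.
#' @export
classify_orientation <- function(lnc, coding) {
  if (nrow(lnc) == 0)
    return(data.frame(id = character(0), class = character(0),
                      partner = character(0), overlap = integer(0),
                      stringsAsFactors = FALSE))
  .check_records(lnc)
  out <- data.frame(id = lnc$id, class = "unclassified",
                    partner = NA_character_, overlap = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(coding) > 0) {
    .check_records(coding)
    gr_l <- GenomicRanges::GRanges(lnc$chrom,
                                   IRanges::IRanges(lnc$start, lnc$end))
    gr_c <- GenomicRanges::GRanges(coding$chrom,
                                   IRanges::IRanges(coding$start, coding$end))
    ov <- GenomicRanges::findOverlaps(gr_l, gr_c, ignore.strand = TRUE)
    if (length(ov) > 0) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::IRanges(lnc$start[qi], lnc$end[qi]),
        IRanges::IRanges(coding$start[si], coding$end[si])))
      anti <- lnc$strand[qi] != coding$strand[si]
      # tie-break: widest overlap, then antisense, then lowest coding id
      ord <- order(qi, -w, !anti, coding$id[si])
      best <- ord[!duplicated(qi[ord])]
      out$class[qi[best]] <- ifelse(anti[best], "antisense", "sense")
      out$partner[qi[best]] <- coding$id[si[best]]
      out$overlap[qi[best]] <- w[best]
    }
  }
  out
}

#' FPKM from raw counts
#'
#' `FPKM[g, j] = counts[g, j] * 1e9 / (length[g] * colsum[j])` with the
#' per-sample column sum taken over the supplied matrix. By construction
#' FPKM is invariant to rescaling a sample's counts.
#'
#' @param counts numeric matrix (genes x samples) or [count_matrix].
#' @param lengths per-gene transcript lengths in nt (named or in row
#'   order); all positive.
#' @return matrix of FPKM values with the input dimnames.
#' @export
compute_fpkm <- function(counts, lengths) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("need one length per gene")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive")
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("zero library size in at least one sample")
  sweep(counts * 1e9 / lengths, 2L, cs, "/")
}

#' log10(FPKM + 1) transform
#'
#' @param fpkm matrix from [compute_fpkm()].
#' @return transformed matrix, used for expression-distribution plots.
#' @export
log10_fpkm1 <- function(fpkm) log10(fpkm + 1)

#' Sample-level principal component analysis
#'
#' Gene-centered SVD of the expression matrix: sample coordinates are the
#' right singular vectors scaled by their singular values, and variance
#' fractions are the squared singular values normalized to sum to 1 over
#' the retained components. Component signs are fixed by making each
#' component's largest-magnitude gene loading positive, so results do not
#' depend on the SVD implementation's sign convention.
#'
#' @param logexpr numeric matrix, genes x samples (log-scale expression).
#' @return list with `coords` (samples x components), `var_frac`
#'   (variance fractions, summing to 1) and `loadings` (genes x
#'   components). A constant matrix yields all-zero coordinates with a
#'   warning.
#' @export
pca_samples <- function(logexpr) {
  if (nrow(logexpr) < 2 || ncol(logexpr) < 2)
    stop("need at least 2 genes and 2 samples")
  xc <- logexpr - rowMeans(logexpr)
  if (all(abs(xc) < 1e-12)) {
    warning("constant expression matrix: PCA undefined, returning zeros")
    k <- min(dim(logexpr)) - 1L
    return(list(coords = matrix(0, ncol(logexpr), k,
                                dimnames = list(colnames(logexpr),
                                                paste0("PC", seq_len(k)))),
                var_frac = rep(NA_real_, k),
                loadings = matrix(0, nrow(logexpr), k)))
  }
  sv <- svd(xc)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  flip <- vapply(seq_along(d), function(i) {
    j <- which.max(abs(u[, i]))
    if (u[j, i] < 0) -1 else 1
  }, 0)
  u <- sweep(u, 2L, flip, "*")
  v <- sweep(v, 2L, flip, "*")
  coords <- sweep(v, 2L, d, "*")
  dimnames(coords) <- list(colnames(logexpr), paste0("PC", seq_along(d)))
  list(coords = coords, var_frac = d^2 / sum(d^2), loadings = u)
}

#' Catalog summary statistics
#'
#' Orientation counts and shares, a transcript-length histogram (first bin
#' 200-2000 nt, then 2000-nt-wide bins), chromosome counts and an
#' exon-count histogram. Counts in each histogram sum to the number of
#' records, and the summary is invariant to input order.
#'
#' @param records transcript record data frame.
#' @param orientation optional result of [classify_orientation()] for the
#'   same records.
#' @param length_breaks histogram breakpoints; default `c(200, 2000, 4000,
#'   ...)` extended to cover the data.
#' @return list of class `catalog_summary` with `n_total`, orientation
#'   counts (`n_sense`, `n_antisense`, `n_unclassified`) and percentage
#'   shares, `length_histogram`, `chromosome_counts`, `exon_histogram`.
#' @export
catalog_summary <- function(records, orientation = NULL,
                            length_breaks = NULL) {
  .check_records(records)
  n <- nrow(records)
  if (is.null(length_breaks)) {
    top <- max(2000, ceiling(max(records$length) / 2000) * 2000)
    length_breaks <- c(200, seq(2000, top, by = 2000))
    if (min(records$length) < 200) length_breaks <- c(0, length_breaks)
  }
  lh <- table(cut(records$length, breaks = length_breaks,
                  include.lowest = TRUE, right = TRUE))
  eh <- table(factor(pmin(records$exon_count, 10L), levels = 1:10,
                     labels = c(1:9, "10+")))
  out <- list(n_total = n,
              length_histogram = lh,
              length_share_pct = round(100 * as.numeric(lh) / n, 2),
              chromosome_counts = table(records$chrom),
              exon_histogram = eh,
              single_exon_pct = round(100 * sum(records$exon_count == 1) / n, 2))
  if (!is.null(orientation)) {
    out$n_sense <- sum(orientation$class == "sense")
    out$n_antisense <- sum(orientation$class == "antisense")
    out$n_unclassified <- sum(orientation$class == "unclassified")
    cl <- sum(out$n_sense, out$n_antisense)
    out$antisense_pct <- if (cl > 0) round(100 * out$n_antisense / cl, 2)
                         else NA_real_
  }
  class(out) <- "catalog_summary"
  out
}

#' Percentage share of one orientation class among classified lncRNAs
#'
#' @param n_antisense,n_sense class counts.
#' @return antisense share in percent, rounded to 2 decimals (e.g. counts
#'   19894 antisense vs 9171 sense give 68.45).
#' @export
antisense_share_pct <- function(n_antisense, n_sense) {
  if (n_antisense + n_sense <= 0) stop("no classified transcripts")
  round(100 * n_antisense / (n_antisense + n_sense), 2)
}
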