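#' Count matrix with sample group labels
#'
#' Lightweight container for one RNA layer: a genes-by-samples matrix of
#' non-negative integer counts plus a two-level group factor (level order
#' defines the comparison: the first level is the reference, e.g. sinus
#' rhythm, the second the case group, e.g. atrial fibrillation).
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative.
#' @param group character or factor of length `ncol(counts)` with exactly
#'   two levels.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `group`.
#' @export
count_matrix <- function(counts, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0 ||
      is.null(colnames(counts)))
    stop("counts must have row (gene) and column (sample) names")
  if (is.null(rownames(counts)))
    rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  group <- as.factor(group)
  if (length(group) != ncol(counts))
    stop("group must have one label per sample")
  if (nlevels(group) != 2L)
    stop("exactly two groups are required (reference first)")
  structure(list(counts = counts, group = group), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix to TSV
#'
#' Layout: a header line `gene_id<TAB>sample1<TAB>...`, then a `#group`
#' line giving each sample's group label, then one row per gene.
#'
#' @param cm a [count_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(cm$counts)), collapse = "\t"), con)
  writeLines(paste(c("#group", as.character(cm$group)), collapse = "\t"), con)
  if (nrow(cm$counts) > 0) {
    body <- apply(cm$counts, 1L, function(r) paste(r, collapse = "\t"))
    writeLines(paste(rownames(cm$counts), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a count matrix written by [write_counts_tsv()]
#'
#' @param path input file path.
#' @return A [count_matrix].
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed counts file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  grp <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  if (grp[1L] != "#group") stop("missing #group line in ", path)
  samples <- header[-1L]
  group <- factor(grp[-1L], levels = unique(grp[-1L]))
  body <- lines[-(1:2)]
  if (length(body) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(samples),
                dimnames = list(character(0), samples))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
    dimnames(m) <- list(vapply(parts, `[[`, "", 1L), samples)
  }
  count_matrix(m, group)
}
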