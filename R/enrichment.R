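# Hypergeometric over-representation analysis of a gene list against
# GMT-format gene-set collections, with Benjamini-Hochberg FDR and top-K
# reporting.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited `term_id`, `description`,
#' then member gene ids.
#'
#' @param path GMT file.
#' @return list of gene sets, each a list with `term_id`, `description`,
#'   `members` (unique character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    list(term_id = f[1L], description = f[2L],
         members = unique(f[-(1:2)]))
  })
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` list genes in a set of size `K`
#' when `n` genes are drawn from a universe of `N`:
#' `p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`.
#'
#' @param k observed overlap; `k = 0` gives 1.
#' @param K set size in the universe.
#' @param n list size in the universe.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    stop("impossible hypergeometric configuration")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR
#'
#' `fdr_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; values are
#' returned in the input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return FDR-adjusted values.
#' @export
bh_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Gene-set over-representation analysis
#'
#' One hypergeometric test per gene set with at least one list gene;
#' list ids outside the universe are dropped (count in the
#' `"n_outside"` attribute), set members outside the universe do not
#' count toward set size. Rows are sorted by p ascending (ties: larger
#' overlap, then term id), BH FDR is computed over the tested sets, and
#' the first `top_k` rows are flagged for reporting.
#'
#' @param gene_list character vector of gene ids (e.g. DE genes in the
#'   ceRNA network).
#' @param gmt gene sets from [read_gmt()] (or a list in that shape).
#' @param universe character vector of background gene ids,
#'   conventionally all genes tested for differential expression.
#' @param top_k number of rows to flag as the report head.
#' @return data frame with columns `term_id`, `description`, `k`, `K`,
#'   `n`, `N`, `p`, `fdr`, `top` (logical).
#' @export
enrich <- function(gene_list, gmt, universe, top_k = 30L) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  gl <- unique(gene_list)
  n_outside <- sum(!gl %in% universe)
  gl <- intersect(gl, universe)
  rows <- lapply(gmt, function(gs) {
    members <- intersect(gs$members, universe)
    k <- length(intersect(gl, members))
    if (k == 0L) return(NULL)
    data.frame(term_id = gs$term_id, description = gs$description,
               k = k, K = length(members), n = length(gl),
               N = length(universe),
               p = hypergeom_p(k, length(members), length(gl),
                               length(universe)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    out <- data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      top = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_outside") <- n_outside
    return(out)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, -out$k, out$term_id), , drop = FALSE]
  out$top <- seq_len(nrow(out)) <= top_k
  rownames(out) <- NULL
  attr(out, "n_outside") <- n_outside
  out
}
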