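# MRE (miRNA response element) prediction: a seed-and-extend scheme. The
# transcript (5'->3' mRNA sense) is scanned for matches to the reverse
# complement of the miRNA seed (positions 2-8 from the miRNA 5' end,
# allowing a limited number of G:U wobbles), and every candidate is
# extended by a local alignment of the full reverse-complemented miRNA
# with affine gaps and a score multiplier on seed columns, mirroring the
# classical 5'-weighted miRNA target predictors.

#' Alignment and seed-scan parameters for MRE prediction
#'
#' Defaults mirror the published defaults of the classical weighted
#' local-alignment miRNA target predictors: +5 match, +1 G:U wobble, -3
#' mismatch, affine gaps -9/-4, a 4x multiplier on miRNA seed positions
#' 2-8 and an emission threshold of 140 (an exact 7-mer seed alone scores
#' 7 * 5 * 4 = 140).
#'
#' @param match_score,wobble_score,mismatch substitution scores (wobble =
#'   G:U pair).
#' @param gap_open,gap_extend affine gap penalties (negative).
#' @param seed_span integer pair: miRNA positions (1-based from the 5'
#'   end) whose alignment columns are weighted; default 2-8.
#' @param seed_weight multiplier applied to substitution scores inside
#'   `seed_span`.
#' @param score_threshold minimum alignment score for an emitted hit.
#' @param max_wobble_in_seed maximum number of G:U pairs tolerated in the
#'   seed during scanning; the strict default 0 demands perfect
#'   Watson-Crick seed pairing, which keeps the decoy false-positive rate
#'   at the analytic 4^-7 chance level.
#' @param allow_seed_gaps permit gap columns inside the seed during
#'   extension (default FALSE, the strict convention).
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(match_score = 5, wobble_score = 1,
                             mismatch = -3, gap_open = -9,
                             gap_extend = -4, seed_span = c(2L, 8L),
                             seed_weight = 4, score_threshold = 140,
                             max_wobble_in_seed = 0L,
                             allow_seed_gaps = FALSE) {
  p <- list(match_score = match_score, wobble_score = wobble_score,
            mismatch = mismatch, gap_open = gap_open,
            gap_extend = gap_extend, seed_span = as.integer(seed_span),
            seed_weight = seed_weight, score_threshold = score_threshold,
            max_wobble_in_seed = as.integer(max_wobble_in_seed),
            allow_seed_gaps = isTRUE(allow_seed_gaps))
  if (p$score_threshold <= 0) stop("score_threshold must be positive")
  if (p$seed_span[1L] < 1L || p$seed_span[1L] > p$seed_span[2L])
    stop("invalid seed_span")
  class(p) <- "alignment_params"
  p
}

# pair classification between a miRNA base and a transcript base:
# 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
.pair_class <- function(mi_base, tx_base) {
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  ifelse(tx_base == wc[mi_base], 2L,
         ifelse((mi_base == "G" & tx_base == "U") |
                (mi_base == "U" & tx_base == "G"), 1L, 0L))
}

#' Scan a transcript for miRNA seed matches
#'
#' Reports every transcript position where the reverse complement of
#' miRNA positions 2-8 matches with at most `max_wobble_in_seed` G:U
#' pairs (all other pairs Watson-Crick). Each candidate is assigned the
#' strongest applicable canonical site class: `8mer` (perfect 2-8 match
#' plus an A opposite miRNA position 1), `7mer-m8` (perfect 2-8 match),
#' `7mer-A1` (wobble at position 8 only, plus the A), else `6mer`.
#' Overlapping candidates are all reported.
#'
#' @param mirna miRNA sequence, 5'->3', RNA alphabet, length >= 8.
#' @param transcript transcript sequence, 5'->3', RNA alphabet.
#' @param params an [alignment_params()].
#' @return data frame with columns `pos` (1-based start of the 7-mer
#'   match on the transcript), `n_wobble`, `seed_class`.
#' @export
seed_scan <- function(mirna, transcript, params = alignment_params()) {
  check_rna(mirna, "miRNA"); check_rna(transcript, "transcript")
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt")
  mi <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  tx <- strsplit(transcript, "", fixed = TRUE)[[1L]]
  L <- length(tx)
  empty <- data.frame(pos = integer(0), n_wobble = integer(0),
                      seed_class = character(0), stringsAsFactors = FALSE)
  if (L < 7L) return(empty)
  # transcript position p + i - 1 pairs with miRNA position 9 - i
  n_win <- L - 6L
  cls <- matrix(0L, nrow = 7L, ncol = n_win)
  for (i in 1:7) {
    m <- mi[9L - i]
    cls[i, ] <- .pair_class(rep(m, n_win), tx[i:(i + n_win - 1L)])
  }
  ok <- colSums(cls == 0L) == 0L
  nw <- colSums(cls == 1L)
  keep <- which(ok & nw <= params$max_wobble_in_seed)
  if (length(keep) == 0L) return(empty)
  a1 <- ifelse(keep + 7L <= L, tx[keep + 7L] == "A", FALSE)
  perfect <- nw[keep] == 0L
  # wobble confined to the position-8 column (transcript offset 0)
  w8_only <- !perfect & cls[1L, keep] == 1L &
    colSums(cls[2:7, keep, drop = FALSE] == 1L) == 0L
  seed_class <- ifelse(perfect & a1, "8mer",
                ifelse(perfect, "7mer-m8",
                ifelse(w8_only & a1, "7mer-A1", "6mer")))
  data.frame(pos = keep, n_wobble = unname(nw[keep]),
             seed_class = seed_class, stringsAsFactors = FALSE)
}

# Local alignment of the reverse-complemented miRNA against a transcript
# window with affine gaps and seed weighting. Returns NULL or a list with
# score, start, end (0-based half-open on the transcript) and the display
# alignment.
.align_window <- function(mi, tx, win_start, win_end, params) {
  Lm <- length(mi)
  q_mi_pos <- Lm:1            # query row i pairs miRNA position Lm + 1 - i
  in_seed <- q_mi_pos >= params$seed_span[1L] &
             q_mi_pos <= params$seed_span[2L]
  t <- tx[win_start:win_end]
  n <- length(t)
  NEG <- -1e9
  M <- matrix(0, Lm + 1L, n + 1L)      # best score ending in a pair
  Ix <- matrix(NEG, Lm + 1L, n + 1L)   # gap in transcript
  Iy <- matrix(NEG, Lm + 1L, n + 1L)   # gap in miRNA
  Sm <- matrix(0L, Lm + 1L, n + 1L)    # start column propagation
  Sx <- matrix(0L, Lm + 1L, n + 1L)
  Sy <- matrix(0L, Lm + 1L, n + 1L)
  Pm <- matrix(0L, Lm + 1L, n + 1L)    # traceback: which matrix fed M
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(Lm + 1L)) {
    qi <- i - 1L
    w <- if (in_seed[qi]) params$seed_weight else 1
    gap_ok_x <- params$allow_seed_gaps || !in_seed[qi]
    for (j in 2:(n + 1L)) {
      pc <- .pair_class(mi[Lm + 1L - qi], t[j - 1L])
      sub <- w * switch(pc + 1L, params$mismatch, params$wobble_score,
                        params$match_score)
      cand <- c(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L])
      kbest <- which.max(cand)
      sc <- cand[kbest] + sub
      if (sc <= 0) {
        M[i, j] <- 0; Sm[i, j] <- 0L; Pm[i, j] <- 0L
      } else {
        M[i, j] <- sc
        # Sm holds the window position (1..n) where the alignment starts
        Sm[i, j] <- if (kbest == 1L && M[i - 1L, j - 1L] <= 0) j - 1L
                    else switch(kbest, Sm[i - 1L, j - 1L],
                                Sx[i - 1L, j - 1L], Sy[i - 1L, j - 1L])
        Pm[i, j] <- kbest
      }
      if (gap_ok_x) {
        o <- M[i - 1L, j] + params$gap_open
        e <- Ix[i - 1L, j] + params$gap_extend
        if (o >= e) { Ix[i, j] <- o; Sx[i, j] <- Sm[i - 1L, j] }
        else { Ix[i, j] <- e; Sx[i, j] <- Sx[i - 1L, j] }
      }
      gap_ok_y <- params$allow_seed_gaps ||
        !(in_seed[qi] || (qi < Lm && in_seed[qi + 1L]))
      if (gap_ok_y) {
        o <- M[i, j - 1L] + params$gap_open
        e <- Iy[i, j - 1L] + params$gap_extend
        if (o >= e) { Iy[i, j] <- o; Sy[i, j] <- Sm[i, j - 1L] }
        else { Iy[i, j] <- e; Sy[i, j] <- Sy[i, j - 1L] }
      }
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (best < params$score_threshold) return(NULL)
  # traceback from the best pair cell for the display alignment
  qa <- character(0); ta <- character(0); bars <- character(0)
  i <- bi; j <- bj; state <- 1L
  while (i > 1L && j > 1L) {
    if (state == 1L) {
      if (M[i, j] <= 0) break
      pc <- .pair_class(mi[Lm + 2L - i], t[j - 1L])
      qa <- c(mi[Lm + 2L - i], qa); ta <- c(t[j - 1L], ta)
      bars <- c(c(" ", ":", "|")[pc + 1L], bars)
      state <- Pm[i, j]; i <- i - 1L; j <- j - 1L
      if (state == 0L) break
    } else if (state == 2L) {
      qa <- c(mi[Lm + 2L - i], qa); ta <- c("-", ta); bars <- c(" ", bars)
      state <- if (Ix[i, j] == M[i - 1L, j] + params$gap_open) 1L else 2L
      i <- i - 1L
    } else {
      qa <- c("-", qa); ta <- c(t[j - 1L], ta); bars <- c(" ", bars)
      state <- if (Iy[i, j] == M[i, j - 1L] + params$gap_open) 1L else 3L
      j <- j - 1L
    }
  }
  start0 <- win_start + Sm[bi, bj] - 1L
  end0 <- win_start + bj - 2L
  list(score = best, start = start0 - 1L, end = end0,
       aligned = c(mirna_3to5 = paste(qa, collapse = ""),
                   pairing = paste(bars, collapse = ""),
                   transcript = paste(ta, collapse = "")))
}

#' Extend a seed candidate into a scored MRE hit
#'
#' Runs a local alignment of the full reverse-complemented miRNA against
#' a transcript window of width `length(miRNA) + 10` around the candidate
#' seed match, with affine gaps and the seed-column weight. A hit is
#' emitted iff the alignment score reaches `score_threshold`.
#'
#' @param mirna,transcript RNA sequences, 5'->3'.
#' @param candidate_pos 1-based transcript start of the seed 7-mer (as in
#'   [seed_scan()]'s `pos`).
#' @param params an [alignment_params()].
#' @return `NULL`, or a list with `score`, `start`, `end` (0-based
#'   half-open transcript coordinates of the aligned region) and
#'   `aligned` (three display strings).
#' @export
align_site <- function(mirna, transcript, candidate_pos,
                       params = alignment_params()) {
  check_rna(mirna, "miRNA"); check_rna(transcript, "transcript")
  mi <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  tx <- strsplit(transcript, "", fixed = TRUE)[[1L]]
  Lm <- length(mi)
  if (candidate_pos < 1L || candidate_pos + 6L > length(tx))
    stop("candidate position out of bounds")
  # ungapped full pairing would span [pos - Lm + 8, pos + 7]; pad by 5
  win_start <- max(1L, candidate_pos - Lm + 3L)
  win_end <- min(length(tx), candidate_pos + 12L)
  .align_window(mi, tx, win_start, win_end, params)
}

#' Predict MRE hits for all miRNA/transcript pairs
#'
#' Seed-scans every pair, extends each candidate with [align_site()], and
#' merges overlapping hits of the same miRNA on the same transcript,
#' keeping the highest score (ties: leftmost). Output order is
#' (transcript, miRNA, start), independent of input ordering.
#'
#' @param mirnas,transcripts named character vectors of RNA sequences
#'   (e.g. from [read_fasta_rna()]).
#' @param params an [alignment_params()].
#' @return data frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end` (0-based half-open), `score`, `seed_class`.
#' @export
predict_targets <- function(mirnas, transcripts,
                            params = alignment_params()) {
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), seed_class = character(0),
                      stringsAsFactors = FALSE)
  if (length(mirnas) == 0L || length(transcripts) == 0L) return(empty)
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  rows <- list()
  for (tx_id in sort(names(transcripts))) {
    tx <- transcripts[[tx_id]]
    for (mi_id in sort(names(mirnas))) {
      cand <- seed_scan(mirnas[[mi_id]], tx, params)
      if (nrow(cand) == 0L) next
      hits <- list()
      for (r in seq_len(nrow(cand))) {
        h <- align_site(mirnas[[mi_id]], tx, cand$pos[r], params)
        if (!is.null(h))
          hits[[length(hits) + 1L]] <-
            data.frame(mirna_id = mi_id, transcript_id = tx_id,
                       start = h$start, end = h$end, score = h$score,
                       seed_class = cand$seed_class[r],
                       stringsAsFactors = FALSE)
      }
      if (length(hits) == 0L) next
      h <- do.call(rbind, hits)
      h <- h[order(h$start, h$end), , drop = FALSE]
      # merge overlapping intervals, keeping the best-scoring (tie: leftmost)
      grp <- integer(nrow(h)); g <- 1L; grp[1L] <- 1L
      if (nrow(h) > 1L) {
        hi <- h$end[1L]
        for (r in 2:nrow(h)) {
          if (h$start[r] < hi) grp[r] <- g
          else { g <- g + 1L; grp[r] <- g }
          hi <- max(hi, h$end[r])
        }
      }
      for (gg in unique(grp)) {
        sub <- h[grp == gg, , drop = FALSE]
        best <- sub[order(-sub$score, sub$start), , drop = FALSE][1L, ]
        rows[[length(rows) + 1L]] <- best
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$mirna_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write MRE hits to TSV
#'
#' Coordinates are converted to 1-based closed intervals for the
#' human-readable report.
#'
#' @param hits data frame from [predict_targets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  rep <- hits
  rep$start <- rep$start + 1L
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
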