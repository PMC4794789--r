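# Conserved-motif discovery: deterministic conservation-window scanning
# with bracket-notation consensus rendering.
#
# A motif here is an ungapped stretch of columns whose mean per-column
# conservation score is high; its consensus pattern writes one token per
# column -- a bare letter when a single residue passes the inclusion
# threshold, a bracketed list ("[FY]") for a small set of alternatives,
# and 'x' for highly variable columns.

# per-column family conservation score with gap down-weighting
family_column_scores <- function(aln, bg, method = "kl") {
  cnts <- count_block(aln_codes(aln))
  w <- 1 - cnts["gap", ] / length(aln$ids)
  score_columns(cnts[AA20, , drop = FALSE], bg, method) * w
}

#' Sliding-window conservation scores
#'
#' Scores every window of `width` columns by the mean family conservation
#' score of its columns (each column's score multiplied by one minus its
#' gap fraction, as in [gent_scan()]).
#'
#' @param aln a [labeled_alignment()].
#' @param width window width in columns, between 1 and `n_columns`.
#' @param bg a [background_frequencies()] model.
#' @param method score function, as in [conservation_score()].
#' @return numeric vector of window scores, named by 1-based start column.
#' @export
scan_windows <- function(aln, width, bg = background_frequencies("uniform"),
                         method = c("kl", "negentropy")) {
  stopifnot(inherits(aln, "labeled_alignment"))
  method <- match.arg(method)
  if (width < 1L || width > aln$n_columns) {
    stop("window width out of range 1..", aln$n_columns)
  }
  s <- family_column_scores(aln, bg, method)
  starts <- seq_len(aln$n_columns - width + 1L)
  # direct per-window means (not a cumsum sweep) so that windows over
  # identical columns score exactly equal and ties stay deterministic
  stats::setNames(vapply(starts, function(st) {
    mean(s[st:(st + width - 1L)])
  }, numeric(1L)), starts)
}

#' Find conserved motifs
#'
#' Greedy selection of the highest-scoring non-overlapping conservation
#' windows, over one or several window widths. Ties break by leftmost
#' start (then narrower width); selected motifs are separated by at least
#' `min_separation` columns.
#'
#' @param aln a [labeled_alignment()].
#' @param width window width(s) in columns; scalar or vector.
#' @param n_motifs number of motifs requested; fewer are returned (with a
#'   message) when the alignment cannot host that many.
#' @param min_separation minimum number of columns between two selected
#'   motifs (default 0).
#' @param bg,method as in [scan_windows()].
#' @param include_threshold,x_max_residues consensus rendering controls,
#'   see [consensus_pattern()].
#' @return data.frame of class `motif_set`, in descending score order:
#'   `motif`, `length`, `pattern`, `start_col`, `end_col`, `score`.
#' @export
find_motifs <- function(aln, width = 21L, n_motifs = 10L,
                        min_separation = 0L,
                        bg = background_frequencies("uniform"),
                        method = c("kl", "negentropy"),
                        include_threshold = 0.10, x_max_residues = 4L) {
  stopifnot(inherits(aln, "labeled_alignment"), n_motifs >= 1L)
  method <- match.arg(method)
  width <- sort(unique(as.integer(width)))
  cand <- do.call(rbind, lapply(width, function(w) {
    sc <- scan_windows(aln, w, bg, method)
    data.frame(start = as.integer(names(sc)), width = w,
               score = unname(sc))
  }))
  cand$end <- cand$start + cand$width - 1L
  cand <- cand[order(-cand$score, cand$start, cand$width), , drop = FALSE]

  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= n_motifs) break
    ok <- all(cand$start[i] > cand$end[sel] + min_separation |
              cand$end[i] < cand$start[sel] - min_separation)
    if (ok) sel <- c(sel, i)
  }
  if (length(sel) < n_motifs) {
    message("only ", length(sel), " of ", n_motifs,
            " requested motifs fit the alignment")
  }
  chosen <- cand[sel, , drop = FALSE]
  out <- data.frame(motif = seq_len(nrow(chosen)),
                    length = chosen$width,
                    pattern = vapply(seq_len(nrow(chosen)), function(i) {
                      consensus_pattern(aln, chosen$start[i], chosen$end[i],
                                        include_threshold, x_max_residues)
                    }, character(1L)),
                    start_col = chosen$start,
                    end_col = chosen$end,
                    score = chosen$score,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_set", "data.frame")
  out
}

#' Bracket-notation consensus pattern of a column range
#'
#' Per column, the residues with family frequency at or above
#' `include_threshold` (gap-inclusive denominator) are listed in
#' descending frequency: a single residue renders as a bare letter, 2 to
#' `x_max_residues` as a bracketed list, and more (or none) as the
#' wildcard `x`.
#'
#' @param aln a [labeled_alignment()].
#' @param start_col,end_col inclusive 1-based column range.
#' @param include_threshold minimum frequency for a residue to appear
#'   (default 0.10).
#' @param x_max_residues maximum bracket arity before collapsing to `x`
#'   (default 4).
#' @return a pattern string with exactly `end_col - start_col + 1`
#'   tokens; see [pattern_tokens()].
#' @examples
#' aln <- labeled_alignment(c(a = "GS", b = "GT"))
#' consensus_pattern(aln, 1, 2)  # "G[ST]"
#' @export
consensus_pattern <- function(aln, start_col, end_col,
                              include_threshold = 0.10,
                              x_max_residues = 4L) {
  stopifnot(inherits(aln, "labeled_alignment"),
            start_col >= 1L, end_col <= aln$n_columns, start_col <= end_col)
  cnts <- count_block(aln_codes(aln))[AA20, start_col:end_col, drop = FALSE]
  n <- length(aln$ids)
  tokens <- vapply(seq_len(ncol(cnts)), function(j) {
    cnt <- cnts[, j]
    keep <- which(cnt / n >= include_threshold)
    keep <- keep[order(-cnt[keep], AA20[keep])]
    k <- length(keep)
    if (k == 1L) AA20[keep]
    else if (k >= 2L && k <= x_max_residues) {
      paste0("[", paste(AA20[keep], collapse = ""), "]")
    } else "x"
  }, character(1L))
  paste(tokens, collapse = "")
}

#' Tokenize a bracket-notation pattern
#'
#' @param pattern a [consensus_pattern()] string.
#' @return character vector with one element per column token (bare
#'   letter, bracketed list, or `x`).
#' @export
pattern_tokens <- function(pattern) {
  regmatches(pattern, gregexpr("\\[[A-Z]+\\]|[A-Z]|x", pattern))[[1L]]
}

#' @export
print.motif_set <- function(x, ...) {
  cat("Conserved motifs (", nrow(x), "):\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 4L)
  invisible(x)
}
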