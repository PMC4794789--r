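# Per-column conservation profiles and the three-band classification
# (100% / 80-99% / 60-79% modal-residue frequency).
#
# Conventions: fractions are computed with gaps in the denominator, so an
# "invariant" column really carries the same residue in every sequence; an
# all-gap column is below_60 by definition. Ambiguity letters (B/Z/X) are
# counted as "other" and are never the modal residue. Modal-residue ties
# break alphabetically.

BAND_LEVELS <- c("invariant", "band_80_99", "band_60_79", "below_60")

# 22 x n_columns count matrix over the given row subset:
# row 1 = gaps, rows 2..21 = AA20, row 22 = ambiguity letters
count_block <- function(codes, rows = seq_len(nrow(codes))) {
  m <- ncol(codes)
  sub <- codes[rows, , drop = FALSE]
  out <- vapply(seq_len(m),
                function(j) tabulate(sub[, j] + 1L, nbins = 22L),
                integer(22L))
  rownames(out) <- c("gap", AA20, "other")
  out
}

rows_in_scope <- function(aln, scope) {
  if (identical(scope, "family")) return(seq_along(aln$ids))
  rows <- which(aln$groups == scope)
  if (!length(rows)) stop("empty scope: no sequences in group '", scope, "'")
  rows
}

#' Residue counts of one alignment column
#'
#' @param aln a [labeled_alignment()].
#' @param col 1-based column index.
#' @param scope `"family"` (all sequences) or a group name.
#' @return An object of class `column_profile`: `col`, `scope`, `counts`
#'   (named integer vector over the 20 residues plus `"other"` for
#'   ambiguity letters), `gap_count` and `n` (sequences in scope);
#'   `sum(counts) + gap_count == n`.
#' @export
column_profile <- function(aln, col, scope = "family") {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (col < 1L || col > aln$n_columns) {
    stop("column index out of range 1..", aln$n_columns)
  }
  rows <- rows_in_scope(aln, scope)
  codes <- aln_codes(aln)[rows, col, drop = TRUE]
  tab <- tabulate(codes + 1L, nbins = 22L)
  structure(list(col = as.integer(col), scope = scope,
                 counts = stats::setNames(tab[-1L], c(AA20, "other")),
                 gap_count = tab[1L], n = length(rows)),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  nz <- x$counts[x$counts > 0L]
  cat("Column ", x$col, " (", x$scope, ", n=", x$n, "): ",
      paste(names(nz), nz, sep = ":", collapse = " "),
      if (x$gap_count) paste0(" gap:", x$gap_count), "\n", sep = "")
  invisible(x)
}

#' Modal residue and its conservation fraction
#'
#' The fraction uses the full scope size `n` as denominator (gaps
#' included); gaps and ambiguity letters are never modal and ties between
#' residues break alphabetically.
#'
#' @param p a [column_profile()].
#' @return list with `modal_residue` (single letter, or `NA` for an
#'   all-gap column) and `fraction` in `[0, 1]`.
#' @export
conservation_fraction <- function(p) {
  stopifnot(inherits(p, "column_profile"), p$n >= 1L)
  cnt <- p$counts[AA20]
  if (max(cnt) == 0L) {
    return(list(modal_residue = NA_character_, fraction = 0))
  }
  i <- which.max(cnt)  # AA20 is alphabetical, which.max takes the first tie
  list(modal_residue = AA20[i], fraction = unname(cnt[i]) / p$n)
}

band_of <- function(fraction) {
  factor(ifelse(fraction == 1, "invariant",
         ifelse(fraction >= 0.80, "band_80_99",
         ifelse(fraction >= 0.60, "band_60_79", "below_60"))),
         levels = BAND_LEVELS)
}

#' Classify every column into a conservation band
#'
#' Bands on the modal-residue fraction f over all sequences (gaps in the
#' denominator): `f == 1` invariant; `0.80 <= f < 1` band_80_99;
#' `0.60 <= f < 0.80` band_60_79; otherwise below_60. Both band boundaries
#' are inclusive at the lower edge.
#'
#' @param aln a [labeled_alignment()].
#' @return data.frame of class `conservation_records` with columns `col`,
#'   `modal_residue`, `fraction`, `percent` (rounded half-up to an
#'   integer; band assignment always uses the unrounded fraction) and
#'   `band`.
#' @export
classify_columns <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  cnts <- count_block(aln_codes(aln))
  aa <- cnts[AA20, , drop = FALSE]
  top <- apply(aa, 2L, which.max)
  mx <- aa[cbind(top, seq_len(ncol(aa)))]
  frac <- ifelse(mx == 0L, 0, mx / length(aln$ids))
  out <- data.frame(col = seq_len(aln$n_columns),
                    modal_residue = ifelse(mx == 0L, NA_character_, AA20[top]),
                    fraction = frac,
                    percent = floor(frac * 100 + 0.5),
                    band = band_of(frac),
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_records", "data.frame")
  out
}

#' Count columns per conservation band
#'
#' @param records a [classify_columns()] result (or any data.frame with a
#'   `band` column).
#' @return named integer vector over the four bands; sums to the number of
#'   records.
#' @export
band_summary <- function(records) {
  band <- factor(records$band, levels = BAND_LEVELS)
  tab <- table(band)
  stats::setNames(as.integer(tab), BAND_LEVELS)
}

#' Per-group residue composition of one column
#'
#' @param aln a [labeled_alignment()] with declared groups.
#' @param col 1-based column index.
#' @return data.frame with one row per declared group (plus
#'   `"unassigned"` when present, plus `"family"`): `scope`, `n`,
#'   `modal_residue`, `fraction`, `gap_fraction`. The full
#'   [column_profile()] objects are attached as attribute `"profiles"`.
#' @examples
#' aln <- labeled_alignment(c(a = "R", b = "R", c = "F"),
#'                          groups = c(a = "G1", b = "G1", c = "G2"))
#' group_composition(aln, 1)
#' @export
group_composition <- function(aln, col) {
  scopes <- c(declared_groups(aln),
              intersect("unassigned", unique(aln$groups)), "family")
  profs <- lapply(scopes, function(s) column_profile(aln, col, s))
  names(profs) <- scopes
  rows <- lapply(profs, function(p) {
    cf <- conservation_fraction(p)
    data.frame(scope = p$scope, n = p$n,
               modal_residue = cf$modal_residue, fraction = cf$fraction,
               gap_fraction = p$gap_count / p$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "profiles") <- profs
  out
}
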