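# Mapping between reference residue numbers and alignment column indices.
#
# Published residue identities are usually quoted on an ungapped reference
# sequence (e.g. "Cys260" of a structure), while the alignment itself is
# addressed by 1-based column index including gap columns. A reference map
# holds the bijection between the two over the non-gap positions of one
# reference row.

#' Build a reference residue-number map
#'
#' Residue number `r` of the reference sequence maps to the alignment
#' column holding its r-th non-gap character (both 1-based).
#'
#' @param aln a [labeled_alignment()].
#' @param ref_id id of the reference sequence in `aln`.
#' @return An object of class `reference_map`: `ref_id`, `res_to_col`
#'   (integer vector indexed by residue number) and `col_to_res` (integer
#'   vector of length `n_columns`, `NA` where the reference row is gapped).
#' @examples
#' aln <- labeled_alignment(c(r = "-MK-IS", s = "AMKLIS"))
#' m <- build_reference_map(aln, "r")
#' m$res_to_col[1]   # column 2
#' map_index_to_ref(m, 5)  # residue 3
#' @export
build_reference_map <- function(aln, ref_id) {
  stopifnot(inherits(aln, "labeled_alignment"))
  if (!ref_id %in% aln$ids) {
    stop("unknown reference sequence: '", ref_id, "'")
  }
  chars <- strsplit(aln$seqs[[ref_id]], "")[[1L]]
  nongap <- which(chars != GAP)
  col_to_res <- rep(NA_integer_, aln$n_columns)
  col_to_res[nongap] <- seq_along(nongap)
  structure(list(ref_id = ref_id,
                 res_to_col = nongap,
                 col_to_res = col_to_res,
                 n_columns = aln$n_columns),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat("Reference map for '", x$ref_id, "': ", length(x$res_to_col),
      " residues over ", x$n_columns, " alignment columns\n", sep = "")
  invisible(x)
}

#' Map an alignment column to a reference residue number
#'
#' @param map a [build_reference_map()] result.
#' @param col 1-based alignment column index.
#' @return the residue number, or `NA_integer_` when the reference row is
#'   gapped at `col`.
#' @export
map_index_to_ref <- function(map, col) {
  stopifnot(inherits(map, "reference_map"))
  if (any(col < 1L | col > map$n_columns)) {
    stop("column index out of range 1..", map$n_columns)
  }
  map$col_to_res[col]
}

#' Map a reference residue number to its alignment column
#'
#' @param map a [build_reference_map()] result.
#' @param res 1-based residue number in the ungapped reference sequence.
#' @return the alignment column index.
#' @export
map_ref_to_index <- function(map, res) {
  stopifnot(inherits(map, "reference_map"))
  if (any(res < 1L | res > length(map$res_to_col))) {
    stop("residue number out of range 1..", length(map$res_to_col))
  }
  map$res_to_col[res]
}
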