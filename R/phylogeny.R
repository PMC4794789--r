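# Distance-based phylogeny stage: gap trimming, protein distances,
# neighbor joining, column bootstrap, majority-rule consensus and
# per-group clade support.

#' Drop gap-rich alignment columns
#'
#' Keeps exactly the columns whose family gap fraction is at or below
#' `max_gap_fraction`, preserving order.
#'
#' @param aln a [labeled_alignment()].
#' @param max_gap_fraction columns with a larger gap fraction are dropped
#'   (default 0.5).
#' @return a [labeled_alignment()] with attribute `"column_map"`: the
#'   original 1-based indices of the kept columns.
#' @export
trim_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(inherits(aln, "labeled_alignment"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- aln_matrix(aln)
  gap_frac <- colMeans(m == GAP)
  keep <- which(gap_frac <= max_gap_fraction)
  if (!length(keep)) stop("trimming removed every column")
  sub <- m[, keep, drop = FALSE]
  out <- labeled_alignment(apply(sub, 1L, paste, collapse = ""),
                           ids = aln$ids, groups = aln$groups)
  attr(out, "column_map") <- keep
  out
}

# pairwise distances from an integer-coded alignment matrix.
# p-distance: mismatch fraction over pairwise non-gap columns.
# kimura: -ln(1 - p - 0.2 p^2); undefined arguments (p >= 0.8541) are
# mapped to a ceiling of 10.0.
dist_from_codes <- function(codes, model = c("p", "kimura")) {
  model <- match.arg(model)
  n <- nrow(codes)
  nongap <- (codes != 0L) * 1
  comparable <- tcrossprod(nongap)
  matches <- matrix(0, n, n)
  for (code in unique(codes[codes != 0L])) {
    ind <- (codes == code) * 1
    matches <- matches + tcrossprod(ind)
  }
  offdiag <- comparable[upper.tri(comparable)]
  if (any(offdiag == 0)) {
    idx <- which(comparable == 0 & upper.tri(comparable), arr.ind = TRUE)[1L, ]
    stop("no comparable (pairwise ungapped) columns between '",
         rownames(codes)[idx[1L]], "' and '", rownames(codes)[idx[2L]], "'")
  }
  p <- (comparable - matches) / comparable
  diag(p) <- 0
  if (model == "kimura") {
    arg <- 1 - p - 0.2 * p^2
    d <- ifelse(arg <= 0, 10.0, -log(pmax(arg, 1e-300)))
    diag(d) <- 0
  } else {
    d <- p
  }
  dimnames(d) <- list(rownames(codes), rownames(codes))
  d
}

#' Pairwise protein distance matrix
#'
#' `model = "p"` gives the mismatch fraction over the columns where both
#' sequences are ungapped; `model = "kimura"` applies Kimura's correction
#' `-ln(1 - p - 0.2 p^2)` for multiple substitutions, with undefined
#' arguments (p at or above 0.8541) mapped to a declared ceiling of 10.0.
#'
#' @param aln a [labeled_alignment()]; every pair of sequences must share
#'   at least one ungapped column.
#' @param model `"p"` or `"kimura"`.
#' @return symmetric numeric matrix with zero diagonal, labeled by
#'   sequence id.
#' @export
distance_matrix <- function(aln, model = c("p", "kimura")) {
  stopifnot(inherits(aln, "labeled_alignment"))
  dist_from_codes(aln_codes(aln), match.arg(model))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix (via [ape::nj()]);
#' negative branch-length estimates are clamped to zero with a message.
#'
#' @param D symmetric distance matrix with labels (e.g. from
#'   [distance_matrix()]), at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

# canonical key for the bipartition separating `side` from the rest:
# the side NOT containing the alphabetically first label, sorted and
# comma-joined
split_key <- function(side, labels) {
  ref <- sort(labels)[1L]
  if (ref %in% side) side <- setdiff(labels, side)
  paste(sort(side), collapse = ",")
}

# non-trivial bipartitions of an unrooted phylo tree, as canonical keys
tree_split_keys <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  sets <- lapply(pp, function(ix) tree$tip.label[ix])
  sets <- sets[vapply(sets, length, integer(1L)) %in% seq(2L, n - 2L)]
  unique(vapply(sets, split_key, character(1L), labels = tree$tip.label))
}

#' Bootstrap support for bipartitions
#'
#' Resamples alignment columns with replacement `R` times; each replicate
#' rebuilds the distance matrix and neighbor-joining tree and tallies its
#' non-trivial bipartitions. A replicate in which some sequence pair has
#' no comparable columns is skipped (the effective denominator `R_used`
#' shrinks accordingly). Reproducible for a fixed `seed`.
#'
#' @param aln a [labeled_alignment()] of at least 4 sequences (trim first
#'   with [trim_columns()] as appropriate).
#' @param R number of bootstrap replicates.
#' @param seed integer seed for the column resampling.
#' @param model distance model, as in [distance_matrix()].
#' @return An object of class `bootstrap_tallies`: `counts` (named
#'   integer vector keyed by canonical split), `R`, `R_used`, `skipped`,
#'   `labels`, `model`, `seed`.
#' @export
bootstrap_support <- function(aln, R, seed = 1L, model = c("p", "kimura")) {
  stopifnot(inherits(aln, "labeled_alignment"), R >= 1L,
            length(aln$ids) >= 4L)
  model <- match.arg(model)
  codes <- aln_codes(aln)
  m <- ncol(codes)
  counts <- integer(0)
  skipped <- 0L
  set.seed(seed)
  for (r in seq_len(R)) {
    cols <- sample.int(m, m, replace = TRUE)
    D <- tryCatch(dist_from_codes(codes[, cols, drop = FALSE], model),
                  error = function(e) NULL)
    if (is.null(D)) {
      skipped <- skipped + 1L
      next
    }
    keys <- tree_split_keys(suppressMessages(nj_tree(D)))
    new <- setdiff(keys, names(counts))
    if (length(new)) counts[new] <- 0L
    counts[keys] <- counts[keys] + 1L
  }
  if (skipped) message(skipped, " replicate(s) skipped (incomparable pair)")
  structure(list(counts = counts, R = R, R_used = R - skipped,
                 skipped = skipped, labels = aln$ids, model = model,
                 seed = seed),
            class = "bootstrap_tallies")
}

#' @export
print.bootstrap_tallies <- function(x, ...) {
  cat("Bootstrap tallies: ", x$R_used, "/", x$R, " replicates, ",
      length(x$counts), " distinct bipartitions, ", length(x$labels),
      " taxa\n", sep = "")
  invisible(x)
}

#' Majority-rule consensus tree
#'
#' Builds the unrooted tree containing exactly the bipartitions present
#' in strictly more than half of the (non-skipped) bootstrap replicates;
#' such splits are always pairwise compatible. Support counts are
#' attached as internal node labels.
#'
#' @param tallies a [bootstrap_support()] result.
#' @return a `phylo` tree without branch lengths; internal node labels
#'   carry the support counts (out of `tallies$R_used`).
#' @export
consensus_tree <- function(tallies) {
  stopifnot(inherits(tallies, "bootstrap_tallies"))
  labels <- tallies$labels
  maj <- tallies$counts[tallies$counts > tallies$R_used / 2]
  clades <- lapply(names(maj), function(k) strsplit(k, ",", fixed = TRUE)[[1L]])
  supports <- as.integer(maj)
  ord <- order(-vapply(clades, length, integer(1L)))
  clades <- clades[ord]
  supports <- supports[ord]

  build <- function(members, label) {
    inside <- which(vapply(clades, function(cl) {
      length(cl) < length(members) && all(cl %in% members)
    }, logical(1L)))
    children <- character(0)
    used <- character(0)
    for (i in inside) {  # size-descending: first hit inside is maximal
      cl <- clades[[i]]
      if (!any(cl %in% used)) {
        children <- c(children, build_idx(i))
        used <- c(used, cl)
      }
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(children, sort(singles)), collapse = ","), ")", label)
  }
  build_idx <- function(i) build(clades[[i]], supports[i])

  nwk <- paste0(build(labels, ""), ";")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "R_used") <- tallies$R_used
  tree
}

#' Clade support for one group
#'
#' Reports whether a group's sequences form a bipartition of the
#' majority-rule consensus, the bootstrap tally of that bipartition, and
#' the largest fraction of the group contained in a pure majority clade
#' (a consensus split side consisting only of group members).
#'
#' @param tallies a [bootstrap_support()] result.
#' @param aln the [labeled_alignment()] the bootstrap was run on (supplies
#'   the group labels).
#' @param group group name.
#' @return list of class `clade_support`: `group`, `n`, `support`
#'   (bootstrap count for the group's bipartition; `NA` for a
#'   single-sequence group), `R_used`, `monophyletic` (present in the
#'   majority-rule consensus) and `largest_pure_fraction`.
#' @export
group_clade_support <- function(tallies, aln, group) {
  stopifnot(inherits(tallies, "bootstrap_tallies"),
            inherits(aln, "labeled_alignment"))
  members <- aln$ids[aln$groups == group]
  if (!length(members)) stop("group '", group, "' has no sequences")
  labels <- tallies$labels
  n_g <- length(members)
  out <- list(group = group, n = n_g, R_used = tallies$R_used)
  if (n_g == 1L || n_g >= length(labels) - 1L) {
    # a single leaf (or all-but-one) is a trivial split: monophyly holds
    # vacuously and bootstrap support is not applicable
    out$support <- NA_integer_
    out$monophyletic <- TRUE
    out$largest_pure_fraction <- 1
  } else {
    key <- split_key(members, labels)
    cnt <- tallies$counts[key]
    out$support <- if (is.na(cnt)) 0L else as.integer(cnt)
    out$monophyletic <- out$support > tallies$R_used / 2
    maj <- names(tallies$counts)[tallies$counts > tallies$R_used / 2]
    best <- 1L  # every singleton leaf is a pure clade
    for (k in maj) {
      side <- strsplit(k, ",", fixed = TRUE)[[1L]]
      for (s in list(side, setdiff(labels, side))) {
        if (all(s %in% members)) best <- max(best, length(s))
      }
    }
    out$largest_pure_fraction <- if (out$monophyletic) 1 else best / n_g
  }
  structure(out, class = "clade_support")
}

#' @export
print.clade_support <- function(x, ...) {
  cat("Group '", x$group, "' (n=", x$n, "): ",
      if (isTRUE(x$monophyletic)) "monophyletic" else "not monophyletic",
      ", support ",
      if (is.na(x$support)) "n/a" else
        paste0(x$support, "/", x$R_used),
      ", largest pure clade ",
      format(x$largest_pure_fraction, digits = 3L), "\n", sep = "")
  invisible(x)
}
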