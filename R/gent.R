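# Group-entropy versus family-entropy scan for group-specific conserved
# positions.
#
# For every alignment column a conservation score is computed twice with
# the same score function: once on the column restricted to one group (GE,
# "group entropy") and once on the whole alignment (FE, "family entropy").
# Positions that are strongly conserved within the group but not across
# the family -- high GE, low FE, the upper-left quadrant of a GE-vs-FE
# plot -- are candidate specificity-determining positions.
#
# Two score functions are available behind one interface: the
# Kullback-Leibler divergence of the column residue distribution from a
# background model (default) and the negentropy log2(20) - H. Both are in
# bits, non-negative, and larger for more conserved columns. Gap cells are
# excluded from the distribution and the score is down-weighted by
# (1 - gap fraction) in scope, so indel-dominated columns rank low.

#' Background residue frequency model
#'
#' @param source `"uniform"` (each residue 1/20) or `"alignment"`
#'   (frequencies pooled over all non-gap cells of `aln`, pseudocount
#'   smoothed).
#' @param aln a [labeled_alignment()], required for `source = "alignment"`.
#' @param pseudocount per-residue pseudocount alpha, added to column counts
#'   when scoring (and to the pooled counts for `source = "alignment"`,
#'   where it must be positive so every frequency stays nonzero).
#' @return An object of class `background_model` with `freqs` (named over
#'   the 20 residues, summing to 1) and `pseudocount`.
#' @export
background_frequencies <- function(source = c("uniform", "alignment"),
                                   aln = NULL, pseudocount = 0.05) {
  source <- match.arg(source)
  stopifnot(pseudocount >= 0)
  if (source == "uniform") {
    freqs <- stats::setNames(rep(1 / 20, 20L), AA20)
  } else {
    stopifnot(inherits(aln, "labeled_alignment"))
    if (pseudocount <= 0) {
      stop("alignment-derived background needs a positive pseudocount")
    }
    cnt <- rowSums(count_block(aln_codes(aln))[AA20, , drop = FALSE])
    if (sum(cnt) == 0) stop("alignment contains no residues")
    freqs <- (cnt + pseudocount) / (sum(cnt) + 20 * pseudocount)
  }
  structure(list(freqs = freqs, pseudocount = pseudocount),
            class = "background_model")
}

# vectorized score over a 20 x m residue-count matrix (gap/ambiguity rows
# already dropped); returns 0 for columns without residues
score_columns <- function(aa_counts, bg, method = c("kl", "negentropy")) {
  method <- match.arg(method)
  a <- bg$pseudocount
  nres <- colSums(aa_counts)
  denom <- nres + 20 * a
  denom[denom == 0] <- 1  # all-gap columns score 0 below
  p <- sweep(aa_counts + a, 2L, denom, "/")
  if (method == "kl") {
    terms <- p * log2(sweep(p, 1L, bg$freqs, "/"))
  } else {
    terms <- log2(20) / 20 + p * log2(p)  # negentropy = log2(20) - H
  }
  terms[p == 0] <- if (method == "kl") 0 else log2(20) / 20
  s <- colSums(terms)
  s[nres == 0] <- 0
  pmax(s, 0)
}

#' Conservation score of a column profile
#'
#' Gap and ambiguity cells are excluded and the residue distribution is
#' renormalized with pseudocount `bg$pseudocount` per residue. `"kl"` is
#' the Kullback-Leibler divergence from the background (zero iff the
#' column matches the background); `"negentropy"` is `log2(20)` minus the
#' Shannon entropy (zero iff uniform). Both in bits (log base 2),
#' non-negative, larger = more conserved; an all-gap column scores 0.
#'
#' @param p a [column_profile()].
#' @param bg a [background_frequencies()] model.
#' @param method `"kl"` or `"negentropy"`.
#' @return a single non-negative number.
#' @examples
#' aln <- labeled_alignment(c(a = "G", b = "G"))
#' bg0 <- background_frequencies("uniform", pseudocount = 0)
#' conservation_score(column_profile(aln, 1), bg0)  # log2(20)
#' @export
conservation_score <- function(p, bg, method = c("kl", "negentropy")) {
  stopifnot(inherits(p, "column_profile"), inherits(bg, "background_model"))
  score_columns(matrix(p$counts[AA20], ncol = 1L, dimnames = list(AA20)),
                bg, method)[[1L]]
}

# modal residue letter per column of a 20 x m count matrix (NA when empty)
modal_letters <- function(aa_counts) {
  top <- apply(aa_counts, 2L, which.max)
  mx <- aa_counts[cbind(top, seq_len(ncol(aa_counts)))]
  ifelse(mx == 0L, NA_character_, AA20[top])
}

# comma-joined residues with frequency >= threshold of the scope size,
# most frequent first, alphabetical within ties
common_letters <- function(aa_counts, n_scope, threshold) {
  vapply(seq_len(ncol(aa_counts)), function(j) {
    cnt <- aa_counts[, j]
    keep <- which(cnt / n_scope >= threshold)
    if (!length(keep)) return("")
    keep <- keep[order(-cnt[keep], AA20[keep])]
    paste(AA20[keep], collapse = ",")
  }, character(1L))
}

#' Scan an alignment for group-specific conservation
#'
#' Computes, for every column, the group score GE (conservation score of
#' the column restricted to `group`), the family score FE (same score over
#' all sequences), the group's modal residue, and the residues common
#' (within-group frequency >= `common_threshold`) in each other declared
#' group. Both scores are multiplied by one minus the gap fraction in
#' their scope.
#'
#' @param aln a [labeled_alignment()] with declared groups.
#' @param group the target group name.
#' @param bg a [background_frequencies()] model; default uniform with
#'   pseudocount 0.05.
#' @param method score function, `"kl"` (default) or `"negentropy"`.
#' @param common_threshold within-group frequency at or above which a
#'   residue is listed as "common" for the other groups (default 0.25).
#' @return A data.frame of class `gent_scan` with columns `col`, `group`,
#'   `GE`, `FE`, `highest_group_residue` and one `common_<group>` column
#'   per other declared group (comma-joined one-letter codes, most
#'   frequent first). Use [rank_group_specific()], [quadrant_classify()]
#'   and `plot()` on it.
#' @export
gent_scan <- function(aln, group, bg = background_frequencies("uniform"),
                      method = c("kl", "negentropy"),
                      common_threshold = 0.25) {
  stopifnot(inherits(aln, "labeled_alignment"))
  method <- match.arg(method)
  groups <- declared_groups(aln)
  if (!group %in% groups) {
    stop("group '", group, "' is not declared in the alignment")
  }
  codes <- aln_codes(aln)
  fam_cnt <- count_block(codes)
  grp_rows <- which(aln$groups == group)
  grp_cnt <- count_block(codes, grp_rows)

  ge_w <- 1 - grp_cnt["gap", ] / length(grp_rows)
  fe_w <- 1 - fam_cnt["gap", ] / length(aln$ids)
  GE <- score_columns(grp_cnt[AA20, , drop = FALSE], bg, method) * ge_w
  FE <- score_columns(fam_cnt[AA20, , drop = FALSE], bg, method) * fe_w

  out <- data.frame(col = seq_len(aln$n_columns), group = group,
                    GE = GE, FE = FE,
                    highest_group_residue =
                      modal_letters(grp_cnt[AA20, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  for (g in setdiff(groups, group)) {
    rows <- which(aln$groups == g)
    cnt <- count_block(codes, rows)[AA20, , drop = FALSE]
    out[[paste0("common_", g)]] <-
      common_letters(cnt, length(rows), common_threshold)
  }
  structure(out, class = c("gent_scan", "data.frame"),
            group = group, method = method,
            n_group = length(grp_rows), pseudocount = bg$pseudocount)
}

# Default quadrant boundaries: the midpoint of each score's observed
# range, i.e. the literal quadrants of the GE-vs-FE scatter. A midrange
# boundary adapts to alignment size like a percentile would, but stays
# meaningful when most columns are unconserved: a position conserved in a
# group holding a large share of the family carries an irreducible
# family-entropy floor (about share * log2(20 * share) bits), which a
# median cutoff over background-dominated alignments would wrongly
# exclude.
default_fe_cutoff <- function(records) {
  (min(records$FE) + max(records$FE)) / 2
}

default_ge_cutoff <- function(records) {
  (min(records$GE) + max(records$GE)) / 2
}

#' Rank group-specific positions
#'
#' Keeps the columns whose family score FE is at or below `fe_cutoff`,
#' orders them by decreasing group score GE (ties by column index) and
#' truncates to `top_n` -- the tabular form of the upper-left quadrant of
#' the GE-vs-FE plot.
#'
#' @param records a [gent_scan()] result.
#' @param fe_cutoff absolute FE cutoff; by default the midpoint of the
#'   observed FE range (the quadrant boundary of the GE-vs-FE plot,
#'   adapting to alignment size).
#' @param top_n number of positions to report (default 10).
#' @return the selected rows of `records`, ranked; the applied cutoff is
#'   attached as attribute `"fe_cutoff"`.
#' @export
rank_group_specific <- function(records, fe_cutoff = NULL, top_n = 10L) {
  stopifnot(inherits(records, "gent_scan"), top_n >= 1L)
  if (is.null(fe_cutoff)) fe_cutoff <- default_fe_cutoff(records)
  keep <- records[records$FE <= fe_cutoff, , drop = FALSE]
  keep <- keep[order(-keep$GE, keep$col), , drop = FALSE]
  keep <- utils::head(keep, top_n)
  rownames(keep) <- NULL
  attr(keep, "fe_cutoff") <- fe_cutoff
  keep
}

#' Quadrant classification of a GEnt scan
#'
#' Partitions columns by the two cutoffs: `group_specific` (GE >=
#' `ge_cutoff` and FE < `fe_cutoff`, the upper-left quadrant),
#' `group_and_family` (both high), `family_conserved` (FE >= cutoff
#' only) and `unconserved` (neither).
#'
#' @param records a [gent_scan()] result.
#' @param ge_cutoff GE cutoff; default midpoint of the observed GE range.
#' @param fe_cutoff FE cutoff; default midpoint of the observed FE range.
#' @return factor of length `nrow(records)`, named by column index.
#' @export
quadrant_classify <- function(records, ge_cutoff = NULL, fe_cutoff = NULL) {
  stopifnot(inherits(records, "gent_scan"))
  if (is.null(ge_cutoff)) ge_cutoff <- default_ge_cutoff(records)
  if (is.null(fe_cutoff)) fe_cutoff <- default_fe_cutoff(records)
  stopifnot(ge_cutoff > 0, fe_cutoff > 0)
  hi_ge <- records$GE >= ge_cutoff
  lo_fe <- records$FE < fe_cutoff
  cls <- ifelse(hi_ge & lo_fe, "group_specific",
         ifelse(hi_ge, "group_and_family",
         ifelse(!lo_fe, "family_conserved", "unconserved")))
  factor(stats::setNames(cls, records$col),
         levels = c("group_specific", "group_and_family",
                    "family_conserved", "unconserved"))
}

#' @export
print.gent_scan <- function(x, ...) {
  cat("GEnt scan: group '", attr(x, "group"), "' (n=", attr(x, "n_group"),
      "), method ", attr(x, "method"), ", ", nrow(x), " columns\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.gent_scan <- function(object, top_n = 10L, ...) {
  top <- rank_group_specific(object, top_n = top_n)
  cat("Top group-specific positions for '", attr(object, "group"),
      "' (FE <= ", format(attr(top, "fe_cutoff"), digits = 3L),
      ", by GE):\n", sep = "")
  print.data.frame(as.data.frame(top), digits = 4L)
  invisible(top)
}

#' GE-versus-FE quadrant plot
#'
#' Scatter of family score (x) against group score (y) with the two
#' cutoffs as dashed lines; upper-left points are the group-specific
#' candidates and are drawn filled.
#'
#' @param x a [gent_scan()] result.
#' @param ge_cutoff,fe_cutoff cutoffs as in [quadrant_classify()].
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the [quadrant_classify()] factor used.
#' @export
plot.gent_scan <- function(x, ge_cutoff = NULL, fe_cutoff = NULL, ...) {
  if (is.null(ge_cutoff)) ge_cutoff <- default_ge_cutoff(x)
  if (is.null(fe_cutoff)) fe_cutoff <- default_fe_cutoff(x)
  quad <- quadrant_classify(x, ge_cutoff, fe_cutoff)
  is_gs <- quad == "group_specific"
  graphics::plot(x$FE, x$GE,
                 pch = ifelse(is_gs, 19L, 1L),
                 col = ifelse(is_gs, "firebrick", "grey40"),
                 xlab = "Family entropy (bits)",
                 ylab = "Group entropy (bits)",
                 main = paste0("Group-specific conservation: ",
                               attr(x, "group")), ...)
  graphics::abline(v = fe_cutoff, h = ge_cutoff, lty = 2L, col = "grey60")
  if (any(is_gs)) {
    graphics::text(x$FE[is_gs], x$GE[is_gs], labels = x$col[is_gs],
                   pos = 4L, cex = 0.7)
  }
  invisible(quad)
}
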