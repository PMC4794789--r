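# Shared fixtures and independent oracles.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

make_aln <- function(seqs, groups = NULL) {
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
  }
  labeled_alignment(seqs, groups = groups)
}

# random gapped alignment, uniform residues
rand_aln <- function(n, m, gap_prob = 0.1, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(AA, m, replace = TRUE)
    ch[runif(m) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  make_aln(seqs)
}

# term-by-term KL divergence oracle (counts over the 20 residues)
kl_brute <- function(counts, q, alpha = 0) {
  p <- (counts + alpha) / (sum(counts) + 20 * alpha)
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  }
  unname(s)
}

# Shannon-entropy oracle, base 2
negentropy_brute <- function(counts, alpha = 0) {
  p <- (counts + alpha) / (sum(counts) + 20 * alpha)
  h <- 0
  for (i in seq_along(p)) if (p[i] > 0) h <- h - p[i] * log2(p[i])
  unname(log2(20) - h)
}

# least-squares branch-length fit of a 4-taxon distance matrix to one of
# the three unrooted topologies; returns the residual sum of squares
ls_rss_4taxon <- function(D, pair1) {
  taxa <- rownames(D)
  pair2 <- setdiff(taxa, pair1)
  # branch order: pair1[1], pair1[2], pair2[1], pair2[2], internal
  rows <- list(c(pair1[1], pair1[2]), c(pair1[1], pair2[1]),
               c(pair1[1], pair2[2]), c(pair1[2], pair2[1]),
               c(pair1[2], pair2[2]), c(pair2[1], pair2[2]))
  X <- t(vapply(rows, function(pr) {
    v <- as.numeric(taxa %in% pr)
    internal <- !(all(pr %in% pair1) || all(pr %in% pair2))
    c(v[match(c(pair1, pair2), taxa)], as.numeric(internal))
  }, numeric(5)))
  y <- vapply(rows, function(pr) D[pr[1], pr[2]], numeric(1))
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

# are two bipartitions (each a side w.r.t. a common reference leaf held
# out of both sides) compatible?
splits_compatible <- function(a, b) {
  length(intersect(a, b)) == 0 || all(a %in% b) || all(b %in% a)
}

# alignment whose every column separates {a,b} from {c,d}
perfect_split_aln <- function(n_cols = 60) {
  half <- n_cols %/% 2
  pat <- function(x1, x2) {
    paste(rep(c(x1, x2), c(half, n_cols - half)), collapse = "")
  }
  make_aln(c(a = pat("A", "G"), b = pat("A", "G"),
             c = pat("T", "C"), d = pat("T", "C")))
}

# 4 groups, every column fully diagnostic of all groups: each group is
# monophyletic in every bootstrap replicate
four_group_aln <- function(per_group = 4, n_cols = 40, seed = 5) {
  set.seed(seed)
  groups <- rep(c("G1", "G2", "G3", "G4"), each = per_group)
  cols <- replicate(n_cols, sample(AA, 4))
  seqs <- vapply(seq_along(groups), function(i) {
    paste(cols[match(groups[i], c("G1", "G2", "G3", "G4")), ],
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s_s%d", groups, seq_along(groups))
  labeled_alignment(seqs, groups = setNames(groups, names(seqs)))
}

small_spec <- function(...) {
  args <- list(...)
  defaults <- list(group_sizes = c(A = 12L, B = 10L, C = 8L, D = 8L),
                   n_columns = 120L, n_invariant = 6L, n_band80 = 5L,
                   n_band60 = 8L,
                   group_specific = c(A = 3L, B = 3L, C = 2L, D = 2L),
                   gap_blocks = list(list(group = "C", start = 30L,
                                          width = 4L)),
                   within_group_noise = 0, seed = 42L)
  defaults[names(args)] <- args
  do.call(synthetic_spec, defaults)
}
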