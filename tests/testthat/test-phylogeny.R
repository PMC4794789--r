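test_that("gap-fraction trimming keeps exactly the qualifying columns", {
  aln <- make_aln(c("MK-A-", "MKLA-", "M--A-", "MK-AC"))
  trimmed <- trim_columns(aln, 0.5)
  gap_frac <- colMeans(do.call(rbind, strsplit(unname(aln$seqs), "")) == "-")
  expect_equal(attr(trimmed, "column_map"), which(gap_frac <= 0.5))
  expect_equal(trimmed$n_columns, sum(gap_frac <= 0.5))

  ungapped <- rand_aln(5, 20, gap_prob = 0, seed = 2)
  expect_equal(unname(trim_columns(ungapped, 0.5)$seqs),
               unname(ungapped$seqs))
  expect_error(trim_columns(make_aln(c("--", "--")), 0.4), "every column")
})

test_that("p and Kimura distances have their closed-form values", {
  aln <- make_aln(c(a = "AAAA", b = "AAAT"))
  Dp <- distance_matrix(aln, "p")
  expect_equal(Dp["a", "b"], 0.25)
  Dk <- distance_matrix(aln, "kimura")
  expect_equal(Dk["a", "b"], -log(1 - 0.25 - 0.2 * 0.25^2))
  expect_equal(round(Dk["a", "b"], 4), 0.3045)

  same <- make_aln(c(a = "MKLV", b = "MKLV"))
  expect_equal(distance_matrix(same, "p")["a", "b"], 0)
  expect_equal(distance_matrix(same, "kimura")["a", "b"], 0)

  # saturated pair: argument of the log is non-positive -> ceiling 10
  far <- make_aln(c(a = paste(rep("A", 20), collapse = ""),
                    b = paste(rep("C", 20), collapse = "")))
  expect_equal(distance_matrix(far, "kimura")["a", "b"], 10)
})

test_that("distances use pairwise-ungapped columns only", {
  aln <- make_aln(c(a = "A-CD", b = "AG-D", c = "AGCD"))
  D <- distance_matrix(aln, "p")
  expect_equal(D["a", "b"], 0)           # only cols 1 and 4 comparable
  expect_equal(D["a", "c"], 0)
  disjoint <- make_aln(c(a = "AC--", b = "--GT"))
  expect_error(distance_matrix(disjoint, "p"), "a.*b|no comparable")
})

test_that("distance matrices are symmetric and permutation-equivariant", {
  aln <- rand_aln(6, 50, gap_prob = 0.1, seed = 31)
  D <- distance_matrix(aln, "kimura")
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  set.seed(1)
  perm <- sample(length(aln$ids))
  shuf <- labeled_alignment(aln$seqs[perm], ids = aln$ids[perm])
  D2 <- distance_matrix(shuf, "kimura")
  expect_equal(D2[aln$ids, aln$ids], D)
})

test_that("NJ solves the 3-taxon closed form", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the additive 4-taxon tree, verified by least squares", {
  taxa <- c("A", "B", "C", "D")
  D <- matrix(3, 4, 4, dimnames = list(taxa, taxa))
  D[cbind(taxa, taxa)] <- 0
  D["A", "B"] <- D["B", "A"] <- 2
  D["C", "D"] <- D["D", "C"] <- 2
  tr <- nj_tree(D)
  # topology AB|CD and exact path metric
  key <- gentscan:::split_key(c("A", "B"), taxa)
  expect_true(key %in% gentscan:::tree_split_keys(tr))
  expect_equal(ape::cophenetic.phylo(tr)[taxa, taxa], D)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
  # brute-force least squares over all three topologies picks the same one
  rss <- vapply(list(c("A", "B"), c("A", "C"), c("A", "D")),
                function(p) ls_rss_4taxon(D, p), numeric(1))
  expect_equal(which.min(rss), 1L)
  expect_equal(rss[1], 0, tolerance = 1e-20)
})

test_that("NJ reproduces path metrics of random trees up to 12 taxa", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:12, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
  }
})

test_that("a perfectly supported split gets support R", {
  aln <- perfect_split_aln(60)
  bs <- bootstrap_support(aln, R = 50, seed = 3, model = "p")
  key <- gentscan:::split_key(c("a", "b"), aln$ids)
  expect_equal(unname(bs$counts[key]), 50L)
  expect_equal(bs$R_used, 50L)
})

test_that("bootstrap is reproducible and bounded by R", {
  aln <- rand_aln(6, 40, gap_prob = 0.05, seed = 17)
  b1 <- bootstrap_support(aln, R = 25, seed = 11)
  b2 <- bootstrap_support(aln, R = 25, seed = 11)
  expect_identical(b1$counts, b2$counts)
  expect_true(all(b1$counts <= 25L))
  b3 <- bootstrap_support(aln, R = 1, seed = 5)
  expect_true(all(b3$counts %in% c(0L, 1L)))
})

test_that("majority-rule consensus keeps strict-majority, compatible splits", {
  aln <- perfect_split_aln(60)
  bs <- bootstrap_support(aln, R = 40, seed = 2, model = "p")
  cons <- consensus_tree(bs)
  expect_s3_class(cons, "phylo")
  expect_setequal(cons$tip.label, aln$ids)
  expect_true("40" %in% cons$node.label)

  # exactly R/2 is excluded: simulate tallies directly
  fake <- structure(list(counts = c("c,d" = 20L), R = 40L, R_used = 40L,
                         skipped = 0L, labels = aln$ids, model = "p",
                         seed = 1L), class = "bootstrap_tallies")
  cons2 <- consensus_tree(fake)
  expect_equal(cons2$Nnode, 1L)  # star: the 50% split is not a majority

  big <- rand_aln(8, 60, gap_prob = 0.05, seed = 23)
  bs2 <- bootstrap_support(big, R = 30, seed = 7)
  maj <- names(bs2$counts)[bs2$counts > bs2$R_used / 2]
  sides <- strsplit(maj, ",", fixed = TRUE)
  if (length(sides) > 1) {
    for (i in seq_along(sides)) for (j in seq_len(i - 1)) {
      expect_true(splits_compatible(sides[[i]], sides[[j]]))
    }
  }
  cons3 <- consensus_tree(bs2)
  expect_setequal(cons3$tip.label, big$ids)
})

test_that("groups with diagnostic columns are monophyletic with full support", {
  aln <- four_group_aln()
  bs <- bootstrap_support(aln, R = 30, seed = 9, model = "p")
  for (g in c("G1", "G2", "G3", "G4")) {
    cs <- group_clade_support(bs, aln, g)
    expect_true(cs$monophyletic, info = g)
    expect_equal(cs$support, 30L, info = g)
    expect_equal(cs$largest_pure_fraction, 1)
  }
})

test_that("degenerate and split groups report as specified", {
  aln <- four_group_aln()
  solo <- set_groups(aln, setNames(c("solo", rep("rest", 15)), aln$ids))
  bs <- bootstrap_support(solo, R = 10, seed = 1, model = "p")
  cs <- group_clade_support(bs, solo, "solo")
  expect_true(cs$monophyletic)
  expect_true(is.na(cs$support))

  # scatter one group across two clades
  mixed <- set_groups(aln, setNames(
    rep(c("GX", "GY", "GX", "GY"), each = 4), aln$ids))
  bs2 <- bootstrap_support(mixed, R = 20, seed = 4, model = "p")
  cs2 <- group_clade_support(bs2, mixed, "GX")
  expect_false(cs2$monophyletic)
  expect_lt(cs2$largest_pure_fraction, 1)
  expect_error(group_clade_support(bs2, mixed, "GZ"), "no sequences")
})
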