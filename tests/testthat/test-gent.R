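bg0 <- background_frequencies("uniform", pseudocount = 0)

test_that("background models normalize and validate", {
  expect_equal(unname(background_frequencies("uniform")$freqs),
               rep(0.05, 20))
  aln <- make_aln(c("AA", "AC"))
  bgA <- background_frequencies("alignment", aln)
  expect_equal(sum(bgA$freqs), 1)
  expect_true(all(bgA$freqs > 0))
  expect_gt(bgA$freqs[["A"]], bgA$freqs[["C"]])
  # unsmoothed pooled frequencies: A 3/4, C 1/4
  raw <- background_frequencies("alignment", aln, pseudocount = 1e-9)
  expect_equal(unname(raw$freqs[c("A", "C")]), c(0.75, 0.25),
               tolerance = 1e-6)
  expect_error(background_frequencies("alignment", make_aln(c("-", "-"))),
               "no residues")
})

test_that("conservation score has its analytic values", {
  inv <- column_profile(make_aln(c("G", "G", "G")), 1)
  expect_equal(conservation_score(inv, bg0, "kl"), log2(20))
  expect_equal(conservation_score(inv, bg0, "negentropy"), log2(20))

  half <- column_profile(make_aln(c("A", "A", "C", "C")), 1)
  expect_equal(conservation_score(half, bg0, "kl"), log2(10))

  # a column distribution equal to the background scores zero
  uni <- column_profile(make_aln(setNames(AA, paste0("s", 1:20))), 1)
  expect_equal(conservation_score(uni, bg0, "kl"), 0)
  expect_equal(conservation_score(uni, bg0, "negentropy"), 0)

  allgap <- column_profile(make_aln(c("-A", "-C")), 1)
  expect_equal(conservation_score(allgap, bg0, "kl"), 0)
})

test_that("scores match brute-force term-by-term sums on random profiles", {
  set.seed(7)
  for (i in 1:25) {
    cnt <- setNames(rpois(20, 2), AA)
    if (sum(cnt) == 0) cnt["A"] <- 1L
    aln <- make_aln(setNames(rep(AA, cnt), paste0("s", seq_len(sum(cnt)))))
    p <- column_profile(aln, 1)
    alpha <- sample(c(0, 0.05, 0.5), 1)
    bg <- background_frequencies("uniform", pseudocount = alpha)
    expect_equal(conservation_score(p, bg, "kl"),
                 kl_brute(cnt, rep(0.05, 20), alpha))
    expect_equal(conservation_score(p, bg, "negentropy"),
                 negentropy_brute(cnt, alpha))
  }
})

test_that("moving counts onto the modal residue never lowers the score", {
  base <- c("C", "D", "E", "F", "G", "H", "I", "K", "L", "M")
  for (method in c("kl", "negentropy")) {
    scores <- vapply(0:10, function(k) {
      seqs <- c(rep("A", 5 + k), base[seq_len(10 - k)])
      conservation_score(column_profile(make_aln(setNames(
        seqs, paste0("s", 1:15))), 1), bg0, method)
    }, numeric(1))
    expect_true(all(diff(scores) >= -1e-12), info = method)
  }
})

test_that("GE equals FE computed on the group-only sub-alignment", {
  out <- generate_alignment(small_spec())
  aln <- out$alignment
  g <- "B"
  scan <- gent_scan(aln, g)
  sub <- subset_alignment(aln, aln$ids[aln$groups == g])
  sub_scan <- gent_scan(set_groups(sub, setNames(rep("B", length(sub$ids)),
                                                 sub$ids)), "B")
  expect_equal(scan$GE, sub_scan$FE)
})

test_that("GE equals FE when group and family distributions coincide", {
  aln <- make_aln(c(a = "AC", b = "GT", c = "AC", d = "GT"),
                  groups = c(a = "G1", b = "G1", c = "G2", d = "G2"))
  scan <- gent_scan(aln, "G1", bg0)  # no pseudocount: depths differ
  expect_equal(scan$GE, scan$FE)
})

test_that("a planted group-specific column has maximal GE and lower FE", {
  aln <- make_aln(c(a = "R", b = "R", c = "F", d = "F", e = "F"),
                  groups = c(a = "GA", b = "GA", c = "GB", d = "GB",
                             e = "GB"))
  scan <- gent_scan(aln, "GA", bg0)
  expect_equal(scan$GE, log2(20))
  expect_lt(scan$FE, scan$GE)
  expect_equal(scan$highest_group_residue, "R")
  expect_equal(scan$common_GB, "F")
})

test_that("common residues follow the 0.25 within-group frequency rule", {
  # group GB at the column: F x2, Y x1, A x1 -> F (0.5) and Y? (0.25)
  aln <- make_aln(c(a = "R", b = "R", c = "F", d = "F", e = "Y", f = "A"),
                  groups = c(a = "GA", b = "GA", c = "GB", d = "GB",
                             e = "GB", f = "GB"))
  scan <- gent_scan(aln, "GA")
  expect_equal(scan$common_GB, "F,A,Y")  # all at >= 0.25; F first, ties abc
  strict <- gent_scan(aln, "GA", common_threshold = 0.4)
  expect_equal(strict$common_GB, "F")
})

test_that("ranking filters on FE then sorts by GE with index tie-break", {
  out <- generate_alignment(small_spec(seed = 8L))
  scan <- gent_scan(out$alignment, "A")
  ranked <- rank_group_specific(scan, top_n = 5)
  expect_lte(nrow(ranked), 5)
  expect_true(all(ranked$FE <= attr(ranked, "fe_cutoff")))
  expect_true(all(diff(ranked$GE) <= 1e-12))
  for (cls in split(ranked$col, ranked$GE)) {
    if (length(cls) > 1) expect_true(all(diff(cls) > 0))
  }
})

test_that("planted group-specific columns are returned exactly at zero noise", {
  out <- generate_alignment(small_spec())
  truth <- out$truth
  for (g in c("A", "B")) {
    cols <- truth$col[truth$archetype == "group_specific" &
                        truth$group == g]
    ranked <- rank_group_specific(gent_scan(out$alignment, g),
                                  top_n = length(cols))
    expect_setequal(ranked$col, cols)
  }
})

test_that("quadrant classification matches brute-force re-evaluation", {
  out <- generate_alignment(small_spec(seed = 13L))
  scan <- gent_scan(out$alignment, "C")
  ge_cut <- 2.5
  fe_cut <- 1.2
  quad <- quadrant_classify(scan, ge_cut, fe_cut)
  brute <- vapply(seq_len(nrow(scan)), function(i) {
    hi <- scan$GE[i] >= ge_cut
    lo <- scan$FE[i] < fe_cut
    if (hi && lo) "group_specific"
    else if (hi) "group_and_family"
    else if (!lo) "family_conserved"
    else "unconserved"
  }, character(1))
  expect_equal(as.character(quad), brute)
  expect_error(quadrant_classify(scan, -1, 1), "not TRUE")
})

test_that("quadrant extremes classify as stated", {
  aln <- make_aln(c(a = "RG", b = "RG", c = "FG", d = "FG"),
                  groups = c(a = "GA", b = "GA", c = "GB", d = "GB"))
  scan <- gent_scan(aln, "GA", bg0)
  quad <- quadrant_classify(scan, ge_cutoff = 2, fe_cutoff = 4)
  expect_equal(as.character(quad[1]), "group_specific")   # GA-only R
  expect_equal(as.character(quad[2]), "group_and_family") # invariant G
})

test_that("gent scan errors on undeclared or empty groups", {
  aln <- make_aln(c(a = "AR", b = "AG"), groups = c(a = "G1", b = "G1"))
  expect_error(gent_scan(aln, "G2"), "not declared")
})
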