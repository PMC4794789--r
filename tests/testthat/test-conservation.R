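test_that("column profiles count residues and gaps in scope", {
  aln <- make_aln(c("A", "A", "A", "-"))
  p <- column_profile(aln, 1)
  expect_equal(unname(p$counts["A"]), 3L)
  expect_equal(p$gap_count, 1L)
  expect_equal(p$n, 4L)
  expect_equal(sum(p$counts) + p$gap_count, p$n)
})

test_that("group scope restricts to the group and errors when empty", {
  aln <- make_aln(c(a = "AR", b = "AR", c = "GR"),
                  groups = c(a = "G1", b = "G1", c = "G2"))
  p <- column_profile(aln, 1, "G1")
  expect_equal(unname(p$counts["A"]), 2L)
  expect_equal(p$n, 2L)
  expect_error(column_profile(aln, 1, "G9"), "empty scope")

  one <- make_aln(c(a = "AG", b = "AG"), groups = c(a = "X", b = "X"))
  expect_equal(column_profile(one, 1, "X")$counts,
               column_profile(one, 1, "family")$counts)
})

test_that("conservation fraction takes the modal residue, ties alphabetical", {
  aln <- make_aln(c("A", "A", "A", "-"))
  cf <- conservation_fraction(column_profile(aln, 1))
  expect_equal(cf$modal_residue, "A")
  expect_equal(cf$fraction, 0.75)

  tie <- make_aln(c("S", "S", "T", "T"))
  cf <- conservation_fraction(column_profile(tie, 1))
  expect_equal(cf$modal_residue, "S")
  expect_equal(cf$fraction, 0.5)

  allgap <- make_aln(c("-A", "-A"))
  cf <- conservation_fraction(column_profile(allgap, 1))
  expect_true(is.na(cf$modal_residue))
  expect_equal(cf$fraction, 0)
})

test_that("fractions match a brute-force scan of random profiles", {
  set.seed(3)
  for (i in 1:20) {
    aln <- rand_aln(15, 10, gap_prob = 0.2, seed = i)
    col <- sample(10, 1)
    p <- column_profile(aln, col)
    cf <- conservation_fraction(p)
    cnt <- p$counts[AA]
    best <- max(cnt)
    expect_equal(cf$fraction, best / p$n)
    expect_equal(cf$modal_residue, sort(names(cnt)[cnt == best])[1])
  }
})

test_that("band thresholds are inclusive at the stated boundaries", {
  # fractions 1.0, 0.8, 0.6, 0.5 over 10 sequences
  cols <- c("AAAAAAAAAA", "CCCCCCCCDD", "EEEEEEFFFF", "GGGGGHHHHI")
  aln <- make_aln(vapply(1:10, function(i) {
    paste(substring(cols, i, i), collapse = "")
  }, character(1)))
  rec <- classify_columns(aln)
  expect_equal(as.character(rec$band),
               c("invariant", "band_80_99", "band_60_79", "below_60"))
  expect_equal(rec$fraction, c(1, 0.8, 0.6, 0.5))
})

test_that("band summary partitions the columns", {
  aln <- rand_aln(12, 40, gap_prob = 0.1, seed = 9)
  rec <- classify_columns(aln)
  bs <- band_summary(rec)
  expect_equal(sum(bs), aln$n_columns)
  expect_named(bs, c("invariant", "band_80_99", "band_60_79", "below_60"))
  empty <- band_summary(rec[0, ])
  expect_true(all(empty == 0L))
})

test_that("planted invariant columns are recovered exactly at zero noise", {
  out <- generate_alignment(small_spec(n_invariant = 10L, n_band80 = 0L,
                                       n_band60 = 0L,
                                       group_specific = integer(0),
                                       gap_blocks = list()))
  bs <- band_summary(classify_columns(out$alignment))
  expect_equal(unname(bs["invariant"]), 10L)
  expect_equal(sort(out$truth$col[out$truth$archetype == "invariant"]),
               classify_columns(out$alignment)$col[
                 classify_columns(out$alignment)$band == "invariant"])
})

test_that("group composition reports every group plus the family", {
  aln <- make_aln(c(a = "R", b = "R", c = "F", d = "F"),
                  groups = c(a = "GA", b = "GA", c = "GB", d = "GB"))
  comp <- group_composition(aln, 1)
  expect_setequal(comp$scope, c("GA", "GB", "family"))
  expect_equal(comp$modal_residue[comp$scope == "GA"], "R")
  expect_equal(comp$fraction[comp$scope == "GA"], 1)
  expect_equal(comp$modal_residue[comp$scope == "GB"], "F")
  profs <- attr(comp, "profiles")
  expect_equal(unname(profs$GA$counts["R"]), 2L)
})

test_that("gap-dominated group columns report their gap fraction", {
  aln <- make_aln(c(a = "Y", b = "Y", c = "-", d = "-"),
                  groups = c(a = "GA", b = "GA", c = "GB", d = "GB"))
  comp <- group_composition(aln, 1)
  expect_equal(comp$gap_fraction[comp$scope == "GB"], 1)
  expect_true(is.na(comp$modal_residue[comp$scope == "GB"]))
})

test_that("group profiles sum to the family profile at every column", {
  aln <- rand_aln(20, 15, gap_prob = 0.2, seed = 21)
  groups <- setNames(rep(c("G1", "G2", "unassigned"), c(8, 7, 5)), aln$ids)
  aln <- set_groups(aln, groups)
  for (col in seq_len(aln$n_columns)) {
    fam <- column_profile(aln, col, "family")
    parts <- lapply(c("G1", "G2", "unassigned"),
                    function(g) column_profile(aln, col, g))
    expect_equal(Reduce(`+`, lapply(parts, `[[`, "counts")), fam$counts)
    expect_equal(sum(vapply(parts, `[[`, numeric(1), "gap_count")),
                 fam$gap_count)
  }
})

test_that("column classification is invariant under row reordering", {
  aln <- rand_aln(10, 30, gap_prob = 0.15, seed = 4)
  set.seed(99)
  perm <- sample(length(aln$ids))
  shuf <- labeled_alignment(aln$seqs[perm], ids = aln$ids[perm])
  expect_equal(classify_columns(shuf)[c("fraction", "band")],
               classify_columns(aln)[c("fraction", "band")])
})
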