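test_that("p-distance counts mismatches over comparable sites", {
  expect_equal(p_distance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  # pairwise deletion: gap column dropped for the pair -> 1 mismatch / 3
  expect_equal(p_distance(c(a = "A-AA", b = "AAAT"))["a", "b"], 1 / 3)
  # complete deletion drops the gapped column for everyone
  d <- p_distance(c(a = "A-AA", b = "AAAT", c = "AAAA"), gap_mode = "complete")
  expect_equal(d["b", "c"], 1 / 3)
  expect_error(p_distance(c(a = "--AA", b = "TT--")), "no comparable sites")
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  tr <- nj_tree(d)
  phy <- tr$phylo
  # branch to taxon 1: (d12 + d13 - d23) / 2 = 0.1
  b1 <- phy$edge.length[phy$edge[, 2] == which(phy$tip.label == "t1")]
  expect_equal(b1, (0.2 + 0.4 - 0.4) / 2)
  b3 <- phy$edge.length[phy$edge[, 2] == which(phy$tip.label == "t3")]
  expect_equal(b3, (0.4 + 0.4 - 0.2) / 2)

  d2 <- d
  d2[1, 2] <- 0.3
  expect_error(nj_tree(d2), "not symmetric")
})

test_that("NJ recovers the generating quartet chosen by the four-point rule", {
  set.seed(50)
  for (rep in 1:40) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.1, 1))
    taxa <- paste0("t", 1:4)
    tr$tip.label <- sample(taxa)
    dm <- stats::cophenetic(tr)[taxa, taxa]
    want <- oracle_quartet(dm)
    got <- quartet_of_tree(nj_tree(dm)$phylo, taxa)
    expect_equal(got, want)
  }
})

test_that("NJ recovers random additive trees exactly (5-6 taxa)", {
  skip_if_not_installed("phangorn")
  set.seed(51)
  for (n in 5:6) {
    for (rep in 1:20) {
      tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
      dm <- stats::cophenetic(tr)
      rec <- nj_tree(dm)$phylo
      expect_equal(phangorn::RF.dist(ape::unroot(tr), rec), 0)
    }
  }
})

test_that("bootstrap supports are seeded, bounded and leaf-order invariant", {
  ca <- gen_clade_alignment(n_per_clade = 4, len = 80, n_diff = 25, seed = 7)
  aln <- ca$alignment

  b1 <- bootstrap_support(aln, B = 1, seed = 3)
  expect_true(all(b1$support %in% c(0, 100)))

  s1 <- bootstrap_support(aln, B = 50, seed = 9)
  s2 <- bootstrap_support(aln, B = 50, seed = 9)
  expect_identical(s1$support, s2$support)

  # reordering rows leaves the supported bipartitions unchanged
  perm <- sample(length(aln))
  aln_perm <- as_alignment(unclass(aln)[perm])
  s3 <- bootstrap_support(aln_perm, B = 50, seed = 9)
  A <- names(ca$clades)[ca$clades == "A"]
  expect_equal(split_support(s1, A), split_support(s3, A))
})

test_that("strongly divergent planted clades earn high split support", {
  ca <- gen_clade_alignment(n_per_clade = 6, len = 120, n_diff = 40, seed = 3)
  tb <- bootstrap_support(ca$alignment, B = 100, seed = 5)
  A <- names(ca$clades)[ca$clades == "A"]
  expect_gte(split_support(tb, A), 95)
})

test_that("clade composition reports monophyly and cover numbers", {
  # unrooted ((a1,a2),b1,(a3,b2)): A = {a1,a2,a3} is interleaved with the
  # b tips, splitting into two maximal pure subtrees {a1,a2} and {a3}
  phy <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,(a3:1,b2:1):1):1);")
  tree <- list(phylo = ape::unroot(phy), n_clamped = 0L, support = NULL)
  class(tree) <- "wrky_tree"
  labels <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  comp <- clade_composition(tree, labels, unions = list())
  expect_false(comp$monophyletic[comp$group == "A"])
  expect_equal(comp$cover_number[comp$group == "A"], 2L)
  expect_false(comp$monophyletic[comp$group == "B"])
  expect_equal(comp$cover_number[comp$group == "B"], 2L)

  # a clade on one edge side is monophyletic; a single leaf trivially so
  labels2 <- c(a1 = "A", a2 = "A", a3 = "C", b1 = "B", b2 = "B")
  comp2 <- clade_composition(tree, labels2, unions = list())
  expect_true(comp2$monophyletic[comp2$group == "A"])
  expect_true(comp2$monophyletic[comp2$group == "C"])

  expect_error(clade_composition(tree, labels[-1], unions = list()),
               "unlabelled")
})

test_that("label unions are evaluated when their members are present", {
  phy <- ape::read.tree(
    text = "(((d1:1,d2:1):1,(e1:1,e2:1):1):1,(x1:1,x2:1):1);")
  tree <- list(phylo = ape::unroot(phy), n_clamped = 0L, support = NULL)
  class(tree) <- "wrky_tree"
  labels <- c(d1 = "IId", d2 = "IId", e1 = "IIe", e2 = "IIe",
              x1 = "IIc", x2 = "IIc")
  comp <- clade_composition(tree, labels)
  expect_true("IId+e" %in% comp$group)
  expect_true(comp$monophyletic[comp$group == "IId+e"])
})

test_that("tidy and glance expose edges, supports and summaries", {
  ca <- gen_clade_alignment(n_per_clade = 4, len = 60, n_diff = 20, seed = 2)
  tb <- bootstrap_support(ca$alignment, B = 20, seed = 1)
  td <- tidy(tb)
  expect_true(all(c("parent", "node", "branch_length", "is_tip", "support")
                  %in% names(td)))
  expect_equal(sum(td$is_tip), 8L)
  expect_true(all(td$branch_length >= 0))
  gl <- glance(tb)
  expect_equal(gl$n_tips, 8L)
  expect_equal(gl$B, 20L)
  expect_true(gl$mean_support >= 0 && gl$mean_support <= 100)
})

test_that("negative NJ branch estimates are clamped and flagged", {
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  # perturb towards a negative internal estimate
  d["a", "b"] <- d["b", "a"] <- 0.1
  tr <- nj_tree(d)
  expect_true(all(tr$phylo$edge.length >= 0))
})

test_that("alignment objects validate shape and ids", {
  expect_error(as_alignment(c(a = "AA", b = "AA")), "at least 3")
  expect_error(as_alignment(c(a = "AA", b = "AAA", c = "AA")), "differ")
  expect_error(as_alignment(setNames(c("AA", "AA", "AA"), c("a", "a", "b"))),
               "duplicate")
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "AR-N", ">s2", "ARKN", ">s3", "ARKD"), f)
  aln <- read_alignment(f)
  expect_s3_class(aln, "wrky_alignment")
  expect_equal(nchar(aln[["s1"]]), 4L)
})

test_that("two-domain proteins contribute suffixed rows to the domain set", {
  set.seed(55)
  p <- gen_protein("Ia")
  prots <- tibble::tibble(protein_id = "w1", protein = p$protein)
  doms <- scan_wrky_domains(prots)
  ds <- domain_sequences(doms, prots)
  expect_setequal(ds$id, c("w1.N", "w1.C"))
  expect_equal(nchar(ds$seq),
               p$domains$zf_end - p$domains$hep_start + 1L)
})
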