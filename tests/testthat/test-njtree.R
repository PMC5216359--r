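test_that("three taxa resolve to the closed-form star", {
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_equal(ape::Ntip(tr), 3)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (2 + 4 - 6) / 2)
  expect_equal(lens[["B"]], (2 + 6 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 6 - 2) / 2)
})

test_that("a 4-taxon additive matrix is recovered exactly, with the
           least-squares enumeration as oracle", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  # oracle: least-squares fit of all three quartet topologies
  rss <- c(AB_CD = ls_fit_quartet(D, "A", "B", "C", "D"),
           AC_BD = ls_fit_quartet(D, "A", "C", "B", "D"),
           AD_BC = ls_fit_quartet(D, "A", "D", "B", "C"))
  expect_equal(names(which.min(rss)), "AB_CD")
  expect_equal(rss[["AB_CD"]], 0, tolerance = 1e-20)
  expect_true(monophyly_check(tr, data.frame(sample_id = LETTERS[1:4],
                                             species = c("x", "x", "y", "y"),
                                             group = "unknown"), "x"))
  # branch lengths are reproduced exactly (patristic = input)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)],
               D, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("NJ recovers random additive trees of 5-8 leaves exactly", {
  for (n in 5:8) {
    for (rep in 1:3) {
      gen <- random_additive(n, seed = 100 * n + rep)
      tr <- neighbor_joining(gen$D)
      expect_setequal(split_signatures(tr), split_signatures(gen$tree))
      # and the metric is reproduced
      cp <- as.matrix(ape::cophenetic.phylo(tr))
      expect_equal(cp[rownames(gen$D), colnames(gen$D)], gen$D,
                   tolerance = 1e-10, ignore_attr = TRUE)
      # independent implementation agrees on the topology
      expect_setequal(split_signatures(tr),
                      split_signatures(ape::nj(gen$D)))
    }
  }
})

test_that("undefined distances abort tree building with named pairs", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- NA
  expect_error(neighbor_joining(D), "a-b")
})

test_that("negative branch lengths are clamped and logged", {
  # strongly non-additive matrix forcing a negative NJ length
  D <- matrix(c(0, 1, 10, 10,
                1, 0, 10, 1,
                10, 10, 0, 1,
                10, 1, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "negative_deficit"), 0)
})

test_that("newick serialization round-trips splits and lengths", {
  gen <- random_additive(6, seed = 77)
  tr <- neighbor_joining(gen$D)
  txt <- to_newick(tr)
  expect_match(txt, ";$")
  back <- ape::read.tree(text = txt)
  expect_setequal(split_signatures(back), split_signatures(tr))
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-4)
})

test_that("bootstrap is deterministic under a fixed seed and bounded", {
  set.seed(5)
  base <- random_dna(90)
  div <- strsplit(base, "")[[1]]
  for (i in sample(90, 18)) div[i] <- setdiff(c("A", "C", "G", "T"),
                                              div[i])[1]
  div <- paste(div, collapse = "")
  aln <- alignment(c(a1 = base, a2 = base, a3 = base,
                     b1 = div, b2 = div, b3 = div))
  t1 <- bootstrap_support(aln, n_reps = 60, seed = 42)
  t2 <- bootstrap_support(aln, n_reps = 60, seed = 42)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.integer(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("a planted deep split earns full bootstrap support", {
  set.seed(6)
  base <- random_dna(100)
  div <- strsplit(base, "")[[1]]
  for (i in sample(100, 20)) div[i] <- setdiff(c("A", "C", "G", "T"),
                                               div[i])[1]
  div <- paste(div, collapse = "")
  aln <- alignment(c(a1 = base, a2 = base, a3 = base,
                     b1 = div, b2 = div, b3 = div))
  tr <- bootstrap_support(aln, n_reps = 80, seed = 1)
  tab <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                    species = rep(c("A", "B"), each = 3),
                    group = "unknown")
  expect_true(monophyly_check(tr, tab, "A"))
  # central split: every column resample preserves it
  members <- c("a1", "a2", "a3")
  pp <- ape::prop.part(tr)
  sup <- NA
  for (k in seq_along(pp)) {
    side <- tr$tip.label[pp[[k]]]
    if (setequal(side, members) || setequal(side, setdiff(tr$tip.label,
                                                          members))) {
      sup <- as.integer(tr$node.label[k])
    }
  }
  expect_equal(sup, 100)
})

test_that("monophyly checks singletons, clades and non-clades", {
  gen <- random_additive(6, seed = 12)
  tr <- gen$tree
  tab <- data.frame(sample_id = tr$tip.label,
                    species = c("solo", rep("grp", 2), rep("rest", 3)),
                    group = "unknown")
  expect_true(monophyly_check(tr, tab, "solo"))
  expect_error(monophyly_check(tr, tab, "absent"), "not present")
})
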