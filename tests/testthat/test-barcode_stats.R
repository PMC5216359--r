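test_that("K2P distance matches the closed form", {
  expect_equal(k2p_distance("ACGT", "ACGT")$distance, 0)
  a <- strrep("A", 10)
  b <- paste0("G", strrep("A", 9))  # 1 transition over 10 sites
  r <- k2p_distance(a, b)
  expect_equal(r$distance, -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(r$counts[c("n", "s", "v")], list(n = 10, s = 1, v = 0))
})

test_that("gaps and ambiguity codes are excluded pairwise", {
  r <- k2p_distance("AC-GTN", "ACCGTA")
  expect_equal(r$counts$n, 4)
  expect_equal(r$distance, 0)
})

test_that("saturation and empty overlap give markers, not errors", {
  r <- k2p_distance("------", "ACGTAC")
  expect_true(is.na(r$distance))
  expect_equal(r$counts$reason, "no comparable sites")
  # all-transversion pair: 1 - 2Q <= 0
  r2 <- k2p_distance("AAAA", "CCCC")
  expect_true(is.na(r2$distance))
  expect_equal(r2$counts$reason, "saturated")
})

test_that("distance_matrix agrees with an independent K2P oracle", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- setNames(vapply(1:6, function(i) {
      random_dna(80, c("A", "C", "G", "T", "A", "C", "G", "T", "-", "N"))
    }, character(1)), paste0("s", 1:6))
    D <- distance_matrix(alignment(seqs))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(D[i, j], oracle_k2p(seqs[[i]], seqs[[j]]),
                   tolerance = 1e-12)
    }
    expect_true(isSymmetric(unclass(D)[,]))
    expect_equal(unname(diag(D)), rep(0, 6))
  }
})

test_that("distance_matrix agrees with ape's K80 implementation", {
  set.seed(7)
  base <- strsplit(random_dna(200), "")[[1]]
  seqs <- vapply(1:8, function(i) {
    x <- base
    idx <- sample(200, 12)
    for (p in idx) x[p] <- sample(c("A", "C", "G", "T"), 1)
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:8)
  D <- distance_matrix(alignment(seqs))
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  Dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(unclass(D)[,], Dape[rownames(D), colnames(D)],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("K2P dominates the p-distance and is monotone in P", {
  set.seed(9)
  for (i in 1:20) {
    a <- random_dna(100); b <- random_dna(100)
    r <- k2p_distance(a, b)
    if (is.na(r$distance)) next
    p <- (r$counts$s + r$counts$v) / r$counts$n
    expect_gte(r$distance, p)
    if (p > 0) expect_gt(r$distance, p)
  }
  # monotone in P at fixed Q on a grid
  Q <- 0.1
  ds <- vapply(seq(0, 0.3, by = 0.02), function(P) {
    -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("complete deletion removes every gapped/ambiguous column", {
  seqs <- c(a = "ACGTAC", b = "AC-TAC", c = "ACGTNC")
  Dp <- distance_matrix(alignment(seqs), deletion = "pairwise")
  Dc <- distance_matrix(alignment(seqs), deletion = "complete")
  expect_equal(attr(Dp, "n")["a", "b"], 5)
  expect_true(all(attr(Dc, "n")[upper.tri(Dc)] == 4))
})

test_that("haplotype collapsing partitions by exact aligned identity", {
  a <- alignment(c(s1 = "AC", s2 = "AC", s3 = "AT", s4 = "GG"))
  h <- collapse_haplotypes(a)
  expect_equal(h$haplotype, c("H1", "H2", "H3"))
  expect_equal(h$n_members, c(2, 1, 1))
  expect_equal(h$members[1], "s1,s2")

  ident <- alignment(c(x = "AAA", y = "AAA", z = "AAA"))
  expect_equal(nrow(collapse_haplotypes(ident)), 1)

  # gap columns distinguish haplotypes (an indel haplotype is its own)
  g <- alignment(c(p = "A-C", q = "AGC"))
  expect_equal(nrow(collapse_haplotypes(g)), 2)
})

test_that("haplotype classes equal a brute-force equality partition", {
  set.seed(13)
  for (rep in 1:10) {
    seqs <- setNames(vapply(1:8, function(i) {
      random_dna(6, c("A", "C", "-"))
    }, character(1)), paste0("q", 1:8))
    h <- collapse_haplotypes(alignment(seqs))
    expect_equal(nrow(h), length(unique(seqs)))
    expect_equal(sum(h$n_members), 8)
  }
})

test_that("variable_sites finds exactly the polymorphic columns", {
  expect_length(variable_sites(alignment(c(a = "ACGT", b = "ACGT"))), 0)
  expect_equal(variable_sites(alignment(c(a = "ACGT", b = "ACCT"))), 3)
  # gap counts as a state
  expect_equal(variable_sites(alignment(c(a = "AC-T", b = "ACGT"))), 3)
})

test_that("species summaries aggregate the right pair sets", {
  lib <- tiny_library()
  D <- distance_matrix(lib$aln)
  intra <- species_summary(D, lib$table, "sp_t")
  expect_equal(intra$n_pairs, 1)
  expect_equal(intra$mean, 0)
  inter <- species_summary(D, lib$table, "sp_t", "sp_c")
  expect_equal(inter$n_pairs, 4)
  expect_equal(inter$min, inter$max)

  single <- data.frame(sample_id = c("t1", "c1"),
                       species = c("solo", "other"),
                       group = c("target", "congener"))
  s <- species_summary(D[c("t1", "c1"), c("t1", "c1")], single, "solo")
  expect_equal(s$n_pairs, 0)
  expect_true(is.na(s$mean))
})

test_that("a fixed difference between tight species yields a barcode gap", {
  lib <- tiny_library()
  D <- distance_matrix(lib$aln)
  g <- barcode_gap(D, lib$table, "sp_t", scope = "congener")
  expect_true(g$gap_present)
  expect_equal(g$max_intra, 0)
  expect_gt(g$min_inter, 0)
  expect_error(barcode_gap(D, lib$table, "sp_t", scope = "adulterant"),
               "empty comparison scope")
})

test_that("distance matrix exports round-trip through both formats", {
  lib <- tiny_library()
  D <- distance_matrix(lib$aln)
  f1 <- withr::local_tempfile(fileext = ".phy")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, f1, "phylip")
  expect_equal(as.integer(trimws(readLines(f1)[1])), 4)
  write_distance_matrix(D, f2, "tsv")
  long <- read.delim(f2)
  expect_equal(nrow(long), 6)
  expect_named(long, c("id_a", "id_b", "d", "n", "s", "v"))
})
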