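# Shared toy constructs. Backgrounds avoid G entirely, so the Bgl I
# motif (which needs GCC and GGC) can only occur where it is planted.
bgl <- default_enzymes()$BglI

bg_actc <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
}

FWD_TOY <- "ATTACCATTACCATTACCAT"          # 20 nt, G-free
REVFOOT_TOY <- "AACCTTAACCTTAACCTTA"       # 19 nt footprint, G-free
MOTIF_TOY <- "GCCTTTTTGGC"                 # concrete Bgl I site

# template whose product is exactly 292 bp with one site cut after 168
toy_template_292 <- function(with_site = TRUE) {
  x <- bg_actc(340, seed = 101)
  substr(x, 21, 40) <- FWD_TOY
  if (with_site) substr(x, 182, 192) <- MOTIF_TOY
  substr(x, 294, 312) <- REVFOOT_TOY
  x
}
toy_fwd <- primer("F-toy", FWD_TOY, "forward")
toy_rev <- primer("R-toy", reverse_complement(REVFOOT_TOY), "reverse")

test_that("motif scanning honours IUPAC semantics and strands", {
  expect_equal(nrow(find_motif_sites("AAAAAAAAAAAAA", bgl)), 0)
  hits <- find_motif_sites("GCCAAAAAGGC", bgl)
  expect_equal(hits$start, 1)
  expect_equal(hits$strand, "+")
  # ambiguous template bases never match (a cut must be certain)
  expect_equal(nrow(find_motif_sites("GCCAAAAAGGN", bgl)), 0)
  expect_error(find_motif_sites("GCC-AAAAGGC", bgl), "gapped")
})

test_that("motif scanner equals a regex oracle, incl. strand symmetry", {
  set.seed(51)
  for (rep in 1:60) {
    x <- paste0(random_dna(25), "GCC", random_dna(5), "GGC",
                random_dna(25))
    got <- find_motif_sites(x, bgl)$start
    expect_equal(sort(got), oracle_motif(x, bgl$motif))
    # hits on the reverse complement mirror the plus-strand hits
    rc_hits <- find_motif_sites(reverse_complement(x), bgl)$start
    expect_equal(sort(nchar(x) - (rc_hits + 10) + 1), sort(got))
  }
})

test_that("digestion reproduces the planted 168+124 fragment pattern", {
  amps <- in_silico_pcr(toy_template_292(), toy_fwd, toy_rev)
  expect_length(amps, 1)
  expect_equal(amps[[1]]$length, 292)
  d <- digest(amps[[1]], bgl)
  expect_equal(d$fragments, c(168, 124))
  # no site: one full-length fragment
  amps0 <- in_silico_pcr(toy_template_292(FALSE), toy_fwd, toy_rev)
  expect_equal(digest(amps0[[1]], bgl)$fragments, 292)
})

test_that("fragments always sum to the product length", {
  set.seed(52)
  for (rep in 1:40) {
    n_sites <- sample(0:3, 1)
    x <- bg_actc(60, seed = 500 + rep)
    for (k in seq_len(n_sites)) {
      x <- paste0(x, MOTIF_TOY, bg_actc(40, seed = 900 + 10 * rep + k))
    }
    d <- digest(x, bgl)
    expect_equal(sum(d$fragments), nchar(x))
    expect_equal(length(d$fragments), length(d$cuts) + 1)
    expect_true(all(d$fragments >= 1))
  }
})

test_that("primer binding applies the mismatch budget and 3' clamp", {
  tpl <- toy_template_292()
  b <- find_primer_sites(tpl, toy_fwd)
  expect_equal(b$start, 21)
  expect_equal(b$mismatches, 0)

  # a single mismatch at primer base 13 still binds, clamp intact
  p13 <- strsplit(FWD_TOY, "")[[1]]
  p13[13] <- "G"
  b13 <- find_primer_sites(tpl, primer("F13", paste(p13, collapse = ""),
                                       "forward"))
  expect_equal(b13$mismatches, 1)
  expect_true(b13$three_prime_clamp_ok)

  # a 3'-terminal mismatch kills the binding even within budget
  pclamp <- strsplit(FWD_TOY, "")[[1]]
  pclamp[20] <- "G"
  expect_equal(nrow(find_primer_sites(tpl, primer("Fc",
    paste(pclamp, collapse = ""), "forward"))), 0)

  # primer longer than the template: no sites
  expect_equal(nrow(find_primer_sites("ACGTACGTAC", toy_fwd)), 0)
})

test_that("in-silico PCR requires both footprints and overwrites primers", {
  # no reverse footprint: no amplification
  x <- bg_actc(200, seed = 61)
  substr(x, 11, 30) <- FWD_TOY
  expect_length(in_silico_pcr(x, toy_fwd, toy_rev), 0)

  amps <- in_silico_pcr(toy_template_292(), toy_fwd, toy_rev)
  p <- amps[[1]]$product
  expect_identical(substr(p, 1, 20), FWD_TOY)
  expect_identical(substr(p, 292 - 18, 292),
                   reverse_complement(toy_rev$sequence))
})

test_that("an engineered primer's product loses the footprint site", {
  # template carries a Bgl I site inside the reverse footprint
  x <- bg_actc(340, seed = 62)
  substr(x, 21, 40) <- FWD_TOY
  foot <- paste0("AACCTTA", MOTIF_TOY, "T")  # 19 nt with embedded site
  substr(x, 294, 312) <- foot
  rev_nat <- primer("Rn", reverse_complement(foot), "reverse")
  amps <- in_silico_pcr(x, toy_fwd, rev_nat)
  expect_equal(nrow(find_motif_sites(amps[[1]]$product, bgl)), 1)

  props <- engineer_primer(c(tpl = x), c(294, 312), bgl, budget = 1,
                           fwd = toy_fwd)
  expect_gt(length(props), 0)
  expect_equal(props[[1]]$n_subs, 1)
  # closed loop: rerun PCR + digestion with every proposal
  for (pr in props) {
    a2 <- in_silico_pcr(x, toy_fwd, pr$primer)
    expect_length(a2, 1)
    expect_equal(nrow(find_motif_sites(a2[[1]]$product, bgl)), 0)
    expect_equal(digest(a2[[1]], bgl)$fragments, a2[[1]]$length)
  }
})

test_that("a footprint-free primer is returned unchanged", {
  x <- toy_template_292(FALSE)
  props <- engineer_primer(c(tpl = x), c(294, 312), bgl, budget = 1,
                           fwd = toy_fwd)
  expect_length(props, 1)
  expect_equal(props[[1]]$n_subs, 0)
  expect_identical(props[[1]]$primer$sequence, toy_rev$sequence)
})

test_that("a site destroyable only inside the clamp is reported, not forced", {
  # the site's only in-footprint fixed bases sit under the 3' clamp of
  # the reverse primer (the left edge of the footprint)
  x <- bg_actc(340, seed = 63)
  substr(x, 21, 40) <- FWD_TOY
  substr(x, 286, 296) <- MOTIF_TOY      # GGC part lands at 294..296
  substr(x, 297, 312) <- substr(REVFOOT_TOY, 4, 19)
  props <- engineer_primer(c(tpl = x), c(294, 312), bgl, budget = 1,
                           fwd = toy_fwd)
  expect_length(props, 0)
  tally <- attr(props, "failure_tally")
  expect_gt(tally[["clamp_mismatch"]], 0)
})

test_that("differential digestion reproduces the planted readout", {
  target <- toy_template_292()
  congener <- toy_template_292(FALSE)
  adulterant <- bg_actc(340, seed = 64)  # no footprints at all
  tpls <- c(t1 = target, t2 = target, c1 = congener, a1 = adulterant)
  tab <- data.frame(sample_id = names(tpls),
                    species = c("tgt", "tgt", "oth", "adu"),
                    group = c("target", "target", "congener",
                              "adulterant"))
  des <- differential_digestion(tpls, tab, toy_fwd, toy_rev, bgl, "tgt")
  expect_true(des$discriminates)
  ps <- des$per_species
  expect_true(ps$amplifies[ps$species == "tgt"] &&
              ps$cut[ps$species == "tgt"])
  expect_identical(ps$fragments[ps$species == "tgt"], "168+124")
  expect_true(ps$amplifies[ps$species == "oth"] &&
              !ps$cut[ps$species == "oth"])
  expect_false(ps$amplifies[ps$species == "adu"])

  expect_error(differential_digestion(tpls[1:2], tab[1:2, ], toy_fwd,
                                      toy_rev, bgl, "tgt"),
               ">= 2 species")
  lines <- capture.output(gel_schematic(des))
  expect_true(any(grepl("168\\+124", lines)))
})

test_that("discordant within-species outcomes are flagged ambiguous", {
  tpls <- c(t1 = toy_template_292(), t2 = toy_template_292(FALSE),
            c1 = toy_template_292(FALSE))
  tab <- data.frame(sample_id = names(tpls),
                    species = c("tgt", "tgt", "oth"),
                    group = c("target", "target", "congener"))
  expect_warning(des <- differential_digestion(tpls, tab, toy_fwd,
                                               toy_rev, bgl, "tgt"),
                 "discordant.*tgt")
  expect_true(des$per_species$ambiguous[des$per_species$species == "tgt"])
})

test_that("select_assay ranks a clean target-only design first", {
  tgt <- toy_template_292()
  oth <- toy_template_292(FALSE)
  tpls <- c(t1 = tgt, t2 = tgt, o1 = oth, o2 = oth)
  tab <- data.frame(sample_id = names(tpls),
                    species = c("tgt", "tgt", "oth", "oth"),
                    group = c("target", "target", "congener", "congener"))
  aln <- alignment(tpls)  # templates are equal length and gap-free
  designs <- select_assay(tpls, aln, tab, "tgt",
                          enzymes = default_enzymes(), fwd = toy_fwd,
                          rev_footprints = list(c(294, 312)))
  expect_gt(length(designs), 0)
  expect_equal(designs[[1]]$engineering$n_subs, 0)
  expect_true(designs[[1]]$discriminates)
})

test_that("select_assay reports a diagnosis when no enzyme applies", {
  tgt <- toy_template_292(FALSE)          # no site anywhere
  oth <- toy_template_292(FALSE)
  oth2 <- sub("^.", "T", oth)             # trivial difference
  tpls <- c(t1 = tgt, o1 = oth2)
  tab <- data.frame(sample_id = names(tpls), species = c("tgt", "oth"),
                    group = c("target", "congener"))
  # give the target a diagnostic state so mining succeeds
  tpls[["t1"]] <- sub("^.", "G", tpls[["t1"]])
  aln <- alignment(tpls)
  designs <- select_assay(tpls, aln, tab, "tgt",
                          enzymes = default_enzymes(), fwd = toy_fwd,
                          rev_footprints = list(c(294, 312)))
  expect_length(designs, 0)
  expect_match(attr(designs, "diagnosis"), "no motif hit", all = FALSE)
})

test_that("enzyme and primer constructors validate their inputs", {
  expect_error(enzyme("X", "GCQC", 2), "non-IUPAC")
  expect_error(enzyme("X", "GCGC", 5), "within the motif")
  expect_error(primer("p", "ACGTACGT", "forward"), ">= 10")
  expect_error(primer("p", "ACGTNACGTA", "forward"), "unambiguous")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tmotif\tcut_offset", "BglI\tGCCNNNNNGGC\t7"), f)
  ez <- read_enzymes(f)
  expect_equal(ez$BglI$cut_offset, 7L)
  writeLines(c("name\tsequence\trole", "F\tATTACCATTACCATTACCAT\tforward"),
             f)
  pr <- read_primers(f)
  expect_equal(pr$F$role, "forward")
})
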