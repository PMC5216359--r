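test_that("identity percent follows the free-end-gap alignment rules", {
  s <- substr(strrep("ACGT", 53), 1, 211)
  expect_equal(identity_percent(s, s), 100)
  s2 <- paste0("T", substr(s, 2, 211))  # one substitution over 211 cols
  expect_equal(identity_percent(s, s2), 99.5)
  expect_equal(identity_percent("AAAAAAAA", "TTTTTTTT"), 0)
  # terminal overhangs are excluded from the column count
  expect_equal(identity_percent(paste0("GGGGGGG", s), s), 100)
  expect_error(identity_percent("", "ACGT"), "empty")
})

test_that("identification picks the nearest species and keeps ties", {
  set.seed(70)
  base <- random_dna(40)
  far <- paste0(substr(base, 1, 30), random_dna(10))
  lib <- c(a1 = base, a2 = base, b1 = far)
  tab <- data.frame(sample_id = names(lib),
                    species = c("spA", "spA", "spB"),
                    group = c("target", "target", "congener"))
  hit <- identify(lib[["a1"]], lib, tab)
  expect_equal(hit$top_species, "spA")
  expect_equal(hit$top_identity, 100)

  # query equidistant from two species' identical references: tie kept
  lib2 <- c(x1 = "ACGTACGTACGTACGTACGT", y1 = "ACGTACGTACGTACGTACGT")
  tab2 <- data.frame(sample_id = names(lib2), species = c("spX", "spY"),
                     group = "congener")
  q <- paste0("T", substr(lib2[[1]], 2, 20))
  tie <- identify(q, lib2, tab2)
  expect_setequal(tie$top_species, c("spX", "spY"))
})

test_that("the k-mer prefilter never changes the identification", {
  set.seed(71)
  lib <- simulate_library(small_syn_config())
  exhaustive <- function(q) {
    ident <- vapply(lib$records, function(r) identity_percent(q, r),
                    numeric(1))
    sp <- lib$table$species[match(names(lib$records),
                                  lib$table$sample_id)]
    best <- vapply(split(ident, sp), max, numeric(1))
    top <- max(best)
    sort(names(best)[best == top])
  }
  prods <- simulate_products(lib, seed = 5)
  for (id in names(prods$records)[1:6]) {
    q <- prods$records[[id]]
    got <- identify(q, lib$records, lib$table)
    expect_setequal(got$top_species, exhaustive(q))
  }
  # a query sharing no k-mer with any reference falls back gracefully
  weird <- strrep("AT", 30)
  expect_s3_class(identify(weird, lib$records, lib$table),
                  "identification")
})

test_that("assay outcomes map to (+,+) / (+,-) / (-,N/A)", {
  lib <- simulate_library(small_syn_config())
  des <- select_assay(lib$records, lib$truth$alignment_barcode,
                      lib$table, "target",
                      enzymes = default_enzymes(), fwd = lib$truth$fwd,
                      rev_footprints =
                        list(lib$truth$rev_footprint_target_template),
                      aln_offset = lib$config$flank_length)[[1]]
  expect_equal(unname(predict_assay(lib$records[["target_s01"]], des)),
               c("+", "+"))
  expect_equal(unname(predict_assay(lib$records[["congener_01_s01"]],
                                    des)), c("+", "-"))
  expect_equal(unname(predict_assay(lib$records[["adulterant_01_s01"]],
                                    des)), c("-", "N/A"))
})

test_that("batch reports aggregate products, mixtures and composition", {
  lib <- simulate_library(small_syn_config())
  comp <- c(target = 2L, congener_01 = 2L, adulterant_01 = 1L,
            "adulterant_01+adulterant_02" = 1L)
  prods <- simulate_products(lib, composition = comp, seed = 9)
  rep <- batch_report(prods$records, lib$records, lib$table,
                      product_ids = setNames(prods$products$product_id,
                                             prods$products$record_id),
                      target = "target")
  expect_equal(length(unique(rep$product_id)), 6)
  truth <- setNames(prods$products$true_species, prods$products$record_id)
  expect_identical(rep$identified, unname(truth[rep$record_id]))
  # the mixed product contributes one row per component, flagged
  mixed <- rep[rep$mixture, ]
  expect_equal(nrow(mixed), 2)
  expect_equal(length(unique(mixed$product_id)), 1)
  comp_tab <- attr(rep, "composition")
  expect_equal(comp_tab$count[comp_tab$species == "target"], 2)
  expect_equal(comp_tab$count[comp_tab$species == "congener_01"], 2)

  empty <- batch_report(character(0), lib$records, lib$table)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(attr(empty, "composition")), 0)
})

test_that("final calls respect thresholds and diagnostic confirmation", {
  lib <- simulate_library(small_syn_config())
  sites <- diagnostic_sites(lib$truth$alignment_barcode, lib$table,
                            "target")
  q <- lib$records[["target_s02"]]
  rep <- batch_report(c(Q = q), lib$records, lib$table, sites = sites,
                      aln = lib$truth$alignment_barcode, target = "target")
  expect_equal(rep$final_call, "target")
  expect_equal(rep$diagnostics, "match")
  # without diagnostic confirmation the call retreats to genus level
  q_broken <- q
  pos <- lib$truth$diagnostic$master_col[2] - 1  # snp position, ungapped
  substr(q_broken, pos, pos) <- "T"
  rep2 <- batch_report(c(Q = q_broken), lib$records, lib$table,
                       sites = sites, aln = lib$truth$alignment_barcode,
                       target = "target")
  if (rep2$identified == "target") {
    expect_equal(rep2$final_call, "target sp.")
  }
})
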