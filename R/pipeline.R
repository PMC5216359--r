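# Pipeline drivers orchestrating the analysis stages. Each run
# validates its inputs, writes its outputs (TSV/JSON/Newick) under an
# output directory and records a manifest echoing the effective
# configuration, so any run is reproducible from its manifest.

write_manifest <- function(out_dir, stage, cfg) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg$stage <- stage
  cfg$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(cfg, file.path(out_dir, paste0(stage,
                                                      "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

check_ids <- function(aln, table) {
  orphans <- setdiff(aln$ids, table$sample_id)
  if (length(orphans)) {
    stop("sequence id(s) missing from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Library statistics stage
#'
#' Per-species sequence-length range, mean GC content, variable-site
#' and haplotype counts, plus intraspecific and target-vs-scope
#' distance summaries and barcode-gap reports.
#'
#' @param aln Library [alignment()].
#' @param table Sample metadata data.frame.
#' @param target Target species label.
#' @param out_dir Output directory (created if needed).
#' @param deletion Gap-handling mode for [distance_matrix()].
#' @return List with `species_stats`, `distance_summaries`, `gaps` and
#'   the distance matrix `D` (invisibly written to `out_dir`).
#' @export
run_stats <- function(aln, table, target, out_dir = tempfile("stats"),
                      deletion = "pairwise") {
  stopifnot(inherits(aln, "dna_alignment"))
  validate_metadata(table)
  if (!nrow(table)) stop("empty metadata", call. = FALSE)
  check_ids(aln, table)

  sp_rows <- lapply(unique(table$species), function(sp) {
    ids <- intersect(table$sample_id[table$species == sp], aln$ids)
    lens <- nchar(degap(aln$seqs[ids]))
    gc <- mean(vapply(degap(aln$seqs[ids]), gc_content, numeric(1)))
    vs <- if (length(ids) >= 2) length(variable_sites(aln, ids))
          else NA_integer_
    hap <- nrow(collapse_haplotypes(aln, ids))
    data.frame(species = sp, n_samples = length(ids),
               length_min = min(lens), length_max = max(lens),
               mean_gc = round(gc, 3), variable_sites = vs,
               haplotypes = hap, stringsAsFactors = FALSE)
  })
  species_stats <- do.call(rbind, sp_rows)

  D <- distance_matrix(aln, deletion = deletion)
  scopes <- list(
    intra = target,
    congener = unique(table$species[table$group == "congener"]),
    adulterant = unique(table$species[table$group == "adulterant"]))
  summaries <- lapply(names(scopes), function(nm) {
    sc <- scopes[[nm]]
    if (!length(sc)) return(NULL)
    s <- species_summary(D, table, target, sc)
    data.frame(comparison = nm, min = s$min, max = s$max, mean = s$mean,
               n_pairs = s$n_pairs, stringsAsFactors = FALSE)
  })
  distance_summaries <- do.call(rbind, summaries)

  gaps <- lapply(c("congener", "adulterant"), function(sc) {
    if (!any(table$group == sc)) return(NULL)
    g <- barcode_gap(D, table, target, scope = sc)
    data.frame(scope = sc, max_intra = g$max_intra,
               min_inter = g$min_inter, gap_present = g$gap_present,
               stringsAsFactors = FALSE)
  })
  gaps <- do.call(rbind, gaps)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write.table(species_stats, file.path(out_dir, "species_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(distance_summaries,
              file.path(out_dir, "distance_summaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_matrix(D, file.path(out_dir, "distances.tsv"), "tsv")
  write_manifest(out_dir, "stats",
                 list(target = target, deletion = deletion,
                      n_sequences = length(aln$ids)))
  invisible(list(species_stats = species_stats,
                 distance_summaries = distance_summaries, gaps = gaps,
                 D = D, out_dir = out_dir))
}

#' Tree stage: NJ with bootstrap and per-species monophyly
#'
#' @param aln Library [alignment()] (>= 3 records).
#' @param table Sample metadata data.frame.
#' @param out_dir Output directory.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Random seed (default 1).
#' @param deletion Gap-handling mode.
#' @return List with `tree` (supports as node labels), `monophyly`
#'   data.frame and the Newick path.
#' @export
run_tree <- function(aln, table, out_dir = tempfile("tree"),
                     n_reps = 1000, seed = 1, deletion = "pairwise") {
  stopifnot(inherits(aln, "dna_alignment"))
  if (length(aln$ids) < 3L) stop(">= 3 sequences required", call. = FALSE)
  validate_metadata(table)
  check_ids(aln, table)
  tree <- bootstrap_support(aln, n_reps = n_reps, seed = seed,
                            deletion = deletion)
  mono <- do.call(rbind, lapply(unique(table$species), function(sp) {
    if (!any(table$sample_id[table$species == sp] %in% tree$tip.label)) {
      return(NULL)
    }
    data.frame(species = sp,
               monophyletic = monophyly_check(tree, table, sp),
               stringsAsFactors = FALSE)
  }))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nwk_path <- file.path(out_dir, "nj_tree.nwk")
  writeLines(to_newick(tree), nwk_path)
  write.table(mono, file.path(out_dir, "monophyly.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "tree",
                 list(n_reps = n_reps, seed = seed, deletion = deletion))
  invisible(list(tree = tree, monophyly = mono, newick = nwk_path,
                 out_dir = out_dir))
}

#' Assay-design stage
#'
#' Mines diagnostic sites, then searches enzymes x reverse-primer
#' footprints for a discriminating PCR-RFLP design, engineering the
#' reverse primer where a confounding restriction site spoils the
#' readout. The result status distinguishes `"clean"`,
#' `"engineered"` and `"none"`.
#'
#' @param templates Named ungapped full templates.
#' @param aln Library [alignment()] for diagnostic mining.
#' @param table Sample metadata data.frame.
#' @param target Target species label.
#' @param fwd Forward [primer()].
#' @param rev_footprints List of candidate reverse footprints
#'   (intervals on the reference target template).
#' @param enzymes Named list of [enzyme()]s
#'   (default [default_enzymes()]).
#' @param aln_offset Template position of alignment column 1 minus 1.
#' @param out_dir Output directory.
#' @param ... Constraints forwarded to [select_assay()].
#' @return List with `designs` (ranked), `sites`, `status`.
#' @export
run_design <- function(templates, aln, table, target, fwd, rev_footprints,
                       enzymes = default_enzymes(), aln_offset = 0,
                       out_dir = tempfile("design"), ...) {
  validate_metadata(table)
  sites <- diagnostic_sites(aln, table, target)
  designs <- select_assay(templates, aln, table, target, enzymes, fwd,
                          rev_footprints, aln_offset = aln_offset, ...)
  status <- if (!length(designs)) "none"
            else if (designs[[1]]$engineering$n_subs == 0L) "clean"
            else "engineered"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_diagnostics(sites, file.path(out_dir, "diagnostic_sites.tsv"))
  if (length(designs)) {
    best <- designs[[1]]
    jsonlite::write_json(
      list(fwd = best$fwd[c("name", "sequence")],
           rev = best$rev[c("name", "sequence")],
           enzyme = best$enzyme[c("name", "motif", "cut_offset")],
           engineering = best$engineering,
           per_species = best$per_species,
           discriminates = best$discriminates),
      file.path(out_dir, "assay_design.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    jsonlite::write_json(list(status = "none",
                              diagnosis = attr(designs, "diagnosis")),
                         file.path(out_dir, "assay_design.json"),
                         auto_unbox = TRUE)
  }
  write_manifest(out_dir, "design", list(target = target, status = status))
  invisible(list(designs = designs, sites = sites, status = status,
                 out_dir = out_dir))
}

#' Identification stage: authenticate query products
#'
#' @param queries Named ungapped query sequences.
#' @param library Named reference sequences.
#' @param table Library metadata data.frame.
#' @param target Target species label.
#' @param product_ids Record-to-product map (default: identity).
#' @param design Optional `assay_design`.
#' @param sites,aln Optional diagnostic sites and the alignment frame
#'   they refer to.
#' @param out_dir Output directory.
#' @return List with `report` and `composition`.
#' @export
run_identify <- function(queries, library, table, target,
                         product_ids = setNames(names(queries),
                                                names(queries)),
                         design = NULL, sites = NULL, aln = NULL,
                         out_dir = tempfile("identify")) {
  validate_metadata(table)
  report <- batch_report(queries, library, table,
                         product_ids = product_ids, design = design,
                         sites = sites, aln = aln, target = target)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_report(report, file.path(out_dir, "authentication"))
  write_manifest(out_dir, "identify",
                 list(target = target, n_queries = length(queries),
                      n_products = length(unique(product_ids))))
  invisible(list(report = report,
                 composition = attr(report, "composition"),
                 out_dir = out_dir))
}

#' Simulation stage: write a synthetic library and query set to disk
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory.
#' @param products_seed Seed for the query-set draw.
#' @return List with the library and products objects and file paths.
#' @export
run_simulate <- function(cfg = synthetic_config(),
                         out_dir = tempfile("simulate"),
                         products_seed = cfg$seed + 1) {
  lib <- simulate_library(cfg)
  prods <- simulate_products(lib, seed = products_seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_fasta(lib$records, file.path(out_dir, "library.fasta"))
  write.table(lib$table, file.path(out_dir, "library_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(prods$records, file.path(out_dir, "queries.fasta"))
  jsonlite::write_json(
    list(diagnostic = lib$truth$diagnostic,
         expected_fragments = lib$truth$expected_fragments,
         amplicon_length_target = lib$truth$amplicon_length_target,
         products = prods$products),
    file.path(out_dir, "truth.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "simulate",
                 list(seed = cfg$seed, products_seed = products_seed))
  invisible(list(lib = lib, products = prods, out_dir = out_dir))
}
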