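# Query identification against the reference library (best-match
# nearest neighbor with a k-mer prefilter), assay-outcome prediction
# and the product-level authentication report.

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percent identity between two sequences
#'
#' Computes a global pairwise alignment internally (Needleman-Wunsch,
#' match +1, mismatch -1, gap -2 per base, free end gaps) and reports
#' `100 * matches / aligned columns`, excluding terminal free-gap
#' overhangs from the column count. Rounded half-up to 1 decimal
#' place - the granularity of best-match identity reports.
#'
#' @param a,b Ungapped DNA strings.
#' @return Percent identity in `[0, 100]`.
#' @export
identity_percent <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty input sequence", call. = FALSE)
  r <- nw_identity_cpp(toupper(a), toupper(b), 1, -1, -2)
  if (r$columns == 0L) return(0)
  round_half_up(100 * r$matches / r$columns, 1)
}

# k-mer set of a sequence
kmer_set <- function(x, k = 8) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

#' Identify a query sequence against the reference library
#'
#' Exhaustive nearest-neighbor identification: the best percent
#' identity ([identity_percent()]) to any member of each species is
#' computed and species are ranked by it. A shared-k-mer prefilter
#' (default k = 8) skips references sharing no k-mer with the query;
#' exactness is preserved by falling back to the full scan when the
#' filter would skip everything. Species tied at the top identity are
#' reported together, never silently broken.
#'
#' @param query A single ungapped DNA string.
#' @param library Named character vector of reference sequences.
#' @param table Sample metadata data.frame (maps ids to species).
#' @param k k-mer length for the prefilter (default 8).
#' @return List of class `identification` with `hits` (data.frame of
#'   species and best identity, sorted descending), `top_species`
#'   (character vector, >1 on ties) and `top_identity`.
#' @export
identify <- function(query, library, table, k = 8) {
  stopifnot(length(library) > 0, !is.null(names(library)))
  qk <- kmer_set(toupper(query), k)
  shares <- vapply(library, function(r) {
    any(qk %in% kmer_set(toupper(r), k))
  }, logical(1))
  cand <- if (any(shares)) library[shares] else library
  ident <- vapply(cand, function(r) identity_percent(query, r), numeric(1))
  sp <- table$species[match(names(cand), table$sample_id)]
  best <- vapply(split(ident, sp), max, numeric(1))
  hits <- data.frame(species = names(best), identity = unname(best),
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$identity, hits$species), , drop = FALSE]
  rownames(hits) <- NULL
  top <- hits$species[hits$identity == hits$identity[1]]
  structure(list(hits = hits, top_species = top,
                 top_identity = hits$identity[1]),
            class = "identification")
}

#' Predict PCR and PCR-RFLP outcomes for a query
#'
#' Runs the assay's primers on the query template: no amplicon gives
#' `("-", "N/A")`; an amplicon uncut by the enzyme gives `("+", "-")`;
#' a cut amplicon gives `("+", "+")`.
#'
#' @param query A single ungapped DNA string.
#' @param design An `assay_design` from [differential_digestion()] or
#'   [select_assay()].
#' @param ... Constraints passed to [in_silico_pcr()].
#' @return Named character vector `c(specific_pcr=, rflp=)`.
#' @export
predict_assay <- function(query, design, ...) {
  amps <- in_silico_pcr(query, design$fwd, design$rev, ...)
  if (!length(amps)) {
    return(c(specific_pcr = "-", rflp = "N/A"))
  }
  cut <- any(vapply(amps, function(a) {
    length(digest(a, design$enzyme)$fragments) > 1L
  }, logical(1)))
  c(specific_pcr = "+", rflp = if (cut) "+" else "-")
}

# species-or-genus final call from identity, diagnostics and thresholds
final_call <- function(top_species, top_identity, diag_verdict, target,
                       species_threshold = 99.0) {
  label <- paste(top_species, collapse = "/")
  if (top_identity < species_threshold) return("unresolved")
  if (!(target %in% top_species)) return(label)
  if (isTRUE(diag_verdict)) return(label)
  # target hit without diagnostic confirmation: genus-level call only
  paste0(sub("[_ ].*$", "", target), " sp.")
}

#' Batch authentication report for query products
#'
#' Identifies every query record, checks the configured target's
#' diagnostic sites, predicts assay outcomes, and assembles one report
#' row per distinct best-match within each product. Products
#' represented by several records with different best matches are
#' flagged as mixtures. A species-composition summary (per product) is
#' attached as the `"composition"` attribute.
#'
#' @param queries Named character vector of ungapped query sequences
#'   (names = record ids).
#' @param library Named character vector of reference sequences.
#' @param table Sample metadata data.frame for the library.
#' @param product_ids Named character vector mapping record ids to
#'   product ids (default: each record is its own product).
#' @param design Optional `assay_design` for PCR/RFLP predictions.
#' @param sites Optional diagnostic sites from [diagnostic_sites()].
#' @param aln Optional library [alignment()]; required with `sites` to
#'   place queries into the diagnostic coordinate frame.
#' @param target Target species label (for the final call rule).
#' @param species_threshold Identity required for a species-level call
#'   (default 99.0).
#' @return data.frame report (one row per product x distinct hit) with
#'   attribute `composition`.
#' @export
batch_report <- function(queries, library, table,
                         product_ids = setNames(names(queries),
                                                names(queries)),
                         design = NULL, sites = NULL, aln = NULL,
                         target = NULL, species_threshold = 99.0) {
  if (!length(queries)) {
    out <- data.frame(product_id = character(0), record_id = character(0),
                      length = integer(0), identified = character(0),
                      identity = numeric(0), diagnostics = character(0),
                      specific_pcr = character(0), rflp = character(0),
                      final_call = character(0), mixture = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "composition") <- data.frame(species = character(0),
                                           count = integer(0),
                                           percent = numeric(0))
    return(out)
  }
  if (is.null(target) && !is.null(design)) target <- design$target

  rows <- lapply(names(queries), function(id) {
    q <- queries[[id]]
    idr <- identify(q, library, table)
    diag_v <- NA
    if (!is.null(sites) && !is.null(aln) && nrow(sites)) {
      qa <- align_query_to_alignment(q, aln)
      diag_v <- attr(check_query_diagnostics(qa, sites), "verdict")
    }
    assay <- if (!is.null(design)) predict_assay(q, design)
             else c(specific_pcr = NA_character_, rflp = NA_character_)
    call <- if (!is.null(target)) {
      final_call(idr$top_species, idr$top_identity, diag_v, target,
                 species_threshold)
    } else paste(idr$top_species, collapse = "/")
    data.frame(product_id = product_ids[[id]], record_id = id,
               length = nchar(q),
               identified = paste(idr$top_species, collapse = "/"),
               identity = idr$top_identity,
               diagnostics = if (is.na(diag_v)) "n/a" else
                 if (diag_v) "match" else "mismatch",
               specific_pcr = assay[["specific_pcr"]],
               rflp = assay[["rflp"]],
               final_call = call, mixture = FALSE,
               stringsAsFactors = FALSE)
  })
  rep_all <- do.call(rbind, rows)

  # collapse records with the same best match within a product; flag
  # products whose records disagree as mixtures
  out <- do.call(rbind, lapply(split(rep_all, rep_all$product_id),
    function(g) {
      parts <- split(g, g$identified)
      mixed <- length(parts) > 1L
      do.call(rbind, lapply(parts, function(p) {
        r <- p[1, , drop = FALSE]
        r$mixture <- mixed
        r
      }))
    }))
  out <- out[order(out$product_id), , drop = FALSE]
  rownames(out) <- NULL

  comp <- as.data.frame(base::table(out$identified),
                        stringsAsFactors = FALSE)
  names(comp) <- c("species", "count")
  n_products <- length(unique(out$product_id))
  comp$percent <- round_half_up(100 * comp$count / n_products, 1)
  comp <- comp[order(-comp$count, comp$species), , drop = FALSE]
  rownames(comp) <- NULL
  attr(out, "composition") <- comp
  out
}

#' Write an authentication report
#'
#' @param report data.frame from [batch_report()].
#' @param path Output path without extension; writes `<path>.tsv` and
#'   `<path>.json`, plus `<path>_composition.tsv`.
#' @export
write_report <- function(report, path) {
  write.table(report, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(report, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  write.table(attr(report, "composition"),
              paste0(path, "_composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
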