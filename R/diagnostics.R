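# Mining of fixed, species-diagnostic characters (SNPs and single-column
# indels) from a library alignment, and checking queries against them.

# could an observed state encode `x`? '-' only matches '-', a concrete
# base matches itself, an ambiguity code matches every base in its set
state_could_be <- function(observed, x) {
  if (observed == x) return(TRUE)
  if (observed == "-" || x == "-") return(FALSE)
  set <- IUPAC_CODES[[observed]]
  !is.null(set) && x %in% set
}

#' Mine diagnostic sites for a target species
#'
#' A column qualifies as diagnostic iff (i) every target sequence
#' carries the same concrete state `x` in `{A, C, G, T, -}` and (ii)
#' `x` is not observed - and could not be encoded by an ambiguity
#' code - in any scope sequence at that column. Results are sorted by
#' position. The coordinate frame (a free-text label describing which
#' alignment the positions refer to) is carried on the result so
#' reports always state it.
#'
#' With `min_target_fraction < 1` the target-monomorphism requirement
#' is relaxed: the most frequent concrete target state qualifies if its
#' frequency is at least that fraction. The default (1.0) demands
#' complete fixation, since only fixed characters are stable
#' authentication evidence.
#'
#' @param aln A [alignment()] containing target and scope samples.
#' @param table Sample metadata data.frame.
#' @param target Target species label.
#' @param scope Species labels to discriminate against (default: every
#'   non-target species in `table` present in the alignment).
#' @param min_target_fraction Required frequency of the diagnostic
#'   state within the target (default 1.0 = fixed).
#' @param frame Coordinate-frame label recorded on the output.
#' @return data.frame with columns `position`, `target_state`,
#'   `other_states`, `type` (`snp`/`indel`), plus attribute `frame`.
#' @export
diagnostic_sites <- function(aln, table, target, scope = NULL,
                             min_target_fraction = 1.0,
                             frame = "library alignment") {
  stopifnot(inherits(aln, "dna_alignment"))
  t_ids <- intersect(table$sample_id[table$species == target], aln$ids)
  if (!length(t_ids)) stop("target species absent: ", target, call. = FALSE)
  if (is.null(scope)) scope <- setdiff(unique(table$species), target)
  scope <- setdiff(scope, target)
  s_ids <- intersect(table$sample_id[table$species %in% scope], aln$ids)
  if (!length(s_ids)) stop("empty comparison scope", call. = FALSE)

  m <- as.matrix(aln)
  tm <- m[t_ids, , drop = FALSE]
  sm <- m[s_ids, , drop = FALSE]
  concrete <- c("A", "C", "G", "T", "-")

  rows <- list()
  for (pos in seq_len(aln$length)) {
    tcol <- tm[, pos]
    tab <- base::table(tcol)
    x <- names(tab)[which.max(tab)]
    if (!(x %in% concrete)) next
    if (tab[[x]] / length(tcol) < min_target_fraction) next
    if (min_target_fraction >= 1 && length(tab) > 1L) next
    scol <- unique(sm[, pos])
    if (any(vapply(scol, state_could_be, logical(1), x = x))) next
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, target_state = x,
      other_states = paste(sort(scol), collapse = ","),
      type = if (x == "-" || any(scol == "-")) "indel" else "snp",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(position = integer(0), target_state = character(0),
                         other_states = character(0), type = character(0),
                         stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame") <- frame
  attr(out, "target") <- target
  out
}

#' Number of polymorphic sites among a set of samples
#'
#' Counts the variable alignment columns over the haplotype-collapsed
#' member set (collapsing removes duplicate sequences but cannot change
#' which columns vary).
#'
#' @param aln A [alignment()].
#' @param members Sample ids (>= 2).
#' @return Integer count.
#' @export
count_polymorphic_sites <- function(aln, members = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(members)) members <- aln$ids
  if (length(members) < 2L) stop(">= 2 members required", call. = FALSE)
  haps <- collapse_haplotypes(aln, members)
  if (nrow(haps) < 2L) return(0L)
  hap_aln <- alignment(setNames(haps$residues, haps$haplotype))
  length(variable_sites(hap_aln))
}

#' Check a query against diagnostic sites
#'
#' Reads the query's state at each diagnostic position (the query must
#' already be placed in the same coordinate frame, e.g. via
#' [align_query_to_alignment()]) and reports per-site match/mismatch
#' plus an overall all-match verdict.
#'
#' @param query_aligned Gapped query string in the alignment frame.
#' @param sites data.frame from [diagnostic_sites()].
#' @return data.frame with `position`, `expected`, `observed`, `match`;
#'   attribute `verdict` is TRUE iff every site matches.
#' @export
check_query_diagnostics <- function(query_aligned, sites) {
  L <- nchar(query_aligned)
  if (nrow(sites) && max(sites$position) > L) {
    stop("diagnostic position ", max(sites$position),
         " outside query frame of length ", L, call. = FALSE)
  }
  observed <- vapply(sites$position,
                     function(p) substr(query_aligned, p, p), character(1))
  out <- data.frame(position = sites$position,
                    expected = sites$target_state,
                    observed = observed,
                    match = observed == sites$target_state,
                    stringsAsFactors = FALSE)
  attr(out, "verdict") <- nrow(out) > 0L && all(out$match)
  out
}

#' Write a diagnostic-site report
#'
#' @param sites data.frame from [diagnostic_sites()].
#' @param path Output TSV path.
#' @export
write_diagnostics <- function(sites, path) {
  out <- cbind(sites, frame = attr(sites, "frame"),
               target = attr(sites, "target"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
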