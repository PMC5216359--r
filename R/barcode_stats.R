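# Barcode-library statistics: haplotype collapsing, variable sites,
# Kimura 2-parameter distances, intra/inter-specific summaries and
# barcode-gap assessment.

# integer coding for distance computations: A=1 C=2 G=3 T=4, everything
# else (gap or ambiguity code) 0 and excluded from comparable sites
code_matrix <- function(aln, members = NULL) {
  m <- as.matrix(aln)
  if (!is.null(members)) {
    miss <- setdiff(members, rownames(m))
    if (length(miss)) {
      stop("sample id(s) not in alignment: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    m <- m[members, , drop = FALSE]
  }
  codes <- matrix(match(m, c("A", "C", "G", "T"), nomatch = 0L),
                  nrow = nrow(m), dimnames = dimnames(m))
  codes
}

# K2P distance from transition/transversion proportions; NA (undefined)
# on zero comparable sites or saturation (log/sqrt argument <= 0)
k2p_from_counts <- function(n, s, v) {
  P <- ifelse(n > 0, s / n, NA_real_)
  Q <- ifelse(n > 0, v / n, NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(P) & w1 > 0 & w2 > 0
  arg <- ifelse(ok, w1, 1) * sqrt(ifelse(ok, w2, 1))
  d <- ifelse(ok, -0.5 * log(arg), NA_real_)
  d + 0  # normalize IEEE -0 from log(1)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Over comparable sites (both residues unambiguous A/C/G/T), computes
#' the transition proportion `P = s/n` and transversion proportion
#' `Q = v/n` and the distance `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`.
#' Zero comparable sites or saturation (a non-positive log/sqrt
#' argument) yield an `NA` distance with a diagnostic reason rather
#' than an error, so matrix builds never abort.
#'
#' @param a,b Aligned residue strings of equal length.
#' @return List with `distance` and `counts`
#'   (`n`, `s`, `v`, `P`, `Q`).
#' @export
k2p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences must have equal (aligned) length", call. = FALSE)
  }
  aln <- alignment(c(seq_a = a, seq_b = b))
  cc <- k2p_counts_cpp(code_matrix(aln))
  n <- cc$n[1, 2]; s <- cc$s[1, 2]; v <- cc$v[1, 2]
  d <- k2p_from_counts(n, s, v)
  reason <- if (!is.na(d)) NA_character_
            else if (n == 0) "no comparable sites" else "saturated"
  list(distance = d,
       counts = list(n = n, s = s, v = v,
                     P = if (n > 0) s / n else NA_real_,
                     Q = if (n > 0) v / n else NA_real_,
                     reason = reason))
}

#' Pairwise K2P distance matrix
#'
#' Builds the full symmetric matrix of pairwise K2P distances. Under
#' `deletion = "pairwise"` (the default, matching the common
#' distance-software default) each pair uses its own comparable-site
#' set; under `"complete"` every column containing a gap or ambiguity
#' code in any sequence is removed before any comparison.
#'
#' @param aln A [alignment()] with >= 2 records.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return Symmetric numeric matrix (undefined entries `NA`) with
#'   attributes `n`, `s`, `v` (site-pair count matrices).
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "dna_alignment"))
  deletion <- match.arg(deletion)
  if (length(aln$ids) < 2L) stop(">= 2 records required", call. = FALSE)
  codes <- code_matrix(aln)
  if (deletion == "complete") {
    keep <- colSums(codes == 0L) == 0L
    codes <- codes[, keep, drop = FALSE]
  }
  cc <- k2p_counts_cpp(codes)
  D <- matrix(k2p_from_counts(cc$n, cc$s, cc$v),
              nrow = nrow(codes), dimnames = list(aln$ids, aln$ids))
  diag(D) <- 0
  dimnames(cc$n) <- dimnames(cc$s) <- dimnames(cc$v) <- dimnames(D)
  structure(D, n = cc$n, s = cc$s, v = cc$v, deletion = deletion)
}

#' Collapse aligned sequences into haplotypes
#'
#' Exact string identity over aligned residues (gap columns included)
#' defines the haplotype classes. Haplotypes are ordered by descending
#' member count, then by first occurrence, and labelled H1, H2, ...
#'
#' @param aln A [alignment()].
#' @param members Optional subset of sample ids (default: all).
#' @return data.frame with columns `haplotype`, `residues`,
#'   `n_members`, `members` (comma-separated ids).
#' @export
collapse_haplotypes <- function(aln, members = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(members)) members <- aln$ids
  if (!length(members)) stop("empty member set", call. = FALSE)
  seqs <- aln$seqs[members]
  classes <- split(members, factor(seqs, levels = unique(seqs)))
  ord <- order(-lengths(classes), seq_along(classes))
  classes <- classes[ord]
  data.frame(
    haplotype = paste0("H", seq_along(classes)),
    residues = names(classes),
    n_members = lengths(classes),
    members = vapply(classes, paste, character(1), collapse = ","),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Variable alignment columns within a sample set
#'
#' Positions (1-based) where at least two distinct states occur among
#' the members; the gap character and each ambiguity code count as
#' their own state.
#'
#' @param aln A [alignment()].
#' @param members Optional subset of sample ids (>= 2; default: all).
#' @return Integer vector of 1-based column positions.
#' @export
variable_sites <- function(aln, members = NULL) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (is.null(members)) members <- aln$ids
  if (length(members) < 2L) stop(">= 2 members required", call. = FALSE)
  m <- as.matrix(aln)[members, , drop = FALSE]
  which(apply(m, 2, function(col) length(unique(col)) > 1L))
}

# pairs of ids (rows of a 2-col matrix) within / between scopes
scope_pairs <- function(ids_a, ids_b) {
  same <- identical(sort(ids_a), sort(ids_b))
  if (same) {
    if (length(ids_a) < 2L) return(matrix(character(0), ncol = 2))
    t(combn(ids_a, 2))
  } else {
    as.matrix(expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  }
}

#' Intra- or inter-specific distance summary
#'
#' Aggregates the pairwise distances between two species scopes. With
#' `species_b` equal to `species_a` the summary is intraspecific
#' (unordered within-species pairs); `species_b = "ALL_OTHERS"` uses
#' every other species in the table; a character vector selects a
#' species set. Undefined entries are excluded and counted.
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param table Sample metadata data.frame.
#' @param species_a Species label.
#' @param species_b Species label, `"ALL_OTHERS"`, or set of labels.
#' @return List with `min`, `max`, `mean`, `n_pairs`, `n_undefined`.
#' @export
species_summary <- function(D, table, species_a, species_b = species_a) {
  ids_a <- table$sample_id[table$species == species_a]
  ids_a <- intersect(ids_a, rownames(D))
  if (!length(ids_a)) stop("no samples for species: ", species_a,
                           call. = FALSE)
  if (identical(species_b, "ALL_OTHERS")) {
    species_b <- setdiff(unique(table$species), species_a)
  }
  if (identical(species_b, species_a)) {
    ids_b <- ids_a
  } else {
    ids_b <- table$sample_id[table$species %in% species_b]
    ids_b <- intersect(ids_b, rownames(D))
    if (!length(ids_b)) stop("no samples in comparison scope", call. = FALSE)
  }
  pairs <- scope_pairs(ids_a, ids_b)
  if (nrow(pairs) == 0L) {
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                n_pairs = 0L, n_undefined = 0L))
  }
  vals <- D[pairs]
  und <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    return(list(min = NA_real_, max = NA_real_, mean = NA_real_,
                n_pairs = 0L, n_undefined = und))
  }
  list(min = min(vals), max = max(vals), mean = mean(vals),
       n_pairs = length(vals), n_undefined = und)
}

#' Barcode-gap assessment for a target species
#'
#' Compares the target's maximum intraspecific distance with the
#' minimum interspecific distance to a comparison scope; a barcode gap
#' is present iff the minimum interspecific exceeds the maximum
#' intraspecific distance.
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param table Sample metadata data.frame.
#' @param target Target species label (>= 2 samples).
#' @param scope `"congener"`, `"adulterant"` or `"all"` - which group
#'   of non-target species to compare against.
#' @return List with `max_intra`, `min_inter`, `gap_present`, `scope`.
#' @export
barcode_gap <- function(D, table, target,
                        scope = c("all", "congener", "adulterant")) {
  scope <- match.arg(scope)
  other <- table[table$species != target, , drop = FALSE]
  if (scope != "all") other <- other[other$group == scope, , drop = FALSE]
  if (!nrow(other)) stop("empty comparison scope: ", scope, call. = FALSE)
  intra <- species_summary(D, table, target)
  if (intra$n_pairs == 0L) {
    stop("target needs >= 2 samples for an intraspecific maximum",
         call. = FALSE)
  }
  inter <- species_summary(D, table, target, unique(other$species))
  list(max_intra = intra$max, min_inter = inter$min,
       gap_present = isTRUE(inter$min > intra$max), scope = scope)
}

#' Export a distance matrix
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param path Output path.
#' @param format `"phylip"` (square) or `"tsv"` (long format with
#'   comparable-site and substitution counts).
#' @export
write_distance_matrix <- function(D, path, format = c("phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "phylip") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(D)), con)
    for (i in seq_len(nrow(D))) {
      writeLines(paste(c(sprintf("%-10s", rownames(D)[i]),
                         sprintf("%.6f", D[i, ])), collapse = "  "), con)
    }
  } else {
    n <- attr(D, "n"); s <- attr(D, "s"); v <- attr(D, "v")
    idx <- which(upper.tri(D), arr.ind = TRUE)
    long <- data.frame(id_a = rownames(D)[idx[, 1]],
                       id_b = colnames(D)[idx[, 2]],
                       d = D[idx], n = n[idx], s = s[idx], v = v[idx])
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
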