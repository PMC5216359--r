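# Progressive multiple alignment (fallback aligner) and profile-based
# placement of query sequences into an existing alignment frame.
#
# The dynamic-programming kernel (Gotoh affine-gap alignment over a
# precomputed column-score matrix) lives in src/align.cpp; everything
# here builds score matrices and assembles alignments from its paths.

# score matrix between two ungapped sequences: match +1 / mismatch -1
seq_score_matrix <- function(a_chars, b_chars, match = 1, mismatch = -1) {
  eq <- outer(a_chars, b_chars, "==")
  ifelse(eq, match, mismatch)
}

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' @param a,b Ungapped DNA strings.
#' @param match,mismatch Substitution scores (defaults +1/-1).
#' @param gap_open Score of the first base of a gap (default -5).
#' @param gap_ext Score of each further gapped base (default -1).
#' @param free_ends Make terminal gaps free (semi-global)?
#' @return List with gapped strings `a` and `b` and the alignment
#'   `score`.
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -5, gap_ext = -1, free_ends = FALSE) {
  ac <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bc <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  S <- seq_score_matrix(ac, bc, match, mismatch)
  p <- gotoh_path_cpp(S, gap_open, gap_ext, free_ends)
  list(a = paste(ifelse(p$a == 0L, "-", ac[pmax(p$a, 1L)]), collapse = ""),
       b = paste(ifelse(p$b == 0L, "-", bc[pmax(p$b, 1L)]), collapse = ""),
       score = p$score,
       path_a = p$a, path_b = p$b)
}

# column base-frequency profile of a character matrix (gaps/ambiguity
# contribute zero mass, so they are scoring-neutral)
profile_freq <- function(m) {
  bases <- c("A", "C", "G", "T")
  f <- vapply(bases, function(b) colMeans(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L && !is.matrix(f)) f <- matrix(f, nrow = 1)
  t(f)  # 4 x L
}

# profile-vs-profile column score: sum_xy fA fB * (+1 if x==y else -1)
# = 2 * <fA, fB> - massA * massB
profile_score_matrix <- function(fa, fb) {
  2 * crossprod(fa, fb) - outer(colSums(fa), colSums(fb))
}

# merge two sub-alignments (character matrices) along a Gotoh path
merge_profiles <- function(ma, mb, gap_open = -5, gap_ext = -1) {
  S <- profile_score_matrix(profile_freq(ma), profile_freq(mb))
  p <- gotoh_path_cpp(S, gap_open, gap_ext, FALSE)
  take <- function(m, idx) {
    out <- matrix("-", nrow(m), length(idx), dimnames = list(rownames(m)))
    keep <- idx != 0L
    out[, keep] <- m[, idx[keep], drop = FALSE]
    out
  }
  rbind(take(ma, p$a), take(mb, p$b))
}

#' Progressive multiple alignment of a sequence library
#'
#' Fallback aligner used when no curated alignment is supplied:
#' pairwise Needleman-Wunsch guide distances (match +1, mismatch -1,
#' gap open -5, gap extend -1), a UPGMA guide tree, and profile-profile
#' merges with the same scores. Deterministic for a fixed input order;
#' tie scores resolve onto one canonical gap placement.
#'
#' @param seqs Named character vector of ungapped sequences (>= 2 for a
#'   real alignment; a single sequence is returned unchanged with a
#'   warning).
#' @param gap_open,gap_ext Gap scores (defaults -5 / -1).
#' @return A [alignment()] object with records in input order.
#' @export
align_library <- function(seqs, gap_open = -5, gap_ext = -1) {
  stopifnot(!is.null(names(seqs)))
  validate_residues(seqs, allow_gaps = FALSE)
  n <- length(seqs)
  if (n == 1L) {
    warning("single sequence: returned unaligned", call. = FALSE)
    return(alignment(seqs))
  }
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  # guide distances: p-distance over each pairwise alignment
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pw <- pairwise_align(seqs[[i]], seqs[[j]], gap_open = gap_open,
                           gap_ext = gap_ext)
      ai <- strsplit(pw$a, "", fixed = TRUE)[[1]]
      bi <- strsplit(pw$b, "", fixed = TRUE)[[1]]
      D[i, j] <- D[j, i] <- 1 - sum(ai == bi) / length(ai)
    }
  }

  # UPGMA guide tree; merge following hclust's merge table
  hc <- hclust(as.dist(D), method = "average")
  mats <- lapply(seq_len(n), function(i) {
    matrix(chars[[i]], nrow = 1, dimnames = list(names(seqs)[i]))
  })
  merged <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    pick <- function(idx) if (idx < 0) mats[[-idx]] else merged[[idx]]
    merged[[k]] <- merge_profiles(pick(hc$merge[k, 1]), pick(hc$merge[k, 2]),
                                  gap_open, gap_ext)
  }
  m <- merged[[n - 1]]
  m <- m[match(names(seqs), rownames(m)), , drop = FALSE]
  alignment_from_matrix(m)
}

#' Place a query sequence into an alignment's coordinate frame
#'
#' Profile-aligns an ungapped query against the column profile of an
#' existing alignment so that per-column states (for diagnostic-site
#' checks) can be read off in the library's 1-based coordinates. Query
#' bases falling between library columns (insertions) are dropped and
#' counted in the `"inserted"` attribute.
#'
#' @param query A single ungapped DNA string.
#' @param aln The reference [alignment()].
#' @param gap_open,gap_ext Gap scores (defaults -5 / -1).
#' @param free_ends Allow free terminal gaps (default TRUE, so partial
#'   queries map into the frame without end-gap penalties)?
#' @return Gapped query string of length `aln$length`, with attribute
#'   `inserted` (number of dropped query bases).
#' @export
align_query_to_alignment <- function(query, aln, gap_open = -5,
                                     gap_ext = -1, free_ends = TRUE) {
  stopifnot(inherits(aln, "dna_alignment"))
  qc <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  fa <- profile_freq(as.matrix(aln))                # 4 x L
  fq <- vapply(qc, function(b) as.numeric(c("A", "C", "G", "T") == b),
               numeric(4))                          # 4 x m
  S <- profile_score_matrix(fa, fq)
  p <- gotoh_path_cpp(S, gap_open, gap_ext, free_ends)
  out <- rep("-", aln$length)
  hit <- p$a != 0L & p$b != 0L
  out[p$a[hit]] <- qc[p$b[hit]]
  inserted <- sum(p$a == 0L)
  structure(paste(out, collapse = ""), inserted = inserted)
}
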