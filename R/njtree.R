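# Neighbor-joining tree construction, bootstrap support and split
# (bipartition) utilities. Trees are returned as ape "phylo" objects,
# unrooted with one basal trifurcation; supports are integer percents
# stored as node labels of the full-data topology.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' `Q(i,j) = (r - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`; branch
#' lengths follow the standard NJ formulas. Negative branch lengths are
#' clamped to zero and the total clamped deficit is stored in the
#' `"negative_deficit"` attribute. Ties in Q are broken by the smallest
#' `(i, j)` index pair in the current label order, so the result is
#' deterministic.
#'
#' @param D Symmetric distance matrix with >= 3 labelled taxa and no
#'   undefined (`NA`) entries.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3L) stop(">= 3 taxa required", call. = FALSE)
  if (anyNA(D)) {
    idx <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop("undefined distance(s) for pair(s): ",
         paste(sprintf("%s-%s", labels[idx[, 1]], labels[idx[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + abs(x); 0 } else x
  }
  frag <- labels  # newick fragment per active node
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    r <- rowSums(D)
    nn <- nrow(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j), i < j, among minima of Q
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))))
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- frag
    D <- D2
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(l1), frag[2], fmt(l2), frag[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# canonical split signatures of the internal edges of an unrooted tree;
# each split is the side NOT containing the lexicographically smallest
# tip label, serialized as a sorted id string
tree_splits <- function(tree, include_trivial = FALSE) {
  tips <- tree$tip.label
  anchor <- min(tips)
  pp <- ape::prop.part(tree)
  sig <- function(side) paste(sort(side), collapse = "\r")
  out <- character(0)
  for (part in pp) {
    side <- tips[part]
    if (length(side) == length(tips)) next  # root trivially holds all tips
    if (anchor %in% side) side <- setdiff(tips, side)
    if (!include_trivial && (length(side) < 2L ||
                             length(side) > length(tips) - 2L)) next
    out <- c(out, sig(side))
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, recomputing the
#' K2P matrix and NJ tree for each replicate. The support of each
#' internal edge of the reference topology is the percentage of
#' replicates containing the same bipartition; supports are attached as
#' integer node labels of the reference tree (supports below any
#' display threshold are a rendering concern and are always retained
#' here). Replicates whose resampled matrix contains undefined
#' distances are discarded and redrawn; the redraw count is stored in
#' the `"redraws"` attribute. Deterministic for a fixed seed.
#'
#' @param aln A [alignment()] with >= 3 records.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer random seed.
#' @param deletion Gap-handling mode passed to [distance_matrix()].
#' @return The reference `phylo` tree with `node.label` supports and
#'   attributes `redraws` and `seed`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              deletion = "pairwise") {
  stopifnot(inherits(aln, "dna_alignment"), n_reps >= 1)
  D <- distance_matrix(aln, deletion = deletion)
  if (anyNA(D)) stop("full-data distance matrix has undefined entries",
                     call. = FALSE)
  ref <- neighbor_joining(D)
  ref_sig <- tree_splits(ref)
  counts <- setNames(integer(length(ref_sig)), ref_sig)

  m <- as.matrix(aln)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  redraws <- 0L
  done <- 0L
  while (done < n_reps) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    Db <- distance_matrix(alignment_from_matrix(m[, cols, drop = FALSE]),
                          deletion = deletion)
    if (anyNA(Db)) { redraws <- redraws + 1L; next }
    bt <- neighbor_joining(Db)
    hits <- intersect(tree_splits(bt), ref_sig)
    counts[hits] <- counts[hits] + 1L
    done <- done + 1L
  }
  support <- round(100 * counts / n_reps)

  # map supports onto the reference tree's internal nodes
  tips <- ref$tip.label
  anchor <- min(tips)
  pp <- ape::prop.part(ref)
  labs <- character(ref$Nnode)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (length(side) == length(tips)) { labs[k] <- ""; next }  # basal node
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L) {
      labs[k] <- ""
      next
    }
    labs[k] <- as.character(support[[paste(sort(side), collapse = "\r")]])
  }
  ref$node.label <- labs
  attr(ref, "redraws") <- redraws
  attr(ref, "seed") <- seed
  ref
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with 6 significant figures; integer
#' bootstrap supports appear as internal-node labels.
#'
#' @param tree A `phylo` object.
#' @return Single Newick string terminated by `;`.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 6)
}

#' Is a species (or species set) monophyletic on an unrooted tree?
#'
#' TRUE iff some edge of the unrooted tree induces a bipartition with
#' exactly the species' leaves on one side. Singletons are trivially
#' monophyletic.
#'
#' @param tree A `phylo` object.
#' @param table Sample metadata data.frame mapping tip ids to species.
#' @param species Species label or set of labels.
#' @return Logical.
#' @export
monophyly_check <- function(tree, table, species) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  members <- intersect(table$sample_id[table$species %in% species], tips)
  if (!length(members)) {
    stop("species not present on tree: ", paste(species, collapse = ", "),
         call. = FALSE)
  }
  if (length(members) == 1L || length(members) == length(tips)) return(TRUE)
  anchor <- min(tips)
  side <- if (anchor %in% members) setdiff(tips, members) else members
  sig <- paste(sort(side), collapse = "\r")
  sig %in% tree_splits(tree, include_trivial = TRUE)
}

#' ASCII rendering of a small tree (log smoke tests)
#'
#' @param tree A `phylo` object.
#' @return Character vector of lines (invisibly); also printed.
#' @export
ascii_tree <- function(tree) {
  out <- utils::capture.output(ape::print.phylo(tree))
  cat(out, sep = "\n")
  invisible(out)
}
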