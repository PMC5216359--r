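# Shared fixtures and independent oracles used across the suite.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# tiny two-species library with one fixed difference
tiny_library <- function() {
  seqs <- c(t1 = "ACGTACGTAC", t2 = "ACGTACGTAC",
            c1 = "ACGTACGTAG", c2 = "ACGTACGTAG")
  tab <- data.frame(sample_id = names(seqs),
                    species = c("sp_t", "sp_t", "sp_c", "sp_c"),
                    group = c("target", "target", "congener", "congener"),
                    stringsAsFactors = FALSE)
  list(aln = alignment(seqs), table = tab)
}

# brute-force K2P from first principles (independent of the package's
# coding): explicit site classification over a pair of aligned strings
oracle_k2p <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  ok <- ac %in% c("A", "C", "G", "T") & bc %in% c("A", "C", "G", "T")
  ac <- ac[ok]; bc <- bc[ok]
  n <- length(ac)
  if (n == 0) return(NA_real_)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  s <- sum(paste0(ac, bc) %in% ts_pairs)
  v <- sum(ac != bc) - s
  P <- s / n; Q <- v / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2)) + 0
}

# brute-force diagnostic-site scan: every column x every candidate
# state, literal definition
oracle_diagnostic <- function(m, target_rows, scope_rows) {
  hits <- integer(0)
  states <- character(0)
  for (j in seq_len(ncol(m))) {
    for (x in c("A", "C", "G", "T", "-")) {
      if (!all(m[target_rows, j] == x)) next
      scope <- m[scope_rows, j]
      could <- vapply(scope, function(o) {
        if (o == x) return(TRUE)
        if (o == "-" || x == "-") return(FALSE)
        s <- its2auth::IUPAC_CODES[[o]]
        !is.null(s) && x %in% s
      }, logical(1))
      if (!any(could)) {
        hits <- c(hits, j); states <- c(states, x)
      }
    }
  }
  data.frame(position = hits, target_state = states,
             stringsAsFactors = FALSE)
}

# regex-based motif scan oracle (both strands, plus-coordinates)
oracle_motif <- function(x, motif) {
  to_regex <- function(m) {
    sets <- its2auth::IUPAC_CODES
    paste(vapply(strsplit(m, "")[[1]], function(ch) {
      s <- sets[[ch]]
      if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
    }, character(1)), collapse = "")
  }
  hit_starts <- function(s, rx) {
    out <- integer(0)
    for (st in seq_len(max(nchar(s) - nchar(motif) + 1, 0))) {
      if (grepl(paste0("^", rx), substr(s, st, st + nchar(motif) - 1))) {
        out <- c(out, st)
      }
    }
    out
  }
  rx <- to_regex(motif)
  plus <- hit_starts(x, rx)
  rc <- its2auth::reverse_complement(x)
  minus <- nchar(x) - (hit_starts(rc, rx) + nchar(motif) - 1) + 1
  as.integer(sort(unique(c(plus, minus))))
}

# least-squares branch-length fit of a fixed 4-taxon topology
# ((a,b),(c,d)) to a distance matrix; returns the residual sum of
# squares (negative lengths permitted, as in the classical fit)
ls_fit_quartet <- function(D, a, b, c, d) {
  # path-length design over 5 branches: la, lb, lc, ld, lm
  pairs <- rbind(c(a, b), c(a, c), c(a, d), c(b, c), c(b, d), c(c, d))
  X <- rbind(c(1, 1, 0, 0, 0),
             c(1, 0, 1, 0, 1),
             c(1, 0, 0, 1, 1),
             c(0, 1, 1, 0, 1),
             c(0, 1, 0, 1, 1),
             c(0, 0, 1, 1, 0))
  y <- D[pairs]
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# random additive (tree-metric) distance matrix from a random topology
random_additive <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 1))
  D <- as.matrix(ape::cophenetic.phylo(tr))
  list(tree = tr, D = D[order(rownames(D)), order(colnames(D))])
}

split_signatures <- function(tree) {
  its2auth:::tree_splits(tree)
}

# small synthetic library shared by the heavier tests (built once)
small_syn_config <- function(seed = 1) {
  synthetic_config(seed = seed, n_congener_species = 3,
                   n_adulterant_species = 3, samples_per_species = 3,
                   target_samples = 5)
}
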