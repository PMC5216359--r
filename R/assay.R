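# In-silico species-specific PCR-RFLP assay design: degenerate
# restriction-motif scanning, primer binding with a 3' clamp rule,
# amplicon prediction (primer bases overwrite the template, as in the
# physical product), digestion, differential-pattern scoring and
# mismatch-engineered primer design.

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param motif Recognition motif over the IUPAC alphabet.
#' @param cut_offset Top-strand cut after this many motif bases
#'   (`1 <= cut_offset <= nchar(motif)`).
#' @return Object of class `enzyme`.
#' @export
enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(IUPAC_CODES))) {
    stop("motif contains non-IUPAC symbol", call. = FALSE)
  }
  if (cut_offset < 1 || cut_offset > length(chars)) {
    stop("cut_offset must lie within the motif", call. = FALSE)
  }
  structure(list(name = name, motif = motif,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

#' Built-in enzyme table
#'
#' Ships Bgl I only (GCCNNNN^NGGC, cutting after motif base 7 with a
#' 3-nt 3' overhang); extend by constructing further [enzyme()] objects
#' or via [read_enzymes()].
#'
#' @return Named list of `enzyme` objects.
#' @export
default_enzymes <- function() {
  list(BglI = enzyme("BglI", "GCCNNNNNGGC", 7L))
}

#' Read an enzyme table from a TSV config file
#'
#' Columns: `name`, `motif`, `cut_offset`.
#'
#' @param path Path to the TSV file.
#' @return Named list of `enzyme` objects.
#' @export
read_enzymes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    enzyme(tab$name[i], tab$motif[i], tab$cut_offset[i])
  })
  setNames(out, tab$name)
}

#' Define a PCR primer
#'
#' @param name Primer name.
#' @param sequence 5'->3' sequence, unambiguous bases only, length
#'   >= 10.
#' @param role `"forward"` or `"reverse"`.
#' @return Object of class `primer`.
#' @export
primer <- function(name, sequence, role = c("forward", "reverse")) {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) < 10L) stop("primer length must be >= 10", call. = FALSE)
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("primer must contain unambiguous bases only", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, role = role),
            class = "primer")
}

#' Read a primer table from a TSV config file
#'
#' Columns: `name`, `sequence`, `role`.
#'
#' @param path Path to the TSV file.
#' @return Named list of `primer` objects.
#' @export
read_primers <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    primer(tab$name[i], tab$sequence[i], tab$role[i])
  })
  setNames(out, tab$name)
}

#' Scan a sequence for a degenerate restriction motif
#'
#' IUPAC semantics: the template base must be unambiguous and contained
#' in the motif symbol's base set, so ambiguous template bases never
#' match (a site must be certain to be cut). With
#' `both_strands = TRUE` the minus strand is scanned via the reverse
#' complement and hits are reported by the plus-strand coordinate of
#' the leftmost footprint base; minus-strand duplicates of plus-strand
#' hits of palindromic motifs are removed.
#'
#' @param residues Ungapped DNA string.
#' @param enz An [enzyme()].
#' @param both_strands Scan both strands (default TRUE)?
#' @return data.frame with columns `start` and `strand`.
#' @export
find_motif_sites <- function(residues, enz, both_strands = TRUE) {
  x <- toupper(residues)
  if (grepl("-", x, fixed = TRUE)) {
    stop("gapped input: motif scan requires ungapped residues",
         call. = FALSE)
  }
  scan_plus <- function(x) {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    mchars <- strsplit(enz$motif, "", fixed = TRUE)[[1]]
    mlen <- length(mchars)
    n <- length(chars)
    if (n < mlen) return(integer(0))
    starts <- seq_len(n - mlen + 1L)
    ok <- rep(TRUE, length(starts))
    for (k in seq_len(mlen)) {
      ok <- ok & (chars[starts + k - 1L] %in% IUPAC_CODES[[mchars[k]]])
    }
    starts[ok]
  }
  plus <- scan_plus(x)
  out <- data.frame(start = plus,
                    strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    mlen <- nchar(enz$motif)
    rc_hits <- scan_plus(reverse_complement(x))
    minus <- nchar(x) - (rc_hits + mlen - 1L) + 1L
    minus <- setdiff(minus, plus)  # palindromic duplicates
    if (length(minus)) {
      out <- rbind(out, data.frame(start = minus, strand = "-",
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Predict the restriction digest of an amplicon
#'
#' Cut coordinates on the linear top strand are
#' `start + cut_offset - 1` for plus-strand motif hits and
#' `start + (motif length - cut_offset)` for minus-strand hits;
#' fragments are the consecutive differences including both ends. No
#' hit yields a single full-length fragment.
#'
#' @param amplicon An amplicon list from [in_silico_pcr()] or an
#'   ungapped DNA string.
#' @param enz An [enzyme()].
#' @return List of class `digest_pattern` with `fragments` (template
#'   order) and `cuts`.
#' @export
digest <- function(amplicon, enz) {
  product <- if (is.list(amplicon)) amplicon$product else amplicon
  L <- nchar(product)
  hits <- find_motif_sites(product, enz, both_strands = TRUE)
  mlen <- nchar(enz$motif)
  cuts <- ifelse(hits$strand == "+",
                 hits$start + enz$cut_offset - 1L,
                 hits$start + (mlen - enz$cut_offset))
  cuts <- sort(unique(cuts[cuts >= 1L & cuts <= L - 1L]))
  structure(list(fragments = diff(c(0L, cuts, L)), cuts = cuts),
            class = "digest_pattern")
}

#' Find primer binding sites on a template
#'
#' Forward primers are scanned against the plus strand, reverse primers
#' against the minus strand (their reverse complement is compared to
#' plus-strand windows). A binding requires at most `max_mismatch`
#' mismatches overall and zero mismatches in the `clamp` 3'-terminal
#' primer bases. Ambiguous template bases count as mismatches.
#'
#' @param template Ungapped DNA string.
#' @param prm A [primer()].
#' @param max_mismatch Mismatch budget (default 1).
#' @param clamp Number of 3'-terminal bases that must match exactly
#'   (default 3).
#' @return data.frame with `start`, `end` (1-based inclusive
#'   plus-strand footprint), `strand`, `mismatches`,
#'   `three_prime_clamp_ok`.
#' @export
find_primer_sites <- function(template, prm, max_mismatch = 1, clamp = 3) {
  x <- toupper(template)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  L <- nchar(prm$sequence)
  n <- length(chars)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      three_prime_clamp_ok = logical(0))
  if (L > n) return(empty)
  fwd <- prm$role == "forward"
  probe <- if (fwd) prm$sequence else reverse_complement(prm$sequence)
  pchars <- strsplit(probe, "", fixed = TRUE)[[1]]
  starts <- seq_len(n - L + 1L)
  mm <- integer(length(starts))
  clamp_mm <- integer(length(starts))
  # primer 3' end sits at the right edge of a forward footprint but at
  # the LEFT edge of a reverse footprint (probe is the revcomp)
  clamp_idx <- if (fwd) (L - clamp + 1L):L else 1L:clamp
  for (k in seq_len(L)) {
    bad <- chars[starts + k - 1L] != pchars[k]
    mm <- mm + bad
    if (k %in% clamp_idx) clamp_mm <- clamp_mm + bad
  }
  ok <- mm <= max_mismatch & clamp_mm == 0L
  data.frame(start = starts[ok], end = starts[ok] + L - 1L,
             strand = rep(if (fwd) "+" else "-", sum(ok)),
             mismatches = mm[ok],
             three_prime_clamp_ok = rep(TRUE, sum(ok)),
             stringsAsFactors = FALSE)
}

#' In-silico PCR
#'
#' Enumerates all forward x reverse binding pairs with the forward
#' footprint 5' of the reverse footprint and a product length within
#' `[min_len, max_len]`. The product sequence has both primer regions
#' overwritten by the primer bases (the reverse primer as its reverse
#' complement) - this is what the physical PCR product contains, and it
#' is essential for correct digestion of products of
#' mismatch-engineered primers.
#'
#' @param template Ungapped DNA string.
#' @param fwd,rev Forward and reverse [primer()]s.
#' @param max_mismatch,clamp Binding constraints (defaults 1 / 3).
#' @param min_len,max_len Product length window (defaults 50 / 2000).
#' @param template_id Optional template label carried on each amplicon.
#' @return List of amplicons, each a list with `template_id`, `start`,
#'   `end`, `length` and `product`; empty list = no amplification.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_mismatch = 1, clamp = 3,
                          min_len = 50, max_len = 2000,
                          template_id = NA_character_) {
  stopifnot(fwd$role == "forward", rev$role == "reverse")
  fb <- find_primer_sites(template, fwd, max_mismatch, clamp)
  rb <- find_primer_sites(template, rev, max_mismatch, clamp)
  out <- list()
  if (!nrow(fb) || !nrow(rb)) return(out)
  rev_rc <- reverse_complement(rev$sequence)
  for (i in seq_len(nrow(fb))) {
    for (j in seq_len(nrow(rb))) {
      if (fb$end[i] >= rb$start[j]) next
      len <- rb$end[j] - fb$start[i] + 1L
      if (len < min_len || len > max_len) next
      product <- substr(template, fb$start[i], rb$end[j])
      substr(product, 1L, nchar(fwd$sequence)) <- fwd$sequence
      substr(product, len - nchar(rev_rc) + 1L, len) <- rev_rc
      out[[length(out) + 1L]] <- list(template_id = template_id,
                                      start = fb$start[i], end = rb$end[j],
                                      length = len, product = product)
    }
  }
  out
}

#' Differential digestion across a library
#'
#' Runs [in_silico_pcr()] plus [digest()] for every sample, collapses
#' samples to a per-species consensus (discordant species are flagged
#' ambiguous with a warning), and summarizes whether the target is
#' uniquely both amplified and cut - the assay's readout. Samples with
#' several amplicons are scored as cut if any amplicon is cut.
#'
#' @param templates Named character vector of ungapped templates.
#' @param table Sample metadata data.frame.
#' @param fwd,rev [primer()]s.
#' @param enz An [enzyme()].
#' @param target Target species label.
#' @param ... Constraints passed to [in_silico_pcr()].
#' @return Object of class `assay_design` with `per_sample`,
#'   `per_species`, `discriminates`, `fwd`, `rev`, `enzyme`, `target`.
#' @export
differential_digestion <- function(templates, table, fwd, rev, enz,
                                   target, ...) {
  stopifnot(length(templates) > 0, !is.null(names(templates)))
  if (length(unique(table$species)) < 2L) {
    stop("library must contain >= 2 species for discrimination",
         call. = FALSE)
  }
  rows <- lapply(names(templates), function(id) {
    amps <- in_silico_pcr(templates[[id]], fwd, rev, template_id = id, ...)
    sp <- table$species[match(id, table$sample_id)]
    grp <- table$group[match(id, table$sample_id)]
    if (!length(amps)) {
      return(data.frame(sample_id = id, species = sp, group = grp,
                        amplifies = FALSE, amplicon_length = NA_integer_,
                        cut = NA, fragments = NA_character_,
                        stringsAsFactors = FALSE))
    }
    digs <- lapply(amps, digest, enz = enz)
    cut <- any(vapply(digs, function(d) length(d$fragments) > 1L,
                      logical(1)))
    best <- which(vapply(digs, function(d) length(d$fragments),
                         integer(1)) > 1L)
    show <- if (length(best)) best[1] else 1L
    data.frame(sample_id = id, species = sp, group = grp,
               amplifies = TRUE, amplicon_length = amps[[show]]$length,
               cut = cut,
               fragments = paste(digs[[show]]$fragments, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)

  per_species <- do.call(rbind, lapply(split(per_sample,
                                             per_sample$species),
    function(g) {
      key <- paste(g$amplifies, g$fragments)
      ambiguous <- length(unique(key)) > 1L
      data.frame(species = g$species[1], group = g$group[1],
                 amplifies = all(g$amplifies),
                 cut = isTRUE(all(g$cut)),
                 fragments = if (ambiguous) NA_character_ else
                   g$fragments[1],
                 ambiguous = ambiguous, stringsAsFactors = FALSE)
    }))
  rownames(per_species) <- NULL
  if (any(per_species$ambiguous)) {
    warning("discordant within-species assay outcomes: ",
            paste(per_species$species[per_species$ambiguous],
                  collapse = ", "), call. = FALSE)
  }
  tgt <- per_species[per_species$species == target, , drop = FALSE]
  non <- per_species[per_species$species != target, , drop = FALSE]
  discriminates <- nrow(tgt) == 1L && tgt$amplifies && tgt$cut &&
    !any(non$amplifies & non$cut %in% TRUE)
  structure(list(per_sample = per_sample, per_species = per_species,
                 discriminates = discriminates, fwd = fwd, rev = rev,
                 enzyme = enz, target = target),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("PCR-RFLP assay: %s/%s + %s; target %s; discriminates: %s\n",
              x$fwd$name, x$rev$name, x$enzyme$name, x$target,
              x$discriminates))
  print(x$per_species)
  invisible(x)
}

#' Text gel schematic for an assay design
#'
#' Species-by-fragment-length table mimicking a gel readout.
#'
#' @param design An `assay_design`.
#' @return Character vector of lines (invisibly); also printed.
#' @export
gel_schematic <- function(design) {
  ps <- design$per_species
  lines <- c(sprintf("%-24s %-8s %s", "species", "PCR", "fragments (bp)"),
             sprintf("%-24s %-8s %s", ps$species,
                     ifelse(ps$amplifies, "+", "-"),
                     ifelse(ps$amplifies, ps$fragments, "no product")))
  cat(lines, sep = "\n")
  invisible(lines)
}

# enzyme sites of `product` overlapping the interval [from, to]
sites_overlapping <- function(product, enz, from, to) {
  hits <- find_motif_sites(product, enz, both_strands = TRUE)
  mlen <- nchar(enz$motif)
  hits[hits$start <= to & (hits$start + mlen - 1L) >= from, , drop = FALSE]
}

#' Engineer a primer to destroy a restriction site under its footprint
#'
#' Starting from the primer read off a reference template footprint,
#' enumerates substitution variants (up to `budget` substituted bases)
#' such that (i) every template's amplicon loses all enzyme sites
#' overlapping the primer footprint, (ii) the primer still binds every
#' template within `max_mismatch` mismatches with an intact 3' clamp,
#' and (iii) no new enzyme site appears anywhere in any product.
#' Proposals are ranked by fewest substitutions, then by distance of
#' the substitutions from the 3' end (farther preferred). The original
#' primer is returned unchanged when no overlapping site exists.
#'
#' @param templates Named character vector of ungapped templates that
#'   must keep amplifying.
#' @param footprint Integer `c(start, end)` plus-strand interval of the
#'   primer footprint on the reference template.
#' @param enz An [enzyme()].
#' @param budget Maximum substitutions (>= 1, default 1).
#' @param fwd The forward [primer()] completing the pair.
#' @param ref Reference template name (default: first).
#' @param name Name given to engineered primers.
#' @param max_mismatch,clamp,min_len,max_len PCR constraints.
#' @return List of proposals, each with `primer`, `n_subs`,
#'   `positions` (5'-based substitution positions) and
#'   `min_3prime_distance`; an empty list carries a per-constraint
#'   `failure_tally` attribute.
#' @export
engineer_primer <- function(templates, footprint, enz, budget = 1, fwd,
                            ref = names(templates)[1], name = "PR",
                            max_mismatch = 1, clamp = 3,
                            min_len = 50, max_len = 2000) {
  stopifnot(budget >= 1, length(footprint) == 2)
  base_seq <- reverse_complement(substr(templates[[ref]], footprint[1],
                                        footprint[2]))
  L <- nchar(base_seq)
  base_prm <- primer(name, base_seq, "reverse")

  evaluate <- function(prm) {
    # returns NULL on success or a failure-class string
    for (id in names(templates)) {
      amps <- in_silico_pcr(templates[[id]], fwd, prm,
                            max_mismatch = max_mismatch, clamp = clamp,
                            min_len = min_len, max_len = max_len,
                            template_id = id)
      if (!length(amps)) return("no_amplicon")
      for (amp in amps) {
        plen <- amp$length
        foot_from <- plen - L + 1L
        if (nrow(sites_overlapping(amp$product, enz, foot_from, plen))) {
          return("footprint_site_remains")
        }
        # (iii): candidate product sites must be exactly the template's
        # interior sites (between the primer footprints)
        interior_from <- amp$start + nchar(fwd$sequence)
        interior_to <- amp$end - L
        tmpl_hits <- find_motif_sites(templates[[id]], enz)
        mlen <- nchar(enz$motif)
        tmpl_interior <- tmpl_hits$start[
          tmpl_hits$start >= interior_from &
          (tmpl_hits$start + mlen - 1L) <= interior_to]
        allowed <- sort(tmpl_interior - amp$start + 1L)
        got <- sort(find_motif_sites(amp$product, enz)$start)
        if (!identical(as.integer(got), as.integer(allowed))) {
          return("new_site")
        }
      }
    }
    NULL
  }

  # clean case: original primer already satisfies all constraints
  if (is.null(evaluate(base_prm))) {
    return(list(list(primer = base_prm, n_subs = 0L, positions = integer(0),
                     min_3prime_distance = Inf)))
  }

  tally <- c(clamp_mismatch = 0L, no_amplicon = 0L,
             footprint_site_remains = 0L, new_site = 0L)
  proposals <- list()
  bases <- c("A", "C", "G", "T")
  base_chars <- strsplit(base_seq, "", fixed = TRUE)[[1]]
  for (k in seq_len(min(budget, L))) {
    for (pos_set in combn(seq_len(L), k, simplify = FALSE)) {
      if (any(pos_set > L - clamp)) {
        tally["clamp_mismatch"] <- tally["clamp_mismatch"] + 1L
        next  # a substitution inside the clamp can never bind
      }
      alt_sets <- lapply(pos_set, function(p) setdiff(bases, base_chars[p]))
      grid <- do.call(expand.grid, c(alt_sets, stringsAsFactors = FALSE))
      for (g in seq_len(nrow(grid))) {
        cand_chars <- base_chars
        cand_chars[pos_set] <- as.character(unlist(grid[g, ]))
        cand <- primer(paste0(name, "_m", paste(pos_set, collapse = "_")),
                       paste(cand_chars, collapse = ""), "reverse")
        fail <- evaluate(cand)
        if (is.null(fail)) {
          proposals[[length(proposals) + 1L]] <- list(
            primer = cand, n_subs = k, positions = pos_set,
            min_3prime_distance = min(L - pos_set))
        } else {
          tally[fail] <- tally[fail] + 1L
        }
      }
    }
    if (length(proposals)) break  # fewest substitutions first
  }
  if (!length(proposals)) {
    return(structure(list(), failure_tally = tally))
  }
  ord <- order(vapply(proposals, `[[`, integer(1), "n_subs"),
               -vapply(proposals, `[[`, numeric(1), "min_3prime_distance"))
  proposals[ord]
}

#' Select and rank PCR-RFLP assay designs
#'
#' For each enzyme and each candidate reverse-primer footprint: build
#' the primer pair, predict per-species outcomes, and check that some
#' motif hit in the target's amplicon overlaps a diagnostic site while
#' non-target amplicons lack the site. Where a confounding site under
#' the reverse footprint spoils discrimination, primer engineering
#' ([engineer_primer()]) is attempted. Designs are ranked: clean
#' (no engineering) first, then engineered by substitution count, then
#' by the larger minimum fragment-length difference from non-target
#' patterns.
#'
#' @param templates Named character vector of ungapped full templates.
#' @param aln Library [alignment()] (for diagnostic mining); its
#'   columns must correspond to template positions via `aln_offset`.
#' @param table Sample metadata data.frame.
#' @param target Target species label.
#' @param enzymes Named list of [enzyme()]s.
#' @param fwd Forward [primer()].
#' @param rev_footprints List of `c(start, end)` intervals (plus-strand
#'   coordinates on the reference target template) to try as reverse
#'   footprints.
#' @param aln_offset Template position of alignment column 1 minus 1
#'   for the reference target sample (default 0 = alignment covers the
#'   template from its first base).
#' @param budget Substitution budget for engineering (default 1).
#' @param max_mismatch,clamp,min_len,max_len PCR constraints.
#' @return Ranked list of `assay_design` objects (each with an
#'   `engineering` element); empty list carries a `diagnosis`
#'   attribute.
#' @export
select_assay <- function(templates, aln, table, target, enzymes, fwd,
                         rev_footprints, aln_offset = 0, budget = 1,
                         max_mismatch = 1, clamp = 3,
                         min_len = 50, max_len = 2000) {
  dsites <- diagnostic_sites(aln, table, target)
  t_ids <- table$sample_id[table$species == target]
  t_ids <- intersect(t_ids, names(templates))
  if (!length(t_ids)) stop("no target templates", call. = FALSE)
  ref_id <- t_ids[1]

  # map diagnostic alignment columns to reference-template positions
  ref_row <- strsplit(aln$seqs[[ref_id]], "", fixed = TRUE)[[1]]
  col_to_tpl <- cumsum(ref_row != "-") + aln_offset
  diag_tpl <- col_to_tpl[dsites$position[dsites$target_state != "-"]]

  designs <- list()
  diagnosis <- character(0)
  amplifiers <- function(fp) {
    # templates that amplify with the natural primer pair
    rev_nat <- primer("RPnat", reverse_complement(
      substr(templates[[ref_id]], fp[1], fp[2])), "reverse")
    keep <- vapply(names(templates), function(id) {
      length(in_silico_pcr(templates[[id]], fwd, rev_nat,
                           max_mismatch = max_mismatch, clamp = clamp,
                           min_len = min_len, max_len = max_len)) > 0
    }, logical(1))
    names(templates)[keep]
  }

  for (ename in names(enzymes)) {
    enz <- enzymes[[ename]]
    # the enzyme must hit the target template at a diagnostic position
    tgt_hits <- find_motif_sites(templates[[ref_id]], enz)
    mlen <- nchar(enz$motif)
    overlaps_diag <- any(vapply(tgt_hits$start, function(s) {
      any(diag_tpl >= s & diag_tpl <= s + mlen - 1L)
    }, logical(1)))
    if (!overlaps_diag) {
      diagnosis <- c(diagnosis, sprintf(
        "%s: no motif hit overlapping a diagnostic site in the target",
        ename))
      next
    }
    for (fp in rev_footprints) {
      rev_nat <- primer(sprintf("PR_%d_%d", fp[1], fp[2]),
                        reverse_complement(substr(templates[[ref_id]],
                                                  fp[1], fp[2])),
                        "reverse")
      des <- differential_digestion(templates, table, fwd, rev_nat, enz,
                                    target, max_mismatch = max_mismatch,
                                    clamp = clamp, min_len = min_len,
                                    max_len = max_len)
      if (des$discriminates) {
        des$engineering <- list(n_subs = 0L)
        designs[[length(designs) + 1L]] <- des
        next
      }
      # try to rescue with a mismatch-engineered reverse primer,
      # using only the templates that amplify with the natural pair
      amp_ids <- amplifiers(fp)
      if (!length(amp_ids)) {
        diagnosis <- c(diagnosis, sprintf(
          "%s footprint %d-%d: no template amplifies", ename, fp[1], fp[2]))
        next
      }
      props <- engineer_primer(templates[amp_ids], fp, enz, budget = budget,
                               fwd = fwd, ref = ref_id,
                               name = rev_nat$name,
                               max_mismatch = max_mismatch, clamp = clamp,
                               min_len = min_len, max_len = max_len)
      found <- FALSE
      for (pr in props) {
        des2 <- differential_digestion(templates, table, fwd, pr$primer,
                                       enz, target,
                                       max_mismatch = max_mismatch,
                                       clamp = clamp, min_len = min_len,
                                       max_len = max_len)
        if (des2$discriminates) {
          des2$engineering <- list(n_subs = pr$n_subs,
                                   positions = pr$positions)
          designs[[length(designs) + 1L]] <- des2
          found <- TRUE
          break
        }
      }
      if (!found) {
        diagnosis <- c(diagnosis, sprintf(
          "%s footprint %d-%d: no discriminating design (engineering %s)",
          ename, fp[1], fp[2],
          if (length(props)) "insufficient" else "failed"))
      }
    }
  }
  if (!length(designs)) {
    return(structure(list(), diagnosis = diagnosis))
  }
  # rank: clean first, then fewer substitutions, then larger minimum
  # fragment-length contrast against non-target species
  contrast <- vapply(designs, function(d) {
    ps <- d$per_species
    tf <- as.integer(strsplit(ps$fragments[ps$species == d$target],
                              "+", fixed = TRUE)[[1]])
    non <- ps[ps$species != d$target & ps$amplifies, , drop = FALSE]
    if (!nrow(non)) return(Inf)
    min(vapply(seq_len(nrow(non)), function(i) {
      nf <- as.integer(strsplit(non$fragments[i], "+", fixed = TRUE)[[1]])
      min(abs(outer(tf, nf, "-")))
    }, numeric(1)))
  }, numeric(1))
  nsubs <- vapply(designs, function(d) d$engineering$n_subs, integer(1))
  designs[order(nsubs, -contrast)]
}
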