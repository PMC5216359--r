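# Synthetic reference libraries and market-style query sets with the
# statistical structure the analysis assumes: a target species with
# shallow intraspecific variation, congeners at barcode-gap-breaking
# divergence, distant adulterants, two planted diagnostic characters
# (one indel, one substitution), conserved primer landing sites, a
# target-only enzyme site overlapping the diagnostic substitution, and
# a confounding enzyme site under the reverse-primer footprint shared
# by the whole target genus. Every planted feature is recorded in a
# truth ledger and protected from mutation; accidental enzyme-motif
# occurrences are scrubbed so the ledger stays true.

# fixed planted sequences (master = gapped alignment coordinates)
SYN_FWD_SEQ <- "ATGCGATACTTGGTGTGAAT"             # universal forward primer
SYN_MOTIF_TARGET <- "GCCTCATGGGC"                 # Bgl I site, target only
SYN_MOTIF_OTHER  <- "GCTTCATGGGC"                 # same region, site broken
SYN_REV_FOOT     <- "ACTGACGCCAGTCAGGCAT"         # genus-conserved reverse
                                                  #   footprint (top strand),
                                                  #   confounding site inside
SYN_REV_FOOT_AD  <- "CAGGACGTCAGTCAGGCAT"         # adulterant version: 3'
                                                  #   clamp broken, no site

#' Configuration for the synthetic library generator
#'
#' Defaults emulate a market-authentication study: a target species
#' sampled deeply (25 individuals) with mean intraspecific K2P around
#' 0.006, eleven congeners at 0.01-0.03 substitutions/site from the
#' target, ten distant adulterants, GC content 64.5%, and a
#' transition/transversion rate ratio of 4.
#'
#' @param seed Integer seed; the same config yields identical output.
#' @param n_congener_species,n_adulterant_species Species counts.
#' @param samples_per_species Samples per non-target species.
#' @param target_samples Samples of the target species.
#' @param barcode_length Target barcode length in bp (default 211; the
#'   alignment gains one column for the target's planted deletion, so
#'   non-target barcodes are one base longer).
#' @param flank_length Conserved flank on each side (default 45, >= 41
#'   so the forward primer fits; full templates then support primer
#'   binding and an amplicon of ~292 bp).
#' @param kappa Transition/transversion rate ratio (default 4).
#' @param intra_subs Expected substitutions per sampled individual
#'   relative to its species ancestor (default 0.65, giving mean
#'   pairwise intraspecific K2P of about 2 * 0.65 / 211 ~ 0.006).
#' @param congener_divergence Mean expected substitutions/site between
#'   the target and a congener (default 0.02; per-congener rates are
#'   drawn uniformly in 0.5-1.5 times this value).
#' @param genus_stem_divergence Substitutions/site on the stem branch
#'   shared by the target and its congeners (default 0.05). These
#'   shared derived states unite the genus into one supported clade
#'   relative to the distant adulterants without affecting any
#'   within-genus distance.
#' @param adulterant_divergence Substitutions/site to adulterants
#'   (default 0.25).
#' @param gc_target GC fraction of the ancestral barcode (default
#'   0.645).
#' @param amplicon_length Target-species product length of the
#'   species-specific PCR (default 292).
#' @param fragment_1 Length of the 5' restriction fragment of the
#'   target product (default 168; the 3' fragment is the remainder).
#' @param diagnostic_indel Barcode alignment column of the planted
#'   target deletion (default 68).
#' @param target_species Species label used for the target.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_congener_species = 11,
                             n_adulterant_species = 10,
                             samples_per_species = 4,
                             target_samples = 25,
                             barcode_length = 211,
                             flank_length = 45,
                             kappa = 4.0,
                             intra_subs = 0.65,
                             congener_divergence = 0.02,
                             genus_stem_divergence = 0.05,
                             adulterant_divergence = 0.25,
                             gc_target = 0.645,
                             amplicon_length = 292,
                             fragment_1 = 168,
                             diagnostic_indel = 68,
                             target_species = "target") {
  cfg <- as.list(environment())
  stopifnot(flank_length >= 41, barcode_length >= 150,
            congener_divergence > 0, congener_divergence < 1,
            adulterant_divergence > 0, adulterant_divergence < 1,
            fragment_1 + 24 < amplicon_length)
  class(cfg) <- "synthetic_config"
  cfg
}

# geometry of the planted features in master (gapped) coordinates
syn_geometry <- function(cfg) {
  flank <- cfg$flank_length
  ncol_barcode <- cfg$barcode_length + 1L          # +1: the indel column
  master_len <- 2L * flank + ncol_barcode
  fwd_start <- flank - 39L                         # 20 bp primer + 20 spacer
  fwd_cols <- fwd_start:(fwd_start + nchar(SYN_FWD_SEQ) - 1L)
  indel_col <- flank + cfg$diagnostic_indel
  rev_len <- nchar(SYN_REV_FOOT)
  # target template amplicon: fwd_start .. fwd_start + amplicon_length-1;
  # +1 converts the template end to a master column past the deletion
  rev_end <- fwd_start + cfg$amplicon_length
  rev_cols <- (rev_end - rev_len + 1L):rev_end
  motif_len <- nchar(SYN_MOTIF_TARGET)
  cut_offset <- default_enzymes()$BglI$cut_offset
  motif_start_tpl <- cfg$fragment_1 - cut_offset + fwd_start
  motif_cols <- (motif_start_tpl + 1L):(motif_start_tpl + motif_len)
  snp_col <- motif_cols[3]                         # third base of the GCC
  confound_primer_pos <- 13L                       # 5'-based primer position
  confound_start <- rev_end - confound_primer_pos + 1L
  barcode_cols <- (flank + 1L):(flank + ncol_barcode)

  g <- list(master_len = master_len, barcode_cols = barcode_cols,
            fwd_cols = fwd_cols, rev_cols = rev_cols,
            indel_col = indel_col, motif_cols = motif_cols,
            snp_col = snp_col, confound_start = confound_start)
  ok <- indel_col > max(fwd_cols) + 20L &&
    min(motif_cols) > indel_col + motif_len &&
    max(motif_cols) < min(rev_cols) - motif_len &&
    max(rev_cols) <= master_len &&
    snp_col %in% barcode_cols && min(motif_cols) %in% barcode_cols
  if (!ok) stop("planted feature placements collide; adjust the config",
                call. = FALSE)
  g
}

# K2P-process substitution of one base: transition with probability
# kappa/(kappa+2), otherwise one of the two transversions
syn_substitute <- function(base, kappa) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  if (runif(1) < kappa / (kappa + 2)) ts[[base]]
  else sample(tv[[base]], 1)
}

syn_mutate <- function(chars, free, n, kappa) {
  n <- min(n, length(free))
  if (n < 1L) return(chars)
  at <- if (length(free) == 1L) free else sample(free, n)
  for (p in at) chars[p] <- syn_substitute(chars[p], kappa)
  chars
}

# destroy non-planted enzyme motifs in a (gapped) master sequence,
# editing only unprotected fixed-motif positions
syn_scrub <- function(chars, enz, allowed_master_starts, protected) {
  mchars <- strsplit(enz$motif, "", fixed = TRUE)[[1]]
  fixed_off <- which(mchars != "N")
  master_of_tpl <- which(chars != "-")
  for (iter in 1:10) {
    tpl <- paste(chars[chars != "-"], collapse = "")
    hits <- find_motif_sites(tpl, enz, both_strands = TRUE)$start
    allowed_tpl <- match(allowed_master_starts, master_of_tpl)
    bad <- setdiff(hits, allowed_tpl[!is.na(allowed_tpl)])
    if (!length(bad)) return(chars)
    for (h in bad) {
      cols <- master_of_tpl[h + fixed_off - 1L]
      editable <- cols[!(cols %in% protected)]
      if (!length(editable)) next
      col <- editable[1]
      off <- fixed_off[match(col, cols)]
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(IUPAC_CODES[[mchars[off]]], chars[col]))[1]
      chars[col] <- repl
    }
  }
  chars
}

#' Simulate a reference barcode library with planted truth
#'
#' Draws an ancestral barcode at the configured GC content, derives the
#' target, congener and adulterant ancestors by a kappa-weighted
#' substitution process at the configured divergences, plants the
#' diagnostic characters, primer footprints and enzyme sites, then
#' draws individual samples with Poisson(`intra_subs`) private
#' substitutions. Planted features are protected from mutation, and
#' chance enzyme-motif occurrences are deterministically destroyed, so
#' the truth ledger is exact.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `records` (named ungapped full templates),
#'   `table` (sample metadata), and `truth` (master alignment, barcode
#'   frame, planted diagnostic sites, primers, enzyme, expected
#'   fragments, per-species divergences, protected position sets).
#' @export
simulate_library <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  g <- syn_geometry(cfg)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(cfg$seed)

  bases <- c("A", "C", "G", "T")
  probs <- c((1 - cfg$gc_target) / 2, cfg$gc_target / 2,
             cfg$gc_target / 2, (1 - cfg$gc_target) / 2)
  a0 <- sample(bases, g$master_len, replace = TRUE, prob = probs)

  put <- function(chars, cols, s) {
    chars[cols] <- strsplit(s, "", fixed = TRUE)[[1]]
    chars
  }
  # ancestral (non-target) states of the planted regions
  a0 <- put(a0, g$fwd_cols, SYN_FWD_SEQ)
  a0[g$indel_col] <- "G"
  a0 <- put(a0, g$motif_cols, SYN_MOTIF_OTHER)
  a0 <- put(a0, g$rev_cols, SYN_REV_FOOT)

  prot_common <- c(g$fwd_cols, g$indel_col, g$snp_col)
  prot_group <- unique(c(prot_common, g$motif_cols, g$rev_cols))
  prot_adult <- unique(c(prot_common, g$rev_cols))
  enz <- default_enzymes()$BglI
  allowed_group <- c(g$motif_cols[1], g$confound_start)
  allowed_adult <- integer(0)

  a0 <- syn_scrub(a0, enz, allowed_group, prot_group)

  # genus ancestor: shared stem substitutions unite target + congeners
  # into one clade relative to the distant adulterants
  free0 <- setdiff(intersect(which(a0 != "-"), g$barcode_cols), prot_group)
  ag <- syn_mutate(a0, free0,
                   stats::rbinom(1, length(free0),
                                 cfg$genus_stem_divergence), cfg$kappa)
  ag <- syn_scrub(ag, enz, allowed_group, prot_group)

  # target ancestor: planted deletion + diagnostic substitution (which
  # completes the target-only enzyme site)
  anc_target <- ag
  anc_target[g$indel_col] <- "-"
  anc_target <- put(anc_target, g$motif_cols, SYN_MOTIF_TARGET)

  # intraspecific variation and congener divergence act on the barcode
  # region only; the flanks model conserved rRNA context, which is what
  # keeps universal primer sites intact across the genus
  free_of <- function(chars, prot, cols = g$barcode_cols) {
    setdiff(intersect(which(chars != "-"), cols), prot)
  }

  species <- list()
  div <- numeric(0)
  species[[cfg$target_species]] <- list(anc = anc_target, group = "target",
                                        prot = prot_group,
                                        allowed = allowed_group,
                                        n = cfg$target_samples)
  for (i in seq_len(cfg$n_congener_species)) {
    d <- runif(1, 0.5, 1.5) * cfg$congener_divergence
    free <- free_of(ag, prot_group)
    nsub <- stats::rbinom(1, length(free), d)
    anc <- syn_mutate(ag, free, nsub, cfg$kappa)
    # a congener is a distinct species: force >= 1 barcode substitution
    if (all(anc[g$barcode_cols] == ag[g$barcode_cols])) {
      anc <- syn_mutate(anc, intersect(free, g$barcode_cols), 1L, cfg$kappa)
    }
    anc <- syn_scrub(anc, enz, allowed_group, prot_group)
    nm <- sprintf("congener_%02d", i)
    species[[nm]] <- list(anc = anc, group = "congener", prot = prot_group,
                          allowed = allowed_group,
                          n = cfg$samples_per_species)
    div[nm] <- d
  }
  for (i in seq_len(cfg$n_adulterant_species)) {
    # distant genera diverge across the whole template (flanks included)
    free <- free_of(a0, prot_adult, seq_len(g$master_len))
    nsub <- stats::rbinom(1, length(free), cfg$adulterant_divergence)
    anc <- syn_mutate(a0, free, nsub, cfg$kappa)
    anc <- put(anc, g$rev_cols, SYN_REV_FOOT_AD)
    anc <- syn_scrub(anc, enz, allowed_adult, prot_adult)
    nm <- sprintf("adulterant_%02d", i)
    species[[nm]] <- list(anc = anc, group = "adulterant",
                          prot = prot_adult, allowed = allowed_adult,
                          n = cfg$samples_per_species)
    div[nm] <- cfg$adulterant_divergence
  }

  master <- character(0)
  meta <- list()
  for (nm in names(species)) {
    sp <- species[[nm]]
    free <- free_of(sp$anc, sp$prot)
    for (k in seq_len(sp$n)) {
      chars <- syn_mutate(sp$anc, free, rpois(1, cfg$intra_subs), cfg$kappa)
      chars <- syn_scrub(chars, enz, sp$allowed, sp$prot)
      id <- sprintf("%s_s%02d", nm, k)
      master[id] <- paste(chars, collapse = "")
      meta[[id]] <- data.frame(sample_id = id, species = nm,
                               group = sp$group, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, meta)
  rownames(tab) <- NULL

  aln_full <- alignment(master)
  barcode_seqs <- substr(master, min(g$barcode_cols), max(g$barcode_cols))
  names(barcode_seqs) <- names(master)

  diag_truth <- data.frame(
    master_col = c(g$indel_col, g$snp_col),
    barcode_col = c(g$indel_col, g$snp_col) - (min(g$barcode_cols) - 1L),
    target_state = c("-", "C"),
    type = c("indel", "snp"), stringsAsFactors = FALSE)

  fwd <- primer("UNIV-F", SYN_FWD_SEQ, "forward")
  rev_nat <- primer("GENUS-R", reverse_complement(SYN_REV_FOOT), "reverse")

  truth <- list(
    master = master,
    alignment_full = aln_full,
    alignment_barcode = alignment(barcode_seqs),
    barcode_cols = c(min(g$barcode_cols), max(g$barcode_cols)),
    geometry = g,
    diagnostic = diag_truth,
    fwd = fwd, rev_natural = rev_nat,
    rev_footprint_master = c(min(g$rev_cols), max(g$rev_cols)),
    rev_footprint_target_template = c(min(g$rev_cols), max(g$rev_cols)) - 1L,
    enzyme = enz,
    expected_fragments = c(cfg$fragment_1,
                           cfg$amplicon_length - cfg$fragment_1),
    amplicon_length_target = cfg$amplicon_length,
    divergence = div,
    protected = lapply(species, `[[`, "prot"),
    allowed_motif_starts = lapply(species, `[[`, "allowed"))

  list(records = degap(master), table = tab, truth = truth, config = cfg)
}

#' Default market-survey composition for simulated products
#'
#' Mirrors a market authentication survey of 30 products: 2 authentic,
#' 12 from three congeners, 15 from five adulterant species, and one
#' two-species mixture (a `+`-joined label).
#'
#' @param lib A library from [simulate_library()].
#' @return Named integer vector (label -> product count); labels with
#'   `+` denote mixtures.
#' @export
default_market_composition <- function(lib) {
  sp <- unique(lib$table$species)
  tg <- lib$config$target_species
  need <- c("congener_01", "congener_02", "congener_03",
            "adulterant_01", "adulterant_02", "adulterant_03",
            "adulterant_04", "adulterant_05", "adulterant_06")
  if (all(need %in% sp)) {
    c(setNames(2L, tg),
      congener_01 = 9L, congener_02 = 2L, congener_03 = 1L,
      adulterant_01 = 8L, adulterant_02 = 3L, adulterant_03 = 2L,
      adulterant_04 = 1L, adulterant_05 = 1L,
      "adulterant_02+adulterant_06" = 1L)
  } else {
    others <- setdiff(sp, tg)
    out <- c(2L, rep(1L, length(others)))
    names(out) <- c(tg, others)
    out
  }
}

#' Simulate commercial-product query sequences
#'
#' Each product draws a random conspecific library individual and adds
#' Poisson(`intra_subs`) private substitutions (planted features stay
#' protected and chance enzyme sites are scrubbed, exactly as in the
#' library). A `+`-joined composition label emits one record per
#' component species under a single product id, emulating a mixed
#' product.
#'
#' @param lib A library from [simulate_library()].
#' @param composition Named counts of products per species label
#'   (default: [default_market_composition()]).
#' @param seed Integer seed.
#' @return List with `records` (named ungapped sequences), `products`
#'   (data.frame record_id, product_id, true_species) and `table`
#'   (query metadata rows).
#' @export
simulate_products <- function(lib, composition = NULL, seed = 1) {
  if (is.null(composition)) composition <- default_market_composition(lib)
  labels <- rep(names(composition), composition)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)

  cfg <- lib$config
  truth <- lib$truth
  enz <- truth$enzyme
  records <- character(0)
  rows <- list()
  if (!length(labels)) {
    return(list(records = records,
                products = data.frame(record_id = character(0),
                                      product_id = character(0),
                                      true_species = character(0)),
                table = data.frame(sample_id = character(0),
                                   species = character(0),
                                   group = character(0))))
  }
  for (k in seq_along(labels)) {
    pid <- sprintf("Y%02d", k)
    comps <- strsplit(labels[k], "+", fixed = TRUE)[[1]]
    bad <- setdiff(comps, unique(lib$table$species))
    if (length(bad)) stop("composition label(s) not in library: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (ci in seq_along(comps)) {
      sp <- comps[ci]
      pool <- lib$table$sample_id[lib$table$species == sp]
      src <- if (length(pool) == 1L) pool else sample(pool, 1)
      chars <- strsplit(truth$master[[src]], "", fixed = TRUE)[[1]]
      prot <- truth$protected[[sp]]
      bc <- truth$barcode_cols[1]:truth$barcode_cols[2]
      free <- setdiff(intersect(which(chars != "-"), bc), prot)
      chars <- syn_mutate(chars, free, rpois(1, cfg$intra_subs), cfg$kappa)
      chars <- syn_scrub(chars, enz, truth$allowed_motif_starts[[sp]], prot)
      rid <- if (length(comps) > 1L) paste0(pid, letters[ci]) else pid
      records[rid] <- paste(chars[chars != "-"], collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, product_id = pid, true_species = sp,
        stringsAsFactors = FALSE)
    }
  }
  products <- do.call(rbind, rows)
  list(records = records, products = products,
       table = data.frame(sample_id = products$record_id,
                          species = products$true_species,
                          group = "query", stringsAsFactors = FALSE))
}
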