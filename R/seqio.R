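# Sequence and metadata I/O plus shared sequence utilities.
#
# Sequences are represented throughout as named character vectors of
# uppercase residues (names are the unique sample ids); sample metadata
# lives in a separate data.frame (see read_metadata). Aligned sets are
# wrapped in a "dna_alignment" object, which fixes the 1-based column
# coordinate frame used by all downstream stages.

validate_residues <- function(seqs, allow_gaps = FALSE, context = "sequence") {
  alphabet <- if (allow_gaps) SEQ_ALPHABET else setdiff(SEQ_ALPHABET, "-")
  for (id in names(seqs)) {
    chars <- strsplit(seqs[[id]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad)) {
      stop(sprintf("invalid residue '%s' at position %d in %s '%s'",
                   chars[bad[1]], bad[1], context, id), call. = FALSE)
    }
  }
  invisible(seqs)
}

#' Read a multi-record FASTA file
#'
#' Parses a FASTA file into a named character vector of uppercase
#' residues. The header token before the first whitespace becomes the
#' record id; line breaks and internal whitespace are removed.
#'
#' @param path Path to a FASTA file.
#' @param allow_gaps Accept `-` characters (aligned input)?
#' @return Named character vector of residues (names = record ids).
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       seqtype = "DNA"),
    error = function(e) stop("empty or malformed FASTA file: ", path,
                             call. = FALSE))
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(gsub("[[:space:]]", "", vapply(recs, as.character,
                                                 character(1))))
  names(seqs) <- ids
  validate_residues(seqs, allow_gaps = allow_gaps)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of residues.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = width, as.string = TRUE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a TSV with columns `sample_id`, `species`, `group` and
#' optionally `accession`. The group must be one of `target`,
#' `congener`, `adulterant`, `query`, `unknown`.
#'
#' @param path Path to a tab-separated metadata file with a header row.
#' @return data.frame with validated columns.
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_metadata(tab)
}

#' Validate a sample metadata data.frame
#'
#' @param tab data.frame with columns sample_id, species, group.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_metadata <- function(tab) {
  need <- c("sample_id", "species", "group")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tab$species))) stop("empty species label", call. = FALSE)
  bad <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad)) {
    stop("unknown group value(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(GROUP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' GC content of a DNA sequence
#'
#' Fraction (G + C) / (A + C + G + T) over unambiguous bases only; gaps
#' and IUPAC ambiguity codes are excluded from both numerator and
#' denominator.
#'
#' @param residues A single DNA string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  total <- sum(counts)
  if (total == 0L) stop("no unambiguous bases in sequence", call. = FALSE)
  unname((counts[["G"]] + counts[["C"]]) / total)
}

#' Reverse complement with IUPAC support
#'
#' Reverses a sequence and complements every residue, including
#' ambiguity codes (R<->Y, K<->M, B<->V, D<->H; S, W, N and `-` are
#' self-complementary).
#'
#' @param residues A single DNA string (gaps allowed).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(residues) {
  x <- toupper(residues)
  validate_residues(setNames(x, "input"), allow_gaps = TRUE)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length residue strings
#'   (gaps allowed). Column coordinates are 1-based.
#' @return Object of class `dna_alignment` with elements `ids`, `seqs`
#'   and `length`.
#' @export
alignment <- function(seqs) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate ids in alignment", call. = FALSE)
  }
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) {
    stop("aligned sequences must all have the same length; got lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "), call. = FALSE)
  }
  validate_residues(seqs, allow_gaps = TRUE)
  structure(list(ids = names(seqs), seqs = seqs, length = len),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param x A `dna_alignment`.
#' @param ... Unused.
#' @return Character matrix, rows = sequences (named), columns = sites.
#' @export
as.matrix.dna_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# rebuild a dna_alignment from a character matrix
alignment_from_matrix <- function(m) {
  alignment(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

#' Remove the last n columns of an alignment
#'
#' Harmonization step for mixing full-length and 3'-truncated
#' sequences: drops the final `n` alignment columns from every record.
#'
#' @param aln A `dna_alignment`.
#' @param n Number of trailing columns to remove (`0 <= n < length`).
#' @return Trimmed `dna_alignment`.
#' @export
trim_alignment_tail <- function(aln, n) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (n < 0 || n >= aln$length) {
    stop("n must satisfy 0 <= n < alignment length (", aln$length, ")",
         call. = FALSE)
  }
  if (n == 0) return(aln)
  alignment(setNames(substr(aln$seqs, 1L, aln$length - n), aln$ids))
}

#' Strip gap characters from sequences
#'
#' @param seqs Named character vector (may contain `-`).
#' @return Named character vector without gaps.
#' @export
degap <- function(seqs) {
  setNames(gsub("-", "", seqs, fixed = TRUE), names(seqs))
}
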