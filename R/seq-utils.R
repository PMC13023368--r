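# Low-level DNA string helpers shared across modules. Sequences are plain
# upper-case character scalars/vectors; Biostrings is used only at the
# FASTA/FASTQ boundary and for translation.

DNA_BASES <- c("A", "C", "G", "T")

assert_dna <- function(x, arg = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s",
                 arg, paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGT, case-insensitive).
#' @return character vector of reverse complements, upper case.
#' @examples
#' revcomp("TCAGG")
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# all rotations of a unit, in order of rotation offset
rotations <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(unit)
  doubled <- paste0(unit, unit)
  vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), character(1))
}

# split a scalar string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards; all generator determinism rests on this
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a parent seed and a label, staying inside 32-bit
# integer range; keeps per-species / per-stage streams independent
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483629) + 1L
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# per-site substitution at `rate`; substituted base always differs from source
mutate_seq <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  ch <- seq_chars(seq)
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

# global pairwise identity of two equal-role sequences via Biostrings global
# alignment (matches / alignment length); used for worked examples and group
# summaries
#' Global pairwise identity between two sequences
#'
#' Aligns two sequences end-to-end (Needleman-Wunsch, affine gaps) and
#' reports the fraction of alignment columns that are identical matches.
#'
#' @param a,b DNA strings.
#' @return a single numeric identity in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# ---- FASTA / FASTQ helpers (Biostrings-backed) ------------------------------

# accept a named character vector, a DNAStringSet, or a path to a FASTA file;
# return a named character vector of upper-case sequences
as_genome <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x)) stop("genome must be a named character vector, DNAStringSet, or FASTA path")
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- paste0("seq", seq_along(x))
  }
  toupper(x)
}

write_fasta <- function(seqs, path, width = 80L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, width = width)
  invisible(path)
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
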