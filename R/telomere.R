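# Species-level telomere motif inference. Two evidence modes mirror common
# practice: "termini" examines fixed-width terminal windows of
# chromosome-scale assemblies (telomere-to-telomere style evidence);
# "reads" counts tandem units inside raw reads, which works without any
# assembly. Both canonicalize motifs so either strand/phase of the same
# telomere votes for one motif.

# bases of `seq` covered by any rotation of `unit` on either strand
.motif_covered <- function(seq, unit) {
  pats <- unique(c(rotations(unit), rotations(revcomp(unit))))
  n <- nchar(seq)
  p <- nchar(unit)
  covered <- logical(n)
  for (pat in pats) {
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (st in m) covered[st:(st + p - 1L)] <- TRUE
    }
  }
  sum(covered)
}

# covered-base density of a motif over a set of sequences
.motif_density <- function(seqs, unit) {
  sum(vapply(seqs, .motif_covered, numeric(1), unit = unit)) /
    sum(nchar(seqs))
}

#' Infer the species telomeric repeat motif
#'
#' In `termini` mode, tandem arrays are detected inside the two
#' `terminal_window`-nt windows of every sufficiently long sequence; each
#' chromosome end casts one vote for the canonical motif with the greatest
#' array length in that window, and motifs are ranked by (ends supporting,
#' total array length). Terminal enrichment (motif base density in terminal
#' windows over density in the whole assembly) is reported per motif. In
#' `reads` mode, tandem arrays are detected within individual reads and
#' motifs are ranked by the number of supporting reads.
#'
#' @param x in `termini` mode a genome (named character vector,
#'   `DNAStringSet`, or FASTA path); in `reads` mode a character vector of
#'   reads or a FASTQ path.
#' @param mode `"termini"` or `"reads"`.
#' @param terminal_window terminal window width in nt (default 2000).
#' @param top_k maximum number of ranked motifs returned.
#' @param min_period,max_period,min_copies,min_identity passed to
#'   [find_tandem_arrays()].
#' @param max_reads reads mode subsamples to at most this many reads.
#' @param seed seed for the reads-mode subsample.
#' @return a tibble ranked best-first with columns `canonical`, `display`,
#'   `period`, `n_ends_supporting` (termini) or `n_reads_supporting`
#'   (reads), `total_array_len`, `enrichment` (termini mode; NA otherwise)
#'   and `mode`. Zero rows when no tandem arrays are found.
#' @export
infer_motif <- function(x, mode = c("termini", "reads"),
                        terminal_window = 2000L, top_k = 5L,
                        min_period = 3L, max_period = 10L,
                        min_copies = 4, min_identity = 0.85,
                        max_reads = 1e6, seed = 1L) {
  mode <- match.arg(mode)
  empty <- tibble::tibble(canonical = character(), display = character(),
                          period = integer(),
                          n_ends_supporting = integer(),
                          n_reads_supporting = integer(),
                          total_array_len = numeric(),
                          enrichment = numeric(), mode = character())
  if (mode == "termini") {
    genome <- as_genome(x)
    long_enough <- nchar(genome) >= 2L * terminal_window
    if (!any(long_enough)) {
      stop("termini mode needs at least one sequence >= 2*terminal_window nt",
           call. = FALSE)
    }
    votes <- list()
    for (chrom in names(genome)[long_enough]) {
      s <- genome[[chrom]]
      n <- nchar(s)
      wins <- c(left  = substr(s, 1L, terminal_window),
                right = substr(s, n - terminal_window + 1L, n))
      for (wn in names(wins)) {
        arr <- find_tandem_arrays(wins[[wn]], min_period, max_period,
                                  min_copies, min_identity)
        if (nrow(arr) == 0L) next
        by_motif <- arr |>
          dplyr::group_by(.data$canonical, .data$display, .data$period) |>
          dplyr::summarise(len = sum(.data$end - .data$start),
                           .groups = "drop")
        top <- by_motif |> dplyr::slice_max(.data$len, n = 1, with_ties = FALSE)
        votes[[length(votes) + 1L]] <- dplyr::mutate(top, chromosome = chrom,
                                                     window = wn)
      }
    }
    if (length(votes) == 0L) return(empty)
    rank <- dplyr::bind_rows(votes) |>
      dplyr::group_by(.data$canonical, .data$display, .data$period) |>
      dplyr::summarise(n_ends_supporting = dplyr::n(),
                       total_array_len = sum(.data$len), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n_ends_supporting),
                     dplyr::desc(.data$total_array_len)) |>
      head(top_k)
    term <- unlist(lapply(genome[long_enough], function(s) {
      n <- nchar(s)
      c(substr(s, 1L, terminal_window), substr(s, n - terminal_window + 1L, n))
    }))
    rank$enrichment <- vapply(rank$display, function(u) {
      dg <- .motif_density(genome, u)
      if (dg == 0) return(Inf)
      .motif_density(term, u) / dg
    }, numeric(1), USE.NAMES = FALSE)
    rank$n_reads_supporting <- NA_integer_
    rank$mode <- "termini"
  } else {
    reads <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
      read_fastq_seqs(x)
    } else as.character(x)
    if (length(reads) < 1000L) {
      stop("reads mode needs at least 1000 reads", call. = FALSE)
    }
    if (length(reads) > max_reads) {
      reads <- with_seed(seed, sample(reads, max_reads))
    }
    # cheap prefilter: a qualifying array always contains >= 3 exact
    # consecutive unit copies somewhere, which a backreference regex finds
    # in C speed; only matching reads get the full detector
    pre <- sprintf("([ACGT]{%d,%d})\\1\\1", min_period, max_period)
    reads <- reads[grepl(pre, reads, perl = TRUE)]
    per_read <- lapply(reads, function(r) {
      arr <- find_tandem_arrays(r, min_period, max_period,
                                min_copies, min_identity)
      if (nrow(arr) == 0L) return(NULL)
      arr
    })
    per_read <- dplyr::bind_rows(per_read[!vapply(per_read, is.null, logical(1))],
                                 .id = "read")
    if (nrow(per_read) == 0L) return(empty)
    rank <- per_read |>
      dplyr::group_by(.data$canonical, .data$display, .data$period) |>
      dplyr::summarise(n_reads_supporting = dplyr::n_distinct(.data$read),
                       total_array_len = sum(.data$end - .data$start),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n_reads_supporting),
                     dplyr::desc(.data$total_array_len)) |>
      head(top_k)
    rank$n_ends_supporting <- NA_integer_
    rank$enrichment <- NA_real_
    rank$mode <- "reads"
  }
  dplyr::select(rank, "canonical", "display", "period",
                "n_ends_supporting", "n_reads_supporting",
                "total_array_len", "enrichment", "mode")
}
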