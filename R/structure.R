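# Conserved structural anchors of animal telomerase RNAs, detected by
# exhaustive complementarity scanning of candidate flanks: a template
# boundary hairpin (P1.1-like) just upstream of the template, and a
# crossing-helix (pseudoknot-like) pattern downstream. G-U wobble counts
# as a pair (RNA helices, DNA alphabet). These are corroborating anchors,
# not a covariance model: at permissive stem lengths chance helices are
# common in random sequence, so the flags annotate rather than filter.

# pairing matrix over a character vector (A-T, C-G and G-T wobble)
.pair_matrix <- function(ch) {
  pairable <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "C" & y == "G") | (x == "G" & y == "C") |
    (x == "G" & y == "T") | (x == "T" & y == "G")
  }
  outer(ch, ch, pairable)
}

# helices as runs along anti-diagonals of the pairing matrix:
# D[i,j] = length of the helix whose outermost pair is (i-k+1, j+k-1) and
# innermost pair (i, j); returns tibble of helices of length >= stem_min
.find_helices <- function(ch, stem_min) {
  n <- length(ch)
  if (n < 2L * stem_min + 3L) {
    return(tibble::tibble(a_start = integer(), a_end = integer(),
                          b_start = integer(), b_end = integer(),
                          len = integer()))
  }
  M <- .pair_matrix(ch)
  D <- matrix(0L, n, n)
  D[1, ] <- as.integer(M[1, ])
  for (i in 2:n) {
    prev <- c(D[i - 1L, 2:n], 0L)
    D[i, ] <- (prev + 1L) * M[i, ]
  }
  hits <- which(D >= stem_min & upper.tri(D), arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(a_start = integer(), a_end = integer(),
                          b_start = integer(), b_end = integer(),
                          len = integer()))
  }
  k <- D[hits]
  tibble::tibble(a_start = hits[, 1] - k + 1L, a_end = hits[, 1],
                 b_start = hits[, 2], b_end = hits[, 2] + k - 1L,
                 len = as.integer(k)) |>
    dplyr::filter(.data$b_start - .data$a_end >= 4L)  # >= 3-nt loop/gap
}

# hairpin with arms >= stem_min, loop <= loop_max, whose 3' arm ends within
# `anchor` nt of the sequence 3' end
.has_hairpin <- function(seq, stem_min, loop_max, anchor = 30L) {
  ch <- seq_chars(seq)
  n <- length(ch)
  h <- .find_helices(ch, stem_min)
  if (nrow(h) == 0L) return(FALSE)
  any(h$b_start - h$a_end - 1L <= loop_max & h$b_end > n - anchor)
}

# two helices with interleaved pairing intervals (i < i' < j < j')
.has_crossing <- function(seq, stem_min) {
  h <- .find_helices(seq_chars(seq), stem_min)
  if (nrow(h) < 2L) return(FALSE)
  for (i in seq_len(nrow(h))) {
    cross <- h$a_start > h$a_end[i] & h$a_end < h$b_start[i] &
             h$b_start > h$b_end[i]
    cross[i] <- FALSE
    if (any(cross)) return(TRUE)
  }
  FALSE
}

#' Check TR structural anchors in candidate flanks
#'
#' `has_p11`: a hairpin (arms of at least `stem_min` pairs, loop at most
#' `loop_max` nt, G-U allowed) whose 3' arm lies within 30 nt upstream of
#' the template 5' end (i.e. at the 3' end of `flank5`). `has_pseudoknot`:
#' two helices of at least `stem_min` pairs downstream of the template
#' (`flank3`) whose pairing intervals interleave (crossing pattern).
#' Truncated flanks give NA flags.
#'
#' @param candidates tibble with `flank5`, `flank3`, `truncated` columns.
#' @param stem_min minimum helix length in base pairs.
#' @param loop_max maximum hairpin loop length in nt.
#' @return `candidates` with logical `has_p11`, `has_pseudoknot` columns.
#' @export
structure_checks <- function(candidates, stem_min = 5L, loop_max = 30L) {
  n <- nrow(candidates)
  p11 <- rep(NA, n); pk <- rep(NA, n)
  for (i in seq_len(n)) {
    if (isTRUE(candidates$truncated[i])) next
    p11[i] <- .has_hairpin(candidates$flank5[i], stem_min, loop_max)
    pk[i] <- .has_crossing(candidates$flank3[i], stem_min)
  }
  candidates$has_p11 <- p11
  candidates$has_pseudoknot <- pk
  candidates
}
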