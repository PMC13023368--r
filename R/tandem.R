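# Tandem array detection by sliding-window period autocorrelation:
# positions where seq[i] == seq[i + p] mark p-periodic structure; maximal
# high-identity runs are extended greedily across short mismatch gaps and
# summarized by their per-phase consensus unit.

# merge rle TRUE-runs of the self-match vector across FALSE gaps while the
# pooled match fraction stays >= min_identity; returns matrix of [start,end]
# (1-based, inclusive, in m-space)
.merge_match_runs <- function(m, min_identity) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx_true <- which(r$values)
  if (length(idx_true) == 0L) return(NULL)
  out <- list()
  k <- 1L
  while (k <= length(idx_true)) {
    i <- idx_true[k]
    seg_start <- starts[i]
    seg_end <- ends[i]
    n_match <- r$lengths[i]
    k2 <- k + 1L
    while (k2 <= length(idx_true)) {
      j <- idx_true[k2]
      cand_end <- ends[j]
      cand_match <- n_match + r$lengths[j]
      if (cand_match / (cand_end - seg_start + 1L) >= min_identity) {
        seg_end <- cand_end
        n_match <- cand_match
        k2 <- k2 + 1L
      } else break
    }
    out[[length(out) + 1L]] <- c(seg_start, seg_end)
    # keep the longest pure run too: a greedy merge that drags in leading
    # noise must never lose a clean array to the consensus-identity filter
    runs <- idx_true[k:(k2 - 1L)]
    best <- runs[which.max(r$lengths[runs])]
    if (r$lengths[best] < seg_end - seg_start + 1L) {
      out[[length(out) + 1L]] <- c(starts[best], ends[best])
    }
    k <- k2
  }
  do.call(rbind, out)
}

# is `unit` a whole-number tandem of a shorter unit?
.is_reducible <- function(unit) {
  p <- nchar(unit)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L &&
        unit == paste(rep(substr(unit, 1L, q), p %/% q), collapse = "")) {
      return(TRUE)
    }
  }
  FALSE
}

#' Detect tandem repeat arrays in a DNA sequence
#'
#' Scans one sequence for tandem arrays with unit length (period) in
#' `[min_period, max_period]` using period autocorrelation (`seq[i] ==
#' seq[i+p]`) followed by greedy extension across short mismatch gaps. Each
#' array is reported with its per-phase consensus unit and the canonical
#' (strand/rotation-invariant) motif, on plus-strand coordinates regardless
#' of motif strand.
#'
#' @param seq a single DNA string.
#' @param min_period,max_period period range in nt (defaults 3-10).
#' @param min_copies minimum number of unit copies per array (>= 2).
#' @param min_identity minimum fraction of array bases matching a perfect
#'   tandem of the consensus unit.
#' @return a tibble with columns `start`, `end` (0-based half-open),
#'   `period`, `unit`, `canonical`, `display`, `copies`, `identity`,
#'   sorted by `start`; zero rows if nothing is found.
#' @examples
#' find_tandem_arrays(strrep("TCAGG", 10))
#' @export
find_tandem_arrays <- function(seq, min_period = 3L, max_period = 10L,
                               min_copies = 2, min_identity = 0.9) {
  stopifnot(min_period >= 2L, max_period >= min_period, min_copies >= 2)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_period * min_copies) {
    return(tibble::tibble(start = integer(), end = integer(),
                          period = integer(), unit = character(),
                          canonical = character(), display = character(),
                          copies = numeric(), identity = numeric()))
  }
  ch <- seq_chars(seq)
  hits <- list()
  for (p in min_period:min(max_period, n %/% 2L)) {
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    segs <- .merge_match_runs(m, min_identity)
    if (is.null(segs)) next
    for (s in seq_len(nrow(segs))) {
      a <- segs[s, 1L]            # 1-based array start
      b <- segs[s, 2L] + p        # 1-based array end (inclusive)
      len <- b - a + 1L
      if (len < min_copies * p) next
      idx <- a:b
      phase <- ((idx - a) %% p) + 1L
      unit <- vapply(seq_len(p), function(j) {
        tab <- table(ch[idx][phase == j])
        names(tab)[which.max(tab)]
      }, character(1))
      unit <- paste(unit, collapse = "")
      if (.is_reducible(unit)) next  # found again at its primitive period
      identity <- mean(ch[idx] == seq_chars(unit)[phase])
      if (identity < min_identity) next
      hits[[length(hits) + 1L]] <- list(start = a - 1L, end = b, period = p,
                                        unit = unit, len = len,
                                        identity = identity)
    }
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          period = integer(), unit = character(),
                          canonical = character(), display = character(),
                          copies = numeric(), identity = numeric()))
  }
  h <- dplyr::bind_rows(lapply(hits, tibble::as_tibble))
  # maximal non-overlapping arrays: prefer longer, then smaller period
  h <- dplyr::arrange(h, dplyr::desc(.data$len), .data$period, .data$start)
  keep <- logical(nrow(h))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(h))) {
    s <- h$start[i]; e <- h$end[i]
    if (nrow(occupied) == 0 ||
        all(e <= occupied[, 1] | s >= occupied[, 2])) {
      keep[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  h <- h[keep, , drop = FALSE]
  cm <- canonical_motif(h$unit)
  tibble::tibble(start = as.integer(h$start), end = as.integer(h$end),
                 period = as.integer(h$period), unit = h$unit,
                 canonical = cm$canonical, display = cm$display,
                 copies = (h$end - h$start) / h$period,
                 identity = h$identity) |>
    dplyr::arrange(.data$start)
}
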