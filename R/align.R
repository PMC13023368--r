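# Local alignment engine: an exact affine-gap Smith-Waterman (the oracle)
# and a word-seeded, banded-extension heuristic with BLAST-like statistics.
# Scoring follows the BLASTn-style parameterization used for cross-species
# TR flank searches: word size 11, E-value cutoff 1e-3, gap open/extend 5/2,
# and the conventional +2/-3 match/mismatch companion to those gap costs.

#' Alignment scoring scheme
#'
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param gap_open,gap_extend positive gap penalties; a k-long gap costs
#'   `gap_open + k * gap_extend`.
#' @param word_size exact-seed length in nt (translated searches use
#'   `floor(word_size / 3)` residues).
#' @param evalue_max maximum E-value retained by [seed_extend_search()].
#' @param matrix optional residue substitution matrix (rownames = alphabet)
#'   for protein scoring; when supplied, `match`/`mismatch` are ignored.
#' @return a `tq_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = 5,
                           gap_extend = 2, word_size = 11,
                           evalue_max = 1e-3, matrix = NULL) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0,
            word_size >= 4)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size,
                 evalue_max = evalue_max, matrix = matrix),
            class = "tq_scheme")
}

#' Protein scoring scheme (BLOSUM62, affine gaps)
#'
#' @inheritParams scoring_scheme
#' @export
protein_scheme <- function(gap_open = 11, gap_extend = 1, word_size = 11,
                           evalue_max = 1e-3) {
  structure(list(match = 1, mismatch = -1, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size,
                 evalue_max = evalue_max, matrix = blosum62()),
            class = "tq_scheme")
}

# BLOSUM62 table from Biostrings, loaded once
blosum62 <- function() {
  if (is.null(.tq_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tq_cache$blosum62 <- e$BLOSUM62
  }
  .tq_cache$blosum62
}

# substitution matrix + alphabet for a scheme
.scheme_matrix <- function(scheme) {
  if (!is.null(scheme$matrix)) {
    list(smat = scheme$matrix, alphabet = rownames(scheme$matrix))
  } else {
    ab <- c("A", "C", "G", "T", "N")
    smat <- matrix(scheme$mismatch, 5, 5, dimnames = list(ab, ab))
    diag(smat)[1:4] <- scheme$match
    smat["N", "N"] <- scheme$mismatch
    list(smat = smat, alphabet = ab)
  }
}

.encode <- function(s, alphabet) {
  code <- match(seq_chars(s), alphabet)
  code[is.na(code)] <- length(alphabet)  # unknowns -> last symbol
  code - 1L
}

#' Exact local alignment (Smith-Waterman, affine gaps)
#'
#' Full dynamic-programming local alignment of two plus-strand sequences.
#' Serves as the exact oracle for [seed_extend_search()].
#'
#' @param a,b sequences (DNA by default; protein if `scheme$matrix` set).
#' @param scheme a [scoring_scheme()].
#' @return a one-row tibble: `q_start`, `q_end`, `s_start`, `s_end`
#'   (0-based half-open; `a` is the query), `strand`, `score`, `evalue`
#'   (NA; statistics belong to the heuristic search), `identity`,
#'   `n_match`, `aln_len`. A zero-score empty hit when no positive-scoring
#'   alignment exists.
#' @examples
#' smith_waterman("GGTTA", "GGTTA")
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  sm <- .scheme_matrix(scheme)
  r <- .sw_kernel(.encode(toupper(a), sm$alphabet),
                  .encode(toupper(b), sm$alphabet),
                  sm$smat, scheme$gap_open, scheme$gap_extend)
  tibble::tibble(q_start = r$a_start, q_end = r$a_end,
                 s_start = r$b_start, s_end = r$b_end,
                 strand = "+", score = r$score, evalue = NA_real_,
                 identity = ifelse(r$aln_len > 0, r$n_match / r$aln_len, NA_real_),
                 n_match = r$n_match, aln_len = r$aln_len)
}

# ---- Karlin-Altschul statistics ---------------------------------------------

# ungapped lambda: solve sum_ij p_i p_j exp(lambda * s_ij) = 1 (uniform
# background over the scoring alphabet, ambiguity symbol excluded)
.ka_lambda <- function(smat, n_real) {
  s <- smat[seq_len(n_real), seq_len(n_real)]
  p <- 1 / n_real
  f <- function(l) sum(p * p * exp(l * s)) - 1
  uniroot(f, c(1e-4, 10), tol = 1e-9)$root
}

# K estimated by seeded Monte-Carlo: mean optimal local score of random
# pairs follows E[S] ~ (log(K m n) + gamma) / lambda
.ka_fit <- function(scheme) {
  key <- paste(c(scheme$match, scheme$mismatch, scheme$gap_open,
                 scheme$gap_extend, is.null(scheme$matrix)), collapse = "_")
  hit <- .tq_cache$ka[[key]]
  if (!is.null(hit)) return(hit)
  sm <- .scheme_matrix(scheme)
  n_real <- if (is.null(scheme$matrix)) 4L else 20L
  lambda <- .ka_lambda(sm$smat, n_real)
  len <- 300L
  scores <- with_seed(1234568L, {
    vapply(seq_len(60), function(i) {
      a <- sample.int(n_real, len, replace = TRUE) - 1L
      b <- sample.int(n_real, len, replace = TRUE) - 1L
      .sw_kernel(a, b, sm$smat, scheme$gap_open, scheme$gap_extend)$score
    }, numeric(1))
  })
  K <- exp(lambda * mean(scores) - 0.5772157) / (len * len)
  K <- min(max(K, 1e-6), 1)
  if (is.null(.tq_cache$ka)) .tq_cache$ka <- list()
  fit <- c(lambda = lambda, K = K)
  .tq_cache$ka[[key]] <- fit
  fit
}

.evalue <- function(score, m, n, scheme) {
  fit <- .ka_fit(scheme)
  unname(fit["K"] * m * n * exp(-fit["lambda"] * score))
}

# ---- seed-and-extend heuristic ----------------------------------------------

# all words of length w with their 0-based start positions; words containing
# `exclude` characters are dropped
.words <- function(s, w, exclude = NULL) {
  n <- nchar(s)
  if (n < w) return(list(word = character(), pos = integer()))
  pos <- 0:(n - w)
  word <- substring(s, pos + 1L, pos + w)
  if (!is.null(exclude)) {
    keep <- !grepl(exclude, word, fixed = TRUE)
    word <- word[keep]; pos <- pos[keep]
  }
  list(word = word, pos = pos)
}

# shared-word seeds between query q and subject s, one seed per diagonal
# (the one with the smallest subject position), ordered by subject position
.seeds <- function(q, s, w, exclude = NULL, max_seeds = 500L) {
  qw <- .words(q, w, exclude)
  sw <- .words(s, w, exclude)
  if (length(qw$word) == 0L || length(sw$word) == 0L) return(NULL)
  common <- intersect(qw$word, sw$word)
  if (length(common) == 0L) return(NULL)
  qi <- split(qw$pos, factor(qw$word, levels = common))
  si <- split(sw$pos, factor(sw$word, levels = common))
  pos_q <- integer(0); pos_s <- integer(0)
  for (k in seq_along(common)) {
    qq <- qi[[k]]; ss <- si[[k]]
    pos_q <- c(pos_q, rep(qq, each = length(ss)))
    pos_s <- c(pos_s, rep(ss, times = length(qq)))
  }
  dg <- pos_s - pos_q
  o <- order(dg, pos_s)
  first <- o[!duplicated(dg[o])]
  first <- first[order(pos_s[first])]
  first <- head(first, max_seeds)
  list(pos_q = pos_q[first], pos_s = pos_s[first])
}

# banded extension of one seed; returns a hit in (query, subject) 0-based
# half-open coordinates or NULL
.extend_seed <- function(qe, se, qpos, spos, sm, scheme, band = 48L) {
  qlen <- length(qe); slen <- length(se)
  ws <- max(0L, spos - qlen - 16L)
  we <- min(slen, spos + qlen + scheme$word_size + 16L)
  bwin <- se[(ws + 1L):we]
  r <- .sw_kernel(qe, bwin, sm$smat, scheme$gap_open, scheme$gap_extend,
                  banded = TRUE, diag0 = (spos - ws) - qpos, band = band)
  if (r$score <= 0) return(NULL)
  list(q_start = r$a_start, q_end = r$a_end,
       s_start = ws + r$b_start, s_end = ws + r$b_end,
       score = r$score, n_match = r$n_match, aln_len = r$aln_len)
}

# drop hits overlapping a better hit in both query and subject intervals
.dedupe_hits <- function(h) {
  if (nrow(h) <= 1L) return(h)
  h <- h[order(-h$score, h$q_start, h$s_start), ]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1]) {
    prev <- which(keep[seq_len(i - 1L)])
    ov <- h$s_start[i] < h$s_end[prev] & h$s_end[i] > h$s_start[prev] &
          h$q_start[i] < h$q_end[prev] & h$q_end[i] > h$q_start[prev]
    if (any(ov)) keep[i] <- FALSE
  }
  h[keep, ]
}

#' Seed-and-extend local similarity search
#'
#' BLAST-like search of one query against a set of subject sequences:
#' exact shared words of `scheme$word_size` seed banded affine-gap
#' extensions; overlapping hits keep the best score; hits above
#' `scheme$evalue_max` are dropped. Nucleotide mode searches both strands;
#' translated mode (protein query) searches all six subject reading frames.
#'
#' @param query a single query sequence (DNA, or protein in translated
#'   mode).
#' @param subjects named character vector, `DNAStringSet`, or FASTA path.
#' @param scheme a [scoring_scheme()] (nucleotide) or [protein_scheme()]
#'   (translated).
#' @param mode `"nucleotide"` or `"translated"`.
#' @param query_id id used in the output.
#' @return a tibble of hits: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (0-based half-open, plus strand), `strand`,
#'   `frame` (translated mode), `score`, `evalue`, `identity`, `n_match`,
#'   `aln_len`; sorted by score then `q_start`, `s_start`.
#' @export
seed_extend_search <- function(query, subjects, scheme = scoring_scheme(),
                               mode = c("nucleotide", "translated"),
                               query_id = "query") {
  mode <- match.arg(mode)
  empty <- tibble::tibble(query_id = character(), subject_id = character(),
                          q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          strand = character(), frame = integer(),
                          score = numeric(), evalue = numeric(),
                          identity = numeric(), n_match = integer(),
                          aln_len = integer())
  subjects <- as_genome(subjects)
  query <- toupper(query)
  if (mode == "nucleotide") {
    if (nchar(query) < scheme$word_size) {
      stop("query shorter than word_size", call. = FALSE)
    }
    w_eff <- scheme$word_size
    exclude <- NULL
    strands <- c("+", "-")
  } else {
    if (is.null(scheme$matrix)) scheme$matrix <- blosum62()
    w_eff <- max(3L, scheme$word_size %/% 3L)
    if (nchar(query) < w_eff) {
      stop("protein query shorter than the translated seed length", call. = FALSE)
    }
    exclude <- "*"
    strands <- "+"
  }
  sm <- .scheme_matrix(scheme)
  n_total <- sum(nchar(subjects))
  if (mode == "translated") n_total <- n_total %/% 3L
  hits <- list()
  for (sid in names(subjects)) {
    sseq <- subjects[[sid]]
    targets <- if (mode == "nucleotide") {
      list(list(seq = sseq, strand = "+", frame = NA_integer_),
           list(seq = sseq, strand = "-", frame = NA_integer_))
    } else {
      six_frames(sseq)
    }
    for (tg in targets) {
      qseq <- query
      tseq <- tg$seq
      if (mode == "nucleotide" && tg$strand == "-") qseq <- revcomp(query)
      seeds <- .seeds(qseq, tseq, w_eff, exclude)
      if (is.null(seeds)) next
      qe <- .encode(qseq, sm$alphabet)
      te <- .encode(tseq, sm$alphabet)
      local_hits <- list()
      for (k in seq_along(seeds$pos_q)) {
        qpos <- seeds$pos_q[k]; spos <- seeds$pos_s[k]
        covered <- FALSE
        for (lh in local_hits) {
          if (spos >= lh$s_start && spos < lh$s_end &&
              qpos >= lh$q_start && qpos < lh$q_end) { covered <- TRUE; break }
        }
        if (covered) next
        ext <- .extend_seed(qe, te, qpos, spos, sm, scheme)
        if (!is.null(ext)) local_hits[[length(local_hits) + 1L]] <- ext
      }
      if (length(local_hits) == 0L) next
      pull <- function(f) unlist(lapply(local_hits, `[[`, f), use.names = FALSE)
      h <- data.frame(
        q_start = as.integer(pull("q_start")), q_end = as.integer(pull("q_end")),
        s_start = as.integer(pull("s_start")), s_end = as.integer(pull("s_end")),
        score = as.numeric(pull("score")), n_match = as.integer(pull("n_match")),
        aln_len = as.integer(pull("aln_len")))
      h <- .dedupe_hits(h)
      # map back to plus-strand coordinates of query and subject
      if (mode == "nucleotide") {
        if (tg$strand == "-") {
          qlen <- nchar(query)
          qs <- qlen - h$q_end; qe2 <- qlen - h$q_start
          h$q_start <- qs; h$q_end <- qe2
        }
        h$frame <- NA_integer_
        h$strand <- tg$strand
      } else {
        nt <- aa_to_nt(h$s_start, h$s_end, tg$frame, nchar(sseq))
        h$s_start <- nt$start; h$s_end <- nt$end
        h$strand <- ifelse(tg$frame > 0, "+", "-")
        h$frame <- tg$frame
      }
      h$subject_id <- sid
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L) return(empty)
  out <- dplyr::bind_rows(hits)
  out$query_id <- query_id
  out$evalue <- .evalue(out$score, nchar(query), n_total, scheme)
  out <- out[out$evalue <= scheme$evalue_max, ]
  if (nrow(out) == 0L) return(empty)
  out |>
    dplyr::mutate(identity = .data$n_match / .data$aln_len) |>
    dplyr::select("query_id", "subject_id", "q_start", "q_end",
                  "s_start", "s_end", "strand", "frame", "score",
                  "evalue", "identity", "n_match", "aln_len") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$q_start, .data$s_start)
}

# six-frame translation of a nucleotide sequence; frames +1..+3 on the plus
# strand, -1..-3 on the reverse complement
six_frames <- function(seq) {
  rc <- revcomp(seq)
  out <- list()
  for (f in 1:3) {
    for (src in c(1, -1)) {
      s <- if (src > 0) seq else rc
      sub <- substr(s, f, f + ((nchar(s) - f + 1L) %/% 3L) * 3L - 1L)
      aa <- if (nchar(sub) >= 3L) {
        as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                           no.init.codon = TRUE))
      } else ""
      out[[length(out) + 1L]] <- list(seq = aa, strand = if (src > 0) "+" else "-",
                                      frame = src * f)
    }
  }
  out
}

# map amino-acid half-open coords in a frame back to plus-strand nt coords
aa_to_nt <- function(aa_start, aa_end, frame, nt_len) {
  f <- abs(frame)
  s <- (f - 1L) + 3L * aa_start
  e <- (f - 1L) + 3L * aa_end
  if (frame > 0) list(start = s, end = e)
  else list(start = nt_len - e, end = nt_len - s)
}
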