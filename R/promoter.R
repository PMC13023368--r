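# Type-3 snRNA-like promoter architecture: a proximal sequence element
# (PSE) scored by a position weight matrix inside an upstream window, plus
# a TATA-like element (IUPAC consensus, exact expansion match) closer to
# the transcript start. Upstream coordinates are negative, position -1
# being the last base before the start. The bundled PSE model is a
# synthetic 12-column PWM standing in for a lineage-specific consensus; it
# is user-replaceable via a plain-text PWM file (see [read_pwm()]).

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

.iupac_to_regex <- function(consensus) {
  paste(IUPAC_REGEX[seq_chars(toupper(consensus))], collapse = "")
}

# probability PWM (rows A/C/G/T) -> log2-odds vs uniform background
.pwm_logodds <- function(pwm, pseudo = 1e-3) {
  pwm <- sweep(pwm + pseudo, 2, colSums(pwm + pseudo), "/")
  log2(pwm / 0.25)
}

#' Read a plain-text position weight matrix
#'
#' Whitespace-delimited 4 x L probability matrix with rows in A/C/G/T
#' order; a leading header column of row labels (A/C/G/T) is accepted.
#'
#' @param path file path.
#' @return a 4 x L numeric matrix with rownames A/C/G/T (probabilities).
#' @export
read_pwm <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (is.character(raw[[1]])) {
    rn <- toupper(raw[[1]]); raw <- raw[, -1, drop = FALSE]
  } else rn <- DNA_BASES
  m <- as.matrix(raw)
  mode(m) <- "numeric"
  rownames(m) <- rn
  m[DNA_BASES, , drop = FALSE]
}

# default synthetic PSE probability matrix: the planted consensus with
# 0.85 weight on the consensus base per column
.default_pse_pwm <- function() {
  if (!is.null(.tq_cache$pse_pwm)) return(.tq_cache$pse_pwm)
  cons <- seq_chars(PSE_CONSENSUS)
  m <- matrix(0.05, 4, length(cons), dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 0.85
  .tq_cache$pse_pwm <- m
  m
}

#' Type-3 snRNA promoter model
#'
#' @param pse_pwm 4 x L probability matrix (rows A/C/G/T); default is the
#'   bundled synthetic PSE model.
#' @param tata_consensus IUPAC string for the TATA-like element.
#' @param pse_window,tata_window windows of allowed element start
#'   positions, upstream coordinates (position -1 = last base before the
#'   transcript start).
#' @param pse_min_score minimum PWM log-odds score; default 80% of the
#'   maximum attainable score.
#' @return a `tq_promoter_model` list with the log-odds PWM.
#' @export
promoter_model <- function(pse_pwm = NULL, tata_consensus = "TATAWAW",
                           pse_window = c(-80L, -40L),
                           tata_window = c(-40L, -20L),
                           pse_min_score = NULL) {
  pwm <- .pwm_logodds(pse_pwm %||% .default_pse_pwm())
  max_score <- sum(apply(pwm, 2, max))
  structure(list(pse_pwm = pwm,
                 tata_consensus = toupper(tata_consensus),
                 tata_regex = .iupac_to_regex(tata_consensus),
                 pse_window = as.integer(pse_window),
                 tata_window = as.integer(tata_window),
                 pse_min_score = pse_min_score %||% (0.8 * max_score),
                 pse_max_score = max_score),
            class = "tq_promoter_model")
}

# score PWM at every allowed start offset of `flank` (upstream coords);
# returns list(pos, score) of the best position or NULL
.scan_pwm <- function(flank, pwm, window) {
  L <- ncol(pwm)
  n <- nchar(flank)
  offs <- seq(window[1], window[2])
  offs <- offs[n + offs + 1L >= 1L & n + offs + L <= n]
  if (length(offs) == 0L) return(NULL)
  ch <- seq_chars(flank)
  scores <- vapply(offs, function(o) {
    i0 <- n + o + 1L
    ri <- match(ch[i0:(i0 + L - 1L)], rownames(pwm))
    if (anyNA(ri)) return(-Inf)
    sum(pwm[cbind(ri, seq_len(L))])
  }, numeric(1))
  b <- which.max(scores)
  list(pos = offs[b], score = scores[b])
}

#' Scan candidate upstream flanks for type-3 snRNA promoter architecture
#'
#' Slides the PSE PWM over its upstream window and matches the TATA IUPAC
#' consensus exactly within its window, both on the TR strand of
#' `flank5`, relative to the transcript start (by default the template 5'
#' end, i.e. the end of `flank5`; pass `tss_offset` if a coverage-derived
#' start places the transcript 5' end further upstream). `type3-like`
#' requires both elements, `partial` exactly one, `none` neither.
#'
#' @param candidates tibble with a `flank5` column (TR strand).
#' @param model a [promoter_model()].
#' @param tss_offset non-negative integer: transcript start this many nt
#'   upstream of the template (shifts both windows).
#' @return `candidates` with `promoter_type`, `pse_pos`, `pse_score`,
#'   `tata_pos`, `promoter_partial_scan` columns.
#' @export
scan_promoter <- function(candidates, model = promoter_model(),
                          tss_offset = 0L) {
  n <- nrow(candidates)
  ptype <- character(n); pse_pos <- rep(NA_integer_, n)
  pse_score <- rep(NA_real_, n); tata_pos <- rep(NA_integer_, n)
  partial_scan <- logical(n)
  pse_win <- model$pse_window - tss_offset
  tata_win <- model$tata_window - tss_offset
  for (i in seq_len(n)) {
    flank <- candidates$flank5[i]
    need <- -(pse_win[1])
    partial_scan[i] <- nchar(flank) < need
    pse <- .scan_pwm(flank, model$pse_pwm, pse_win)
    has_pse <- !is.null(pse) && pse$score >= model$pse_min_score
    if (has_pse) { pse_pos[i] <- pse$pos + tss_offset; pse_score[i] <- pse$score }
    # TATA: exact IUPAC expansion match with start inside the window
    tlen <- nchar(model$tata_consensus)
    has_tata <- FALSE
    nf <- nchar(flank)
    for (o in seq(tata_win[1], tata_win[2])) {
      i0 <- nf + o + 1L
      if (i0 < 1L || i0 + tlen - 1L > nf) next
      if (grepl(paste0("^", model$tata_regex),
                substr(flank, i0, i0 + tlen - 1L))) {
        has_tata <- TRUE
        tata_pos[i] <- o + tss_offset
        break
      }
    }
    ptype[i] <- if (has_pse && has_tata) "type3-like"
                else if (has_pse || has_tata) "partial" else "none"
  }
  candidates$promoter_type <- ptype
  candidates$pse_pos <- pse_pos
  candidates$pse_score <- pse_score
  candidates$tata_pos <- tata_pos
  candidates$promoter_partial_scan <- partial_scan
  candidates
}
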