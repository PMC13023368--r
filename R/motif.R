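# Telomere motif canonicalization and template <-> motif correspondence.
#
# A telomeric repeat unit can be observed in any rotation phase and on either
# strand; the canonical form (lexicographic minimum over all rotations of the
# unit and of its reverse complement) makes observations comparable. The
# display form is the convention used in the literature: the G-rich strand,
# rotated so the leading run of T is maximal (e.g. TTAGG, TCAGG, TTTGGG).

# canonical string for one unit (internal scalar fast path)
.canon <- function(unit) {
  min(c(rotations(unit), rotations(revcomp(unit))))
}

# display string for one unit: G-rich strand (G-count tie broken by the
# lexicographically smaller strand), then the rotation with the longest
# leading run of T, ties lexicographic
.display <- function(unit) {
  rc <- revcomp(unit)
  g_fwd <- nchar(gsub("[^G]", "", unit))
  g_rev <- nchar(gsub("[^G]", "", rc))
  cand <- if (g_fwd > g_rev) rotations(unit)
          else if (g_rev > g_fwd) rotations(rc)
          else if (min(rotations(unit)) <= min(rotations(rc))) rotations(unit)
          else rotations(rc)
  lead_t <- vapply(cand, function(r) {
    nchar(regmatches(r, regexpr("^T*", r)))
  }, numeric(1), USE.NAMES = FALSE)
  cand <- cand[lead_t == max(lead_t)]
  min(cand)
}

#' Canonicalize telomeric repeat units
#'
#' Maps each repeat unit to a strand- and rotation-invariant canonical form
#' and to the conventional display form (G-rich strand, rotation with the
#' longest leading run of T, ties broken lexicographically). `canonical_motif`
#' is idempotent: feeding a canonical or display form back returns the same
#' canonical string.
#'
#' @param unit character vector of repeat units (ACGT).
#' @return a tibble with one row per input: `input`, `canonical`, `display`,
#'   `period`.
#' @examples
#' canonical_motif(c("TTAGG", "CCTAA", "GGTCA"))
#' @export
canonical_motif <- function(unit) {
  unit <- toupper(unit)
  assert_dna(unit, "motif unit")
  if (any(nchar(unit) == 0L)) stop("motif unit must be non-empty", call. = FALSE)
  tibble::tibble(
    input     = unit,
    canonical = vapply(unit, .canon, character(1), USE.NAMES = FALSE),
    display   = vapply(unit, .display, character(1), USE.NAMES = FALSE),
    period    = nchar(unit)
  )
}

# smallest period p in [min_p, max_p] whose per-phase majority-consensus
# tandem expansion matches >= min_frac of the bases; returns NULL if none
.best_period <- function(seq, min_p = 3L, max_p = 10L, min_frac = 0.9) {
  ch <- seq_chars(seq)
  n <- length(ch)
  for (p in min_p:min(max_p, n)) {
    phase <- ((seq_len(n) - 1L) %% p) + 1L
    unit <- vapply(seq_len(p), function(j) {
      tab <- table(ch[phase == j])
      names(tab)[which.max(tab)]
    }, character(1))
    frac <- mean(ch == unit[phase])
    if (frac >= min_frac) {
      return(list(period = p, unit = paste(unit, collapse = ""), identity = frac))
    }
  }
  NULL
}

#' Infer the telomeric motif encoded by a TR template region
#'
#' The template region of a telomerase RNA is (near-)complementary to the
#' telomeric repeat it templates. This reverse-complements the template,
#' finds the shortest period in 3-10 nt whose tandem consensus explains at
#' least 90% of the bases, and reports the canonical/display motif.
#'
#' @param template character vector of template-region DNA strings (each at
#'   least 1.5 repeat units long).
#' @param min_period,max_period period search range (nt).
#' @param min_match minimum fraction of template bases explained by the
#'   tandem consensus (default 0.9).
#' @return a tibble with columns `template`, `canonical`, `display`,
#'   `period`, `template_identity`.
#' @examples
#' template_to_motif("TGACCTGACCTGACC")
#' @export
template_to_motif <- function(template, min_period = 3L, max_period = 10L,
                              min_match = 0.9) {
  template <- toupper(template)
  assert_dna(template, "template")
  rows <- lapply(template, function(tp) {
    bp <- .best_period(revcomp(tp), min_period, max_period, min_match)
    if (is.null(bp)) {
      stop(sprintf("non-periodic template: no %d-%dnt unit explains >= %.0f%% of '%s'",
                   min_period, max_period, 100 * min_match, tp), call. = FALSE)
    }
    cm <- canonical_motif(bp$unit)
    tibble::tibble(template = tp, canonical = cm$canonical,
                   display = cm$display, period = bp$period,
                   template_identity = bp$identity)
  })
  dplyr::bind_rows(rows)
}

#' Idealized telomerase primer-extension product ladder
#'
#' Telomerase extends a primer by whole telomeric repeats, so an extension
#' or TRAP assay resolves as a ladder with spacing equal to the motif
#' period. Returns the expected product lengths for 1..n_repeats added
#' repeats.
#'
#' @param primer_len primer length (nt).
#' @param motif a repeat unit string or a row of [canonical_motif()].
#' @param n_repeats number of ladder rungs (>= 1).
#' @return integer vector of product lengths.
#' @examples
#' predict_extension_products(20, "TCAGG", 3)
#' @export
predict_extension_products <- function(primer_len, motif, n_repeats) {
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  period <- if (is.data.frame(motif)) motif$period[1] else nchar(motif)
  as.integer(primer_len + seq_len(n_repeats) * period)
}
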