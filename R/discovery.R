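# Template-guided TR candidate discovery and the three-criteria
# classification: (i) template matching the species telomeric repeat,
# (ii) detectable transcription, (iii) homologs in related species.

# phase-match runs of a tandem expansion of `unit` in `seq` (one strand);
# returns 0-based half-open intervals allowing <= max_mismatch substitutions
.template_runs <- function(seq, unit, min_len, max_len, max_mismatch) {
  n <- nchar(seq)
  p <- nchar(unit)
  if (n < min_len) return(NULL)
  ch <- seq_chars(seq)
  uch <- seq_chars(unit)
  out <- list()
  for (phi in seq_len(p)) {
    exp_ch <- uch[((seq_len(n) + phi - 2L) %% p) + 1L]
    m <- ch == exp_ch
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ti <- which(r$values)
    if (length(ti) == 0L) next
    k <- 1L
    while (k <= length(ti)) {
      i <- ti[k]
      seg_start <- starts[i]; seg_end <- ends[i]
      mism <- 0L
      k2 <- k + 1L
      # absorb single-base mismatch gaps up to the budget
      while (k2 <= length(ti) && mism < max_mismatch &&
             starts[ti[k2]] - seg_end - 1L <= max_mismatch - mism) {
        mism <- mism + (starts[ti[k2]] - seg_end - 1L)
        seg_end <- ends[ti[k2]]
        k2 <- k2 + 1L
      }
      len <- seg_end - seg_start + 1L
      if (len >= min_len && len <= max_len) {
        out[[length(out) + 1L]] <- c(seg_start - 1L, seg_end, mism)
      }
      k <- k2
    }
  }
  out
}

#' Scan a genome for TR template-like loci
#'
#' Finds runs of at least `min_copies` tandem copies of the reverse
#' complement of the species telomeric motif (any rotation phase, either
#' strand, up to `max_mismatch` substitutions per run) and emits candidates
#' with their flanking context oriented 5'->3' on the template-carrying
#' strand. Runs longer than `max_copies` copies (telomeric or satellite
#' arrays seen from the opposite strand) are not template candidates and
#' are skipped.
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param motif species telomeric repeat (unit string or a
#'   [canonical_motif()] row).
#' @param min_copies minimum tandem template copies (default 2.5).
#' @param max_mismatch substitutions tolerated per run (default 1).
#' @param flank flank length reported either side (default 200 nt).
#' @param max_copies maximum copies for a run to count as a template.
#' @param species optional species label carried into the output.
#' @return a tibble of candidates: `species`, `chromosome`, `start`, `end`
#'   (0-based half-open, plus strand), `strand`, `template_seq`, `copies`,
#'   `mismatches`, `flank5`, `flank3` (TR-strand 5'->3'), `truncated`,
#'   `candidate_id`.
#' @export
scan_genome_for_templates <- function(genome, motif, min_copies = 2.5,
                                      max_mismatch = 1L, flank = 200L,
                                      max_copies = 8, species = NA_character_) {
  genome <- as_genome(genome)
  display <- if (is.data.frame(motif)) motif$display[1] else
    canonical_motif(motif)$display
  p <- nchar(display)
  stopifnot(p >= 3L, p <= 10L)
  unit <- revcomp(display)
  min_len <- ceiling(min_copies * p)
  max_len <- floor(max_copies * p)
  rows <- list()
  for (cname in names(genome)) {
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") genome[[cname]] else revcomp(genome[[cname]])
      n <- nchar(sseq)
      runs <- .template_runs(sseq, unit, min_len, max_len, max_mismatch)
      for (rn in runs) {
        a <- rn[1]; b <- rn[2]   # 0-based half-open on the scanned strand
        f5 <- substr(sseq, max(1L, a - flank + 1L), a)
        f3 <- substr(sseq, b + 1L, min(n, b + flank))
        gcoord <- if (strand == "+") c(a, b) else c(n - b, n - a)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species = species, chromosome = cname,
          start = gcoord[1], end = gcoord[2], strand = strand,
          template_seq = substr(sseq, a + 1L, b),
          copies = (b - a) / p, mismatches = rn[3],
          flank5 = f5, flank3 = f3,
          truncated = nchar(f5) < flank | nchar(f3) < flank)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(species = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          strand = character(), template_seq = character(),
                          copies = numeric(), mismatches = integer(),
                          flank5 = character(), flank3 = character(),
                          truncated = logical(), candidate_id = character()))
  }
  out <- dplyr::bind_rows(rows)
  # a run found on one strand reappears reverse-complemented on the other
  # only if the motif is palindromic; merge plain coordinate overlaps
  out <- out |>
    dplyr::arrange(.data$chromosome, .data$start, dplyr::desc(.data$copies)) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(.ov = cumsum(.data$start >= dplyr::lag(cummax(.data$end),
                                                         default = -1L))) |>
    dplyr::group_by(.data$chromosome, .data$.ov) |>
    dplyr::slice_max(.data$copies, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".ov")
  out$candidate_id <- sprintf("%s:%s:%d-%d(%s)",
                              ifelse(is.na(out$species), "NA", out$species),
                              out$chromosome, out$start, out$end, out$strand)
  dplyr::arrange(out, .data$chromosome, .data$start)
}

#' Annotate template/motif concordance
#'
#' Criterion (i): does each candidate's template encode the species'
#' telomeric repeat? Decided by [template_to_motif()] on the template
#' sequence and comparison with the canonical species motif.
#'
#' @param candidates tibble from [scan_genome_for_templates()].
#' @param motif the species motif (string or [canonical_motif()] row).
#' @return `candidates` with `template_motif` and `motif_concordant`
#'   columns.
#' @export
annotate_concordance <- function(candidates, motif) {
  target <- if (is.data.frame(motif)) motif$canonical[1] else
    canonical_motif(motif)$canonical
  tm <- vapply(candidates$template_seq, function(tp) {
    tryCatch(template_to_motif(tp)$canonical, error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  candidates$template_motif <- tm
  candidates$motif_concordant <- !is.na(tm) & tm == target
  candidates
}

#' Transcript boundaries and expression from a coverage track
#'
#' Boundaries are the outermost positions of the longest run where coverage
#' is at least `threshold_frac` of the 90th-percentile coverage over the
#' locus; the expressed flag requires the median coverage inside the
#' interval to be at least 5x the median outside (and positive).
#'
#' @param track tibble with `pos` (0-based) and `coverage` for one locus
#'   region (the locus plus ~500 nt context).
#' @param locus optional `c(start, end)` interval whose 90th percentile
#'   sets the threshold (defaults to the whole track).
#' @param threshold_frac run threshold as a fraction of that percentile.
#' @param expressed_ratio inside/outside median ratio for the expressed
#'   call.
#' @return one-row tibble: `tx_start`, `tx_end` (0-based half-open; NA if
#'   no signal), `expressed`, `median_inside`, `median_outside`.
#' @export
boundary_from_coverage <- function(track, locus = NULL, threshold_frac = 0.1,
                                   expressed_ratio = 5) {
  track <- dplyr::arrange(track, .data$pos)
  ref <- if (!is.null(locus)) {
    track$coverage[track$pos >= locus[1] & track$pos < locus[2]]
  } else track$coverage
  p90 <- if (length(ref) > 0) quantile(ref, 0.9, names = FALSE) else 0
  none <- tibble::tibble(tx_start = NA_integer_, tx_end = NA_integer_,
                         expressed = FALSE, median_inside = NA_real_,
                         median_outside = NA_real_)
  if (p90 <= 0) return(none)
  above <- track$coverage >= threshold_frac * p90
  r <- rle(above)
  if (!any(r$values)) return(none)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ti <- which(r$values)
  best <- ti[which.max(r$lengths[ti])]
  i0 <- starts[best]; i1 <- ends[best]
  inside <- seq(i0, i1)
  med_in <- median(track$coverage[inside])
  med_out <- if (length(inside) < nrow(track)) {
    median(track$coverage[-inside])
  } else 0
  tibble::tibble(tx_start = track$pos[i0], tx_end = track$pos[i1] + 1L,
                 expressed = med_in > 0 & med_in >= expressed_ratio * med_out,
                 median_inside = med_in, median_outside = med_out)
}

# ---- cross-species ortholog grouping ----------------------------------------

# union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
  if (ri != rj) uf[rj] <- ri
  uf
}

#' Group TR candidates into cross-species ortholog groups
#'
#' All-vs-all search of every candidate's concatenated flanks against
#' candidates of every other species; reciprocal best hits passing the
#' scheme's E-value cutoff are single-linkage clustered. Only candidates
#' whose template is concordant with their own species motif
#' (`motif_concordant`) participate. Groups keep at most one member per
#' species (best reciprocal score wins) and groups with fewer than
#' `min_support` species are flagged unsupported.
#'
#' @param candidates tibble with `candidate_id`, `species`, `flank5`,
#'   `flank3` and `motif_concordant` columns (see
#'   [annotate_concordance()]).
#' @param scheme a [scoring_scheme()].
#' @param min_support minimum number of species for a supported group.
#' @return a list with `groups` (tibble: `ortholog_group`, `support`,
#'   `mean_flank_identity`, `supported`) and `candidates` (input plus
#'   `ortholog_group`, `ortholog_support`).
#' @export
group_orthologs <- function(candidates, scheme = scoring_scheme(),
                            min_support = 2L) {
  cand <- candidates
  cand$ortholog_group <- NA_character_
  cand$ortholog_support <- 0L
  if (length(unique(cand$species)) < 2L) {
    warning("ortholog grouping needs >= 2 species; all support = 1")
  }
  elig <- which(cand$motif_concordant %in% TRUE)
  empty_groups <- tibble::tibble(ortholog_group = character(),
                                 support = integer(),
                                 mean_flank_identity = numeric(),
                                 supported = logical())
  if (length(elig) < 2L) {
    return(list(groups = empty_groups, candidates = cand))
  }
  sub <- cand[elig, ]
  seqs <- setNames(paste0(sub$flank5, sub$flank3), sub$candidate_id)
  spp <- setNames(sub$species, sub$candidate_id)
  ids <- names(seqs)
  # best hit of each candidate within each other species
  best <- list()
  for (qi in ids) {
    for (sp_other in setdiff(unique(spp), spp[qi])) {
      targets <- seqs[spp == sp_other]
      h <- seed_extend_search(seqs[[qi]], targets, scheme, query_id = qi)
      if (nrow(h) > 0L) {
        b <- h[1, ]  # already sorted best-first
        best[[paste(qi, sp_other, sep = "\r")]] <-
          tibble::tibble(query = qi, subject = b$subject_id,
                         score = b$score, identity = b$identity)
      }
    }
  }
  if (length(best) == 0L) {
    return(list(groups = empty_groups, candidates = cand))
  }
  best <- dplyr::bind_rows(best)
  # reciprocal best hits
  key <- paste(best$query, best$subject, sep = "\r")
  rev_key <- paste(best$subject, best$query, sep = "\r")
  rbh <- best[rev_key %in% key & best$query < best$subject, ]
  if (nrow(rbh) == 0L) {
    return(list(groups = empty_groups, candidates = cand))
  }
  uf <- .uf_new(length(ids))
  idx <- setNames(seq_along(ids), ids)
  for (k in seq_len(nrow(rbh))) {
    uf <- .uf_union(uf, idx[[rbh$query[k]]], idx[[rbh$subject[k]]])
  }
  root <- vapply(seq_along(ids), function(i) .uf_find(uf, i), integer(1))
  comp <- split(ids, root)
  comp <- comp[vapply(comp, length, integer(1)) >= 2L]
  groups <- list(); members <- list()
  gi <- 0L
  for (cids in comp) {
    gi <- gi + 1L
    gid <- sprintf("OG%03d", gi)
    # best-hit rule: one member per species, by total RBH score
    sc <- vapply(cids, function(id) {
      sum(rbh$score[rbh$query == id | rbh$subject == id])
    }, numeric(1))
    keep <- unlist(lapply(split(cids, spp[cids]), function(g) {
      g[which.max(sc[g])]
    }), use.names = FALSE)
    grbh <- rbh[rbh$query %in% keep & rbh$subject %in% keep, ]
    support <- length(unique(spp[keep]))
    groups[[gi]] <- tibble::tibble(
      ortholog_group = gid, support = as.integer(support),
      mean_flank_identity = if (nrow(grbh) > 0) mean(grbh$identity) else NA_real_,
      supported = support >= min_support)
    members[[gi]] <- tibble::tibble(ortholog_group = gid, candidate_id = keep)
  }
  groups <- dplyr::bind_rows(groups)
  members <- dplyr::bind_rows(members)
  m <- match(cand$candidate_id, members$candidate_id)
  cand$ortholog_group <- members$ortholog_group[m]
  gm <- match(cand$ortholog_group, groups$ortholog_group)
  cand$ortholog_support <- ifelse(is.na(gm), 0L, groups$support[gm])
  list(groups = groups, candidates = cand)
}

#' Classify TR candidates by the three evidence criteria
#'
#' Tier HIGH requires all of (i) template/motif concordance, (ii)
#' detectable transcription, (iii) a supported cross-species ortholog
#' group; MEDIUM requires (i) plus exactly one of (ii)/(iii); LOW is (i)
#' only. Candidates failing (i) are dropped. Structural and promoter flags
#' are annotated as corroborating evidence but do not move tiers.
#'
#' @param candidates tibble carrying `motif_concordant`, `expressed`
#'   (logical, NA = unknown), and `ortholog_support` columns; optional
#'   `has_p11`, `has_pseudoknot`, `promoter_type` columns are carried
#'   through.
#' @param min_support ortholog support needed for criterion (iii).
#' @return the concordant candidates with a `tier` column
#'   (HIGH/MEDIUM/LOW), sorted by tier then ortholog support.
#' @export
classify_candidates <- function(candidates, min_support = 2L) {
  cand <- candidates[candidates$motif_concordant %in% TRUE, , drop = FALSE]
  if (!"expressed" %in% names(cand)) cand$expressed <- NA
  if (!"ortholog_support" %in% names(cand)) cand$ortholog_support <- 0L
  crit_ii <- cand$expressed %in% TRUE
  crit_iii <- cand$ortholog_support >= min_support
  cand$tier <- dplyr::case_when(
    crit_ii & crit_iii ~ "HIGH",
    crit_ii | crit_iii ~ "MEDIUM",
    TRUE ~ "LOW")
  cand$tier <- factor(cand$tier, levels = c("HIGH", "MEDIUM", "LOW"))
  dplyr::arrange(cand, .data$tier, dplyr::desc(.data$ortholog_support))
}
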