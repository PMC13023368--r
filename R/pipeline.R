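# End-to-end workflow: motif inference -> template scan -> ortholog /
# structure / promoter / expression evidence -> three-criteria
# classification -> TERT screen -> presence matrix -> Dollo loss mapping.
# Stages only communicate through the tibbles they return; rerunning with
# the same inputs and seed reproduces identical outputs.

#' Default pipeline parameters
#'
#' All thresholds in one place: terminal window 2000 nt, 200-nt flanks,
#' word size 11, E-value 1e-3, gap penalties 5/2, minimum 2.5 template
#' copies, ortholog support 2.
#'
#' @return a named list.
#' @export
pipeline_params <- function() {
  list(terminal_window = 2000L, flank = 200L, min_copies = 2.5,
       max_mismatch = 1L, max_copies = 8, min_support = 2L,
       word_size = 11L, evalue_max = 1e-3, gap_open = 5, gap_extend = 2,
       match = 2, mismatch = -3, stem_min = 5L, loop_max = 30L,
       motif_min_ends = 2L, threshold_frac = 0.1, expressed_ratio = 5,
       seed = 1L)
}

#' Run the full TR discovery and telomerase-loss workflow
#'
#' Executes, per species: telomere motif inference from assembly termini;
#' template-guided candidate scanning (species lacking an inferable motif
#' are re-scanned with every motif found elsewhere in the bundle before TR
#' is scored absent); concordance, structural, promoter and expression
#' annotation; cross-species ortholog grouping; three-criteria tier
#' classification; optional TERT screening; and Dollo loss mapping of the
#' motif/TR/TERT presence matrix on the species tree.
#'
#' @param genomes named list (per species) of genomes (named character
#'   vectors / `DNAStringSet` / FASTA paths), or a `tq_bundle`.
#' @param tree `ape::phylo` or newick string (defaults to the bundle's
#'   tree); NULL skips loss mapping.
#' @param coverage optional coverage tibble (`species`, `chromosome`,
#'   `pos`, `coverage`); absent coverage leaves expression unknown.
#' @param tert_queries optional protein queries for [screen_tert()];
#'   the bundled synthetic peptide by default.
#' @param run_tert FALSE skips the TERT screen (TERT scored unknown).
#' @param params list from [pipeline_params()] (override entries as
#'   needed).
#' @return a `tq_result` list: `motifs`, `candidates` (classified),
#'   `groups`, `presence`, `loss_events`, `params`.
#' @export
run_pipeline <- function(genomes, tree = NULL, coverage = NULL,
                         tert_queries = NULL, run_tert = TRUE,
                         params = pipeline_params()) {
  if (inherits(genomes, "tq_bundle")) {
    bundle <- genomes
    genomes <- bundle$genomes
    if (is.null(tree)) tree <- bundle$tree
  }
  if (length(genomes) == 0L) stop("no assemblies supplied", call. = FALSE)
  genomes <- lapply(genomes, as_genome)
  species <- names(genomes)
  scheme <- scoring_scheme(match = params$match, mismatch = params$mismatch,
                           gap_open = params$gap_open,
                           gap_extend = params$gap_extend,
                           word_size = params$word_size,
                           evalue_max = params$evalue_max)

  # stage 1: motif inference (termini mode)
  motifs <- dplyr::bind_rows(lapply(species, function(sp) {
    rep <- infer_motif(genomes[[sp]], mode = "termini",
                       terminal_window = params$terminal_window)
    if (nrow(rep) > 0L) dplyr::mutate(rep[1, ], species = sp)
    else tibble::tibble(species = sp)
  }))
  motif_of <- setNames(rep(NA_character_, length(species)), species)
  if ("display" %in% names(motifs)) {
    # a real telomere motif should win the vote at most chromosome ends,
    # not just recur at two of them by chance
    n_ends <- vapply(species, function(sp) {
      2L * sum(nchar(genomes[[sp]]) >= 2L * params$terminal_window)
    }, integer(1))
    need <- pmax(params$motif_min_ends, ceiling(n_ends[motifs$species] / 2))
    ok <- !is.na(motifs$display) & motifs$n_ends_supporting >= need
    motif_of[motifs$species[ok]] <- motifs$display[ok]
  }
  all_motifs <- unique(stats::na.omit(motif_of))

  # stage 2: template scan; motif-less species get the cross-species motifs
  candidates <- dplyr::bind_rows(lapply(species, function(sp) {
    scan_motifs <- if (!is.na(motif_of[[sp]])) motif_of[[sp]] else all_motifs
    dplyr::bind_rows(lapply(scan_motifs, function(m) {
      cc <- scan_genome_for_templates(genomes[[sp]], m,
                                      min_copies = params$min_copies,
                                      max_mismatch = params$max_mismatch,
                                      flank = params$flank,
                                      max_copies = params$max_copies,
                                      species = sp)
      if (nrow(cc) > 0L) cc$scan_motif <- m
      cc
    }))
  }))
  if (nrow(candidates) > 0L) {
    candidates <- dplyr::distinct(candidates, .data$candidate_id,
                                  .keep_all = TRUE)
    # criterion (i): concordance with the species' own motif
    candidates <- dplyr::bind_rows(lapply(split(candidates, candidates$species),
                                          function(cc) {
      sp <- cc$species[1]
      if (is.na(motif_of[[sp]])) {
        cc$template_motif <- NA_character_
        cc$motif_concordant <- FALSE
        cc
      } else annotate_concordance(cc, motif_of[[sp]])
    }))
    # corroborating evidence
    candidates <- structure_checks(candidates, stem_min = params$stem_min,
                                   loop_max = params$loop_max)
    candidates <- scan_promoter(candidates)
    # criterion (ii): expression from coverage
    candidates$expressed <- NA
    candidates$tx_start <- NA_integer_
    candidates$tx_end <- NA_integer_
    if (!is.null(coverage)) {
      for (i in seq_len(nrow(candidates))) {
        cc <- candidates[i, ]
        tr <- coverage[coverage$species == cc$species &
                         coverage$chromosome == cc$chromosome &
                         coverage$pos >= cc$start - 500L &
                         coverage$pos < cc$end + 700L, ]
        if (nrow(tr) == 0L) next
        bd <- boundary_from_coverage(tr, locus = c(cc$start, cc$end),
                                     threshold_frac = params$threshold_frac,
                                     expressed_ratio = params$expressed_ratio)
        candidates$expressed[i] <- bd$expressed
        candidates$tx_start[i] <- bd$tx_start
        candidates$tx_end[i] <- bd$tx_end
      }
      # species with coverage data but no signal at a candidate: FALSE
      with_cov <- unique(coverage$species)
      idx <- candidates$species %in% with_cov & is.na(candidates$expressed)
      candidates$expressed[idx] <- FALSE
    }
    # criterion (iii): ortholog grouping
    og <- group_orthologs(candidates, scheme, min_support = params$min_support)
    groups <- og$groups
    candidates <- og$candidates
    classified <- classify_candidates(candidates,
                                      min_support = params$min_support)
  } else {
    groups <- tibble::tibble()
    classified <- candidates
  }

  # stage 3: TERT screen
  tert_status <- setNames(rep("unknown", length(species)), species)
  if (isTRUE(run_tert)) {
    for (sp in species) {
      tert_status[[sp]] <- screen_tert(genomes[[sp]], tert_queries)$status
    }
  }

  # stage 4: presence matrix + Dollo losses
  tr_present <- vapply(species, function(sp) {
    if (nrow(classified) == 0L) return("absent")
    tiers <- classified$tier[classified$species == sp]
    if (any(tiers %in% c("HIGH", "MEDIUM"))) "present" else "absent"
  }, character(1))
  presence <- tibble::tibble(
    species = species,
    telomere_motif = ifelse(is.na(motif_of), "absent", "present"),
    tr = tr_present,
    tert = unname(tert_status))
  presence <- classify_status(presence)
  loss_events <- if (!is.null(tree)) {
    pr <- presence
    pr$tert[pr$tert == "unknown"] <- "unknown"
    map_telomerase_losses(pr, tree)
  } else tibble::tibble()

  structure(list(motifs = motifs, candidates = classified, groups = groups,
                 presence = presence, loss_events = loss_events,
                 params = params),
            class = "tq_result")
}

#' @export
print.tq_result <- function(x, ...) {
  cat("teloquest result:", nrow(x$presence), "species,",
      nrow(x$candidates), "classified TR candidates",
      sprintf("(%d HIGH)", sum(x$candidates$tier == "HIGH")), "\n")
  print(x$presence)
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' TSV reports for motifs, candidates, presence/status and loss events,
#' plus candidates as GFF3.
#'
#' @param result a `tq_result`.
#' @param dir output directory (created).
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(result$motifs, "motifs.tsv")
  cand <- result$candidates
  if (nrow(cand) > 0L) {
    wt(dplyr::select(cand, -dplyr::any_of(c("flank5", "flank3"))),
       "candidates.tsv")
    write_gff3(dplyr::select(cand, "chromosome", "start", "end", "strand",
                             "candidate_id", "species", "tier"),
               file.path(dir, "candidates.gff3"), type = "TR_candidate")
  } else {
    wt(cand, "candidates.tsv")
  }
  wt(result$presence, "presence.tsv")
  wt(result$loss_events, "loss_events.tsv")
  invisible(dir)
}
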