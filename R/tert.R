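# TERT screening: six-frame translated homology search of an assembly
# against one or more protein queries. A genuine TERT signal shows hits in
# distinct regions of the query (the spread-out reverse-transcriptase
# motifs); a single spurious HSP does not. A strict pass at the scheme's
# E-value cutoff is followed, before absence is declared, by a relaxed
# pass at a raised cutoff.

#' Screen an assembly for TERT-like coding sequence
#'
#' Each query protein is searched against all six reading frames of every
#' contig ([seed_extend_search()], translated mode). The assembly is
#' called `present` if, for any query, the merged query intervals of
#' passing hits either number at least `min_hits` (distinct query regions,
#' e.g. separate RT motifs) or jointly cover at least half the query.
#' If the strict pass fails, a relaxed pass with `relaxed_evalue` is run
#' before `absent` is declared; both passes are reported.
#'
#' @param assembly named character vector / `DNAStringSet` / FASTA path.
#' @param queries protein queries (named character vector, `AAStringSet`,
#'   or FASTA path); defaults to the bundled synthetic query peptide.
#' @param scheme a [protein_scheme()].
#' @param min_hits distinct query regions required (default 2).
#' @param relaxed_evalue E-value cutoff of the second pass.
#' @return a list of class `tq_tert_screen`: `status` ("present"/"absent"),
#'   `pass` which pass decided, `hits` (tibble with a `pass` column),
#'   `per_query` summary tibble.
#' @export
screen_tert <- function(assembly, queries = NULL, scheme = protein_scheme(),
                        min_hits = 2L, relaxed_evalue = 1e-1) {
  assembly <- tryCatch(as_genome(assembly), error = function(e) character(0))
  if (length(assembly) == 0L || all(nchar(assembly) == 0L)) {
    warning("empty assembly; TERT scored absent")
    return(structure(list(status = "absent", pass = NA_character_,
                          hits = NULL, per_query = NULL),
                     class = "tq_tert_screen"))
  }
  if (is.null(queries)) {
    queries <- c(tert_query_synthetic = tert_query_peptide())
  } else if (is.character(queries) && length(queries) == 1L &&
             is.null(names(queries)) && file.exists(queries)) {
    queries <- setNames(
      as.character(Biostrings::readAAStringSet(queries)),
      names(Biostrings::readAAStringSet(queries)))
  } else if (methods::is(queries, "AAStringSet")) {
    queries <- setNames(as.character(queries), names(queries))
  }
  run_pass <- function(evalue_max, label) {
    sch <- scheme
    sch$evalue_max <- evalue_max
    hits <- dplyr::bind_rows(lapply(names(queries), function(qid) {
      seed_extend_search(queries[[qid]], assembly, sch,
                         mode = "translated", query_id = qid)
    }))
    if (nrow(hits) > 0L) hits$pass <- label
    hits
  }
  decide <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0L) {
      return(tibble::tibble(query_id = names(queries),
                            n_regions = 0L, query_coverage = 0,
                            qualifies = FALSE))
    }
    dplyr::bind_rows(lapply(names(queries), function(qid) {
      h <- hits[hits$query_id == qid, ]
      if (nrow(h) == 0L) {
        return(tibble::tibble(query_id = qid, n_regions = 0L,
                              query_coverage = 0, qualifies = FALSE))
      }
      iv <- h[order(h$q_start), c("q_start", "q_end")]
      merged <- list(c(iv$q_start[1], iv$q_end[1]))
      for (k in seq_len(nrow(iv))[-1]) {
        last <- merged[[length(merged)]]
        if (iv$q_start[k] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], iv$q_end[k]))
        } else merged[[length(merged) + 1L]] <- c(iv$q_start[k], iv$q_end[k])
      }
      covered <- sum(vapply(merged, diff, numeric(1))) / nchar(queries[[qid]])
      tibble::tibble(query_id = qid, n_regions = length(merged),
                     query_coverage = covered,
                     qualifies = length(merged) >= min_hits | covered >= 0.5)
    }))
  }
  strict_hits <- run_pass(scheme$evalue_max, "strict")
  strict <- decide(strict_hits)
  if (any(strict$qualifies)) {
    return(structure(list(status = "present", pass = "strict",
                          hits = strict_hits, per_query = strict),
                     class = "tq_tert_screen"))
  }
  relaxed_hits <- run_pass(relaxed_evalue, "relaxed")
  relaxed <- decide(relaxed_hits)
  status <- if (any(relaxed$qualifies)) "present" else "absent"
  structure(list(status = status, pass = "relaxed",
                 hits = dplyr::bind_rows(strict_hits, relaxed_hits),
                 per_query = relaxed),
            class = "tq_tert_screen")
}

#' @export
print.tq_tert_screen <- function(x, ...) {
  cat("TERT screen:", x$status,
      sprintf("(decided by %s pass)\n", x$pass %||% "no"), sep = " ")
  if (!is.null(x$per_query)) print(x$per_query)
  invisible(x)
}
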