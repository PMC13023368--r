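# broom-style accessors for fitted/derived objects

#' Tidy a pipeline result into its candidate table
#'
#' @param x a `tq_result`.
#' @param ... unused.
#' @return the classified candidate tibble.
#' @export
tidy.tq_result <- function(x, ...) x$candidates

#' One-row summary of a pipeline run
#'
#' @param x a `tq_result`.
#' @param ... unused.
#' @return a one-row tibble: species counts, candidate/tier counts, loss
#'   events.
#' @export
glance.tq_result <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$presence),
    n_candidates = nrow(x$candidates),
    n_high = sum(x$candidates$tier == "HIGH"),
    n_medium = sum(x$candidates$tier == "MEDIUM"),
    n_low = sum(x$candidates$tier == "LOW"),
    n_groups = if (is.null(x$groups) || nrow(x$groups) == 0L) 0L
               else sum(x$groups$supported),
    n_loss_species = sum(x$presence$status == "putative telomerase loss"),
    n_loss_events = nrow(x$loss_events))
}

#' Tidy a TERT screen into its hit table
#'
#' @param x a `tq_tert_screen`.
#' @param ... unused.
#' @export
tidy.tq_tert_screen <- function(x, ...) {
  if (is.null(x$hits)) return(tibble::tibble())
  x$hits
}

#' One-row summary of a TERT screen
#'
#' @param x a `tq_tert_screen`.
#' @param ... unused.
#' @export
glance.tq_tert_screen <- function(x, ...) {
  pq <- x$per_query
  tibble::tibble(status = x$status, pass = x$pass,
                 n_hits = if (is.null(x$hits)) 0L else nrow(x$hits),
                 max_regions = if (is.null(pq)) 0L else max(pq$n_regions),
                 max_query_coverage = if (is.null(pq)) 0 else
                   max(pq$query_coverage))
}
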