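# On-disk bundle layout and interval-format writers. Internal coordinates
# are BED-style 0-based half-open; GFF3 output converts to 1-based
# inclusive at this boundary and nowhere else.

# 0-based half-open -> GFF3 1-based inclusive
to_gff3_coords <- function(start, end) list(start = start + 1L, end = end)
# GFF3 1-based inclusive -> 0-based half-open
from_gff3_coords <- function(start, end) list(start = start - 1L, end = end)

#' Write genomic intervals as GFF3
#'
#' @param df tibble with `chromosome`, `start`, `end` (0-based half-open),
#'   optional `strand`, plus any other columns (emitted as attributes).
#' @param path output path.
#' @param source,type GFF3 source and type fields.
#' @export
write_gff3 <- function(df, path, source = "teloquest", type = "region") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) == 0L) return(invisible(path))
  g <- to_gff3_coords(df$start, df$end)
  extra <- setdiff(names(df), c("chromosome", "start", "end", "strand"))
  attrs <- vapply(seq_len(nrow(df)), function(i) {
    kv <- vapply(extra, function(col) {
      paste0(col, "=", as.character(df[[col]][i]))
    }, character(1))
    paste(kv, collapse = ";")
  }, character(1))
  lines <- paste(df$chromosome, source,
                 if ("type" %in% names(df)) df$type else type,
                 g$start, g$end, ".",
                 if ("strand" %in% names(df)) df$strand else ".",
                 ".", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param df tibble with `chromosome`, `start`, `end`, optional `name`,
#'   `strand`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  name <- if ("name" %in% names(df)) df$name else
    if ("type" %in% names(df)) df$type else "."
  lines <- paste(df$chromosome, df$start, df$end, name, 0,
                 if ("strand" %in% names(df)) df$strand else ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a coverage tibble as BedGraph
#'
#' Consecutive equal-coverage positions are collapsed into intervals.
#'
#' @param track tibble with `chromosome`, `pos` (0-based), `coverage`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in unique(track$chromosome)) {
    t2 <- track[track$chromosome == cn, ]
    t2 <- t2[order(t2$pos), ]
    brk <- c(TRUE, diff(t2$pos) != 1L | diff(t2$coverage) != 0)
    grp <- cumsum(brk)
    st <- tapply(t2$pos, grp, min)
    en <- tapply(t2$pos, grp, max) + 1L
    cv <- tapply(t2$coverage, grp, function(x) x[1])
    writeLines(paste(cn, st, en, format(cv, trim = TRUE, digits = 6),
                     sep = "\t"), con)
  }
  invisible(path)
}

read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chromosome", "start", "end", "coverage"))
  dplyr::bind_rows(lapply(seq_len(nrow(df)), function(i) {
    tibble::tibble(chromosome = df$chromosome[i],
                   pos = seq(df$start[i], df$end[i] - 1L),
                   coverage = df$coverage[i])
  }))
}

#' Write a synthetic bundle to a directory
#'
#' Emits per-species genome FASTA, the species tree (newick), the truth
#' tables (TSV), truth loci as GFF3 (1-based) and BED (0-based), and, when
#' supplied, coverage tracks (BedGraph) and reads (FASTQ).
#'
#' @param bundle a `tq_bundle` from [generate_dataset()].
#' @param dir output directory (created).
#' @param coverage optional tibble from [simulate_coverage_track()].
#' @param reads optional named list of per-species read tibbles.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, coverage = NULL, reads = NULL) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (sp in names(bundle$genomes)) {
    write_fasta(bundle$genomes[[sp]], file.path(dir, "genomes", paste0(sp, ".fa")))
  }
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  tr <- bundle$truth
  for (nm in c("species", "loci", "promoters", "tert_loci", "telomeres")) {
    write.table(tr[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(tr$loss_clade, file.path(dir, "truth", "loss_clade.txt"))
  if (nrow(tr$loci) > 0L) {
    write_gff3(tr$loci, file.path(dir, "truth", "loci.gff3"))
    write_bed(dplyr::mutate(tr$loci, name = paste(.data$species, .data$type,
                                                  sep = "_")),
              file.path(dir, "truth", "loci.bed"))
  }
  if (!is.null(coverage)) {
    dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
    for (sp in unique(coverage$species)) {
      write_bedgraph(coverage[coverage$species == sp, ],
                     file.path(dir, "coverage", paste0(sp, ".bedgraph")))
    }
  }
  if (!is.null(reads)) {
    dir.create(file.path(dir, "reads"), showWarnings = FALSE)
    for (sp in names(reads)) {
      write_fastq(reads[[sp]], file.path(dir, "reads", paste0(sp, ".fastq")))
    }
  }
  invisible(dir)
}

#' Load a bundle directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a list with `genomes`, `tree`, `coverage` (NULL if absent),
#'   `reads_paths`, `truth` (NULL if absent).
#' @export
load_bundle <- function(dir) {
  fa <- list.files(file.path(dir, "genomes"), pattern = "\\.fa$",
                   full.names = TRUE)
  genomes <- setNames(lapply(fa, as_genome),
                      sub("\\.fa$", "", basename(fa)))
  tree <- if (file.exists(file.path(dir, "tree.nwk"))) {
    ape::read.tree(file.path(dir, "tree.nwk"))
  } else NULL
  cov_files <- list.files(file.path(dir, "coverage"),
                          pattern = "\\.bedgraph$", full.names = TRUE)
  coverage <- if (length(cov_files) > 0L) {
    dplyr::bind_rows(lapply(cov_files, function(f) {
      dplyr::mutate(read_bedgraph(f),
                    species = sub("\\.bedgraph$", "", basename(f)))
    }))
  } else NULL
  truth <- NULL
  loci_tsv <- file.path(dir, "truth", "loci.tsv")
  if (file.exists(loci_tsv)) {
    truth <- list(
      loci = tibble::as_tibble(read.table(loci_tsv, sep = "\t", header = TRUE,
                                          stringsAsFactors = FALSE)),
      species = tibble::as_tibble(read.table(file.path(dir, "truth", "species.tsv"),
                                             sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE)),
      loss_clade = readLines(file.path(dir, "truth", "loss_clade.txt")))
  }
  list(genomes = genomes, tree = tree, coverage = coverage,
       reads_paths = list.files(file.path(dir, "reads"), full.names = TRUE),
       truth = truth)
}
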