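# Synthetic multi-species genome bundles with planted ground truth. The
# generator emulates the statistical structure the analysis assumes:
# chromosomes capped by mutated tandem telomeric arrays (G-rich strand
# 5'->3' toward the 3' end at the right terminus), TR loci whose template is
# the reverse complement of the species motif in tandem copies flanked by
# conserved-but-diverged sequence derived from one ancestral flank, type-3
# snRNA-like promoter elements upstream, TERT coding fragments, interstitial
# decoy arrays, and optional clades where motif/TR/TERT are jointly deleted.

# template unit convention: among rotations of revcomp(display motif),
# prefer the lexicographically smallest rotation starting with T (TTAGG ->
# TAACC, TCAGG -> TGACC), else the smallest rotation
template_unit <- function(display) {
  rots <- rotations(revcomp(display))
  t_first <- rots[startsWith(rots, "T")]
  if (length(t_first) > 0) min(t_first) else min(rots)
}

# 12-column PSE-like consensus used by the bundled promoter model; the
# generator plants this exact string
PSE_CONSENSUS <- "TTCACCGTAACG"
TATA_ELEMENT <- "TATAAAA"

# transcript extends this many nt 3' of the template on the TR strand, so a
# 15-nt template yields a 200-nt transcript
TRANSCRIPT_TAIL <- 185L

#' Describe one synthetic species
#'
#' @param name species identifier (a tree tip label).
#' @param motif telomeric repeat unit (3-10 nt, ACGT).
#' @param n_chromosomes,chrom_length genome shape.
#' @param telomere_copies mean repeat copies per chromosome end (lengths are
#'   drawn per end from a geometric distribution with this mean, minimum 10
#'   copies); 0 disables telomeres (loss clades).
#' @param telomere_mutation_rate per-base substitution rate within telomere
#'   arrays, in `[0, 0.2]`.
#' @param has_tr,has_tert whether a TR locus / TERT fragments are planted.
#' @param flank_divergence per-site substitution probability of each TR
#'   flank relative to the shared ancestral flank, in `[0, 0.5]`.
#' @param n_decoy_templates template-bearing decoy loci with random flanks
#'   planted per species (exercise the classification filters).
#' @return a one-row tibble.
#' @export
species_spec <- function(name, motif, n_chromosomes = 4L,
                         chrom_length = 20000L, telomere_copies = 100,
                         telomere_mutation_rate = 0.02,
                         has_tr = TRUE, has_tert = TRUE,
                         flank_divergence = 0.1,
                         n_decoy_templates = 10L) {
  motif <- toupper(motif)
  assert_dna(motif, "motif")
  stopifnot(nchar(motif) >= 3L, nchar(motif) <= 10L,
            n_chromosomes >= 1L, chrom_length > 0L,
            telomere_mutation_rate >= 0, telomere_mutation_rate <= 0.2,
            flank_divergence >= 0, flank_divergence <= 0.5)
  if (chrom_length <= 2 * (telomere_copies * nchar(motif) + 2000)) {
    stop("chrom_length must exceed 2*(telomere_copies*|motif| + 2000)",
         call. = FALSE)
  }
  tibble::tibble(name = name, motif = motif,
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 telomere_copies = telomere_copies,
                 telomere_mutation_rate = telomere_mutation_rate,
                 has_tr = has_tr, has_tert = has_tert,
                 flank_divergence = flank_divergence,
                 n_decoy_templates = as.integer(n_decoy_templates))
}

#' Describe a synthetic multi-species bundle
#'
#' @param tree a newick string or `ape::phylo` with tip labels matching
#'   `species$name`.
#' @param species a tibble of [species_spec()] rows, one per tree tip.
#' @param loss_clade optional character vector of tips forming a
#'   monophyletic clade where telomeres, TR, and TERT are jointly deleted;
#'   the corresponding species rows are overridden accordingly.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   bundles.
#' @return a `tq_bundle_spec` list.
#' @export
bundle_spec <- function(tree, species, loss_clade = NULL, seed = 1L) {
  if (is.character(tree)) {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                     error = function(e) NULL)
    if (is.null(tree) || length(tree$tip.label) == 0L) {
      stop("invalid newick tree", call. = FALSE)
    }
  }
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!setequal(tips, species$name) || anyDuplicated(species$name)) {
    stop("species table must have exactly one row per tree tip", call. = FALSE)
  }
  if (!is.null(loss_clade)) {
    if (!all(loss_clade %in% tips)) {
      stop("loss_clade tips not in tree", call. = FALSE)
    }
    if (!is_monophyletic_clade(tree, loss_clade)) {
      stop("loss_clade must be monophyletic in the tree", call. = FALSE)
    }
    idx <- species$name %in% loss_clade
    species$has_tr[idx] <- FALSE
    species$has_tert[idx] <- FALSE
    species$telomere_copies[idx] <- 0
  }
  structure(list(tree = tree, species = species,
                 loss_clade = loss_clade, seed = as.integer(seed)),
            class = "tq_bundle_spec")
}

# is `tips` exactly the tip set of one clade?
is_monophyletic_clade <- function(tree, tips) {
  if (length(tips) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  desc <- ape::extract.clade(tree, mrca)$tip.label
  setequal(desc, tips)
}

# choose a non-overlapping interior slot of `width` nt on a chromosome
.alloc_slot <- function(occupied, chrom_len, width, margin = 2500L) {
  for (try in 1:500) {
    start <- sample.int(chrom_len - width - 2L * margin, 1L) + margin
    if (nrow(occupied) == 0L ||
        all(start + width + 50L <= occupied[, 1] | start >= occupied[, 2] + 50L)) {
      return(start)
    }
  }
  stop("could not place a planted locus; chromosome too crowded", call. = FALSE)
}

# overwrite chromosome segment [start, start + nchar(insert)) (0-based)
.overwrite <- function(chrom, start, insert) {
  paste0(substr(chrom, 1L, start),
         insert,
         substr(chrom, start + nchar(insert) + 1L, nchar(chrom)))
}

# map a locus-relative half-open interval (on the TR strand) to genomic
# plus-strand coordinates of a locus inserted at `ins` with length L
.rel_to_genomic <- function(a, b, ins, L, strand) {
  if (strand == "+") c(ins + a, ins + b) else c(ins + L - b, ins + L - a)
}

#' Generate a synthetic multi-species genome bundle
#'
#' Builds per-species genomes with planted telomeres, TR loci, promoter
#' elements, TERT coding fragments and decoys, and returns them together
#' with machine-readable ground truth. Deterministic: the same spec and
#' seed give identical bundles.
#'
#' @param spec a [bundle_spec()].
#' @return a `tq_bundle` list: `genomes` (named list of named character
#'   vectors), `truth` (list of tibbles: `species`, `loci`, `promoters`,
#'   `tert_loci`, `telomeres`, `loss_clade`), `tree`, `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "tq_bundle_spec"))
  with_seed(spec$seed, .generate_dataset(spec))
}

.generate_dataset <- function(spec) {
  sp <- spec$species
  # one ancestral flank pair shared by all species' TR loci
  anc5 <- random_dna(250L)
  anc3 <- random_dna(250L)
  tert_aa <- tert_query_peptide()
  genomes <- list()
  truth_species <- list(); truth_loci <- list(); truth_prom <- list()
  truth_tert <- list(); truth_telo <- list()
  for (i in seq_len(nrow(sp))) {
    s <- sp[i, ]
    set.seed(child_seed(spec$seed, s$name))
    display <- canonical_motif(s$motif)$display
    p <- nchar(display)
    tunit <- template_unit(display)
    genome <- character(0)
    occ <- list()
    for (ci in seq_len(s$n_chromosomes)) {
      chrom <- random_dna(s$chrom_length)
      occupied <- matrix(numeric(0), ncol = 2)
      cname <- sprintf("%s_chr%d", s$name, ci)
      # telomeres: right terminus = G-rich strand 5'->3' toward the 3' end;
      # left terminus is its reverse complement
      if (s$telomere_copies > 0) {
        for (side in c("left", "right")) {
          copies <- max(10L, rgeom(1L, 1 / (s$telomere_copies + 1)))
          arr <- strrep(display, copies)
          arr <- mutate_seq(arr, s$telomere_mutation_rate)
          if (side == "left") arr <- revcomp(arr)
          alen <- nchar(arr)
          if (side == "left") {
            chrom <- .overwrite(chrom, 0L, arr)
            iv <- c(0L, alen)
          } else {
            chrom <- .overwrite(chrom, s$chrom_length - alen, arr)
            iv <- c(s$chrom_length - alen, s$chrom_length)
          }
          occupied <- rbind(occupied, iv)
          truth_telo[[length(truth_telo) + 1L]] <- tibble::tibble(
            species = s$name, chromosome = cname, start = iv[1], end = iv[2],
            side = side, copies = copies)
        }
        # interstitial decoy arrays at ~1 per 50 kb
        n_decoy <- stats::rpois(1L, s$chrom_length / 50000)
        if (n_decoy > 0) {
          for (d in seq_len(n_decoy)) {
            copies <- 15L + sample.int(15L, 1L)
            arr <- mutate_seq(strrep(display, copies), 0.02)
            if (runif(1) < 0.5) arr <- revcomp(arr)
            st <- .alloc_slot(occupied, s$chrom_length, nchar(arr))
            chrom <- .overwrite(chrom, st, arr)
            occupied <- rbind(occupied, c(st, st + nchar(arr)))
          }
        }
      }
      occ[[cname]] <- occupied
      genome[[cname]] <- chrom
    }
    # TR locus: diverged ancestral flanks around 3 tandem template copies
    if (isTRUE(s$has_tr)) {
      template <- strrep(tunit, 3L)
      flank5 <- mutate_seq(anc5, s$flank_divergence)
      flank3 <- mutate_seq(anc3, s$flank_divergence)
      # promoter elements planted exact, relative to the template 5' end
      # (the planted transcript start): PSE at -60, TATA at -30
      flank5 <- paste0(substr(flank5, 1L, 250L - 60L),
                       PSE_CONSENSUS,
                       substr(flank5, 250L - 60L + nchar(PSE_CONSENSUS) + 1L,
                              250L - 30L),
                       TATA_ELEMENT,
                       substr(flank5, 250L - 30L + nchar(TATA_ELEMENT) + 1L, 250L))
      locus <- paste0(flank5, template, flank3)
      L <- nchar(locus)
      tlen <- nchar(template)
      cname <- sample(names(genome), 1L)
      strand <- if (runif(1) < 0.5) "+" else "-"
      ins <- .alloc_slot(occ[[cname]], s$chrom_length, L)
      genome[[cname]] <- .overwrite(genome[[cname]], ins,
                                    if (strand == "+") locus else revcomp(locus))
      occ[[cname]] <- rbind(occ[[cname]], c(ins, ins + L))
      tmpl_g <- .rel_to_genomic(250L, 250L + tlen, ins, L, strand)
      tx_g <- .rel_to_genomic(250L, 250L + tlen + TRANSCRIPT_TAIL, ins, L, strand)
      truth_loci[[length(truth_loci) + 1L]] <- tibble::tibble(
        species = s$name, type = "tr", chromosome = cname,
        start = ins, end = ins + L, strand = strand,
        template_start = tmpl_g[1], template_end = tmpl_g[2],
        template_seq = template, annealing_seq = tunit,
        transcript_start = tx_g[1], transcript_end = tx_g[2])
      pse_g <- .rel_to_genomic(190L, 190L + nchar(PSE_CONSENSUS), ins, L, strand)
      tata_g <- .rel_to_genomic(220L, 220L + nchar(TATA_ELEMENT), ins, L, strand)
      truth_prom[[length(truth_prom) + 1L]] <- tibble::tibble(
        species = s$name, chromosome = cname, strand = strand,
        element = c("PSE", "TATA"),
        start = c(pse_g[1], tata_g[1]), end = c(pse_g[2], tata_g[2]),
        offset = c(-60L, -30L))
    }
    # decoy template loci: same template run, unrelated random flanks
    if (s$n_decoy_templates > 0 && s$telomere_copies > 0) {
      template <- strrep(tunit, 3L)
      for (d in seq_len(s$n_decoy_templates)) {
        locus <- paste0(random_dna(250L), template, random_dna(250L))
        L <- nchar(locus)
        cname <- sample(names(genome), 1L)
        strand <- if (runif(1) < 0.5) "+" else "-"
        ins <- .alloc_slot(occ[[cname]], s$chrom_length, L)
        genome[[cname]] <- .overwrite(genome[[cname]], ins,
                                      if (strand == "+") locus else revcomp(locus))
        occ[[cname]] <- rbind(occ[[cname]], c(ins, ins + L))
        tmpl_g <- .rel_to_genomic(250L, 250L + nchar(template), ins, L, strand)
        truth_loci[[length(truth_loci) + 1L]] <- tibble::tibble(
          species = s$name, type = "decoy", chromosome = cname,
          start = ins, end = ins + L, strand = strand,
          template_start = tmpl_g[1], template_end = tmpl_g[2],
          template_seq = template, annealing_seq = tunit,
          transcript_start = NA_real_, transcript_end = NA_real_)
      }
    }
    # TERT: the query peptide encoded in-frame as two exon-like fragments
    if (isTRUE(s$has_tert)) {
      half <- nchar(tert_aa) %/% 2L
      frags <- c(substr(tert_aa, 1L, half),
                 substr(tert_aa, half + 1L, nchar(tert_aa)))
      strand <- if (runif(1) < 0.5) "+" else "-"
      cname <- sample(names(genome), 1L)
      for (fi in seq_along(frags)) {
        cds <- encode_peptide(frags[fi])
        ins <- .alloc_slot(occ[[cname]], s$chrom_length, nchar(cds))
        genome[[cname]] <- .overwrite(genome[[cname]], ins,
                                      if (strand == "+") cds else revcomp(cds))
        occ[[cname]] <- rbind(occ[[cname]], c(ins, ins + nchar(cds)))
        truth_tert[[length(truth_tert) + 1L]] <- tibble::tibble(
          species = s$name, chromosome = cname, fragment = fi,
          start = ins, end = ins + nchar(cds), strand = strand,
          query_start = ifelse(fi == 1L, 0L, half),
          query_end = ifelse(fi == 1L, half, nchar(tert_aa)))
      }
    }
    genomes[[s$name]] <- genome
    truth_species[[length(truth_species) + 1L]] <- tibble::tibble(
      species = s$name, motif = s$motif,
      motif_canonical = canonical_motif(s$motif)$canonical,
      motif_display = display, template_unit = tunit,
      has_tr = s$has_tr, has_tert = s$has_tert,
      has_telomeres = s$telomere_copies > 0)
  }
  structure(list(
    genomes = genomes,
    truth = list(species = dplyr::bind_rows(truth_species),
                 loci = dplyr::bind_rows(truth_loci),
                 promoters = dplyr::bind_rows(truth_prom),
                 tert_loci = dplyr::bind_rows(truth_tert),
                 telomeres = dplyr::bind_rows(truth_telo),
                 loss_clade = spec$loss_clade %||% character(0)),
    tree = spec$tree, spec = spec), class = "tq_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic codon encoding of a peptide (first codon in the standard
# genetic code table for each residue)
encode_peptide <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codons <- vapply(seq_chars(aa), function(r) {
    names(gc)[gc == r][1]
  }, character(1))
  if (anyNA(codons)) stop("peptide contains a non-standard residue", call. = FALSE)
  paste(codons, collapse = "")
}

#' Bundled synthetic TERT-like query peptide
#'
#' A 120-residue synthetic stand-in for a reverse-transcriptase protein
#' query (see `inst/extdata/tert_query_synthetic.fa`); used as the default
#' query of [screen_tert()] and as the peptide the generator plants.
#' @return a single protein string.
#' @export
tert_query_peptide <- function() {
  path <- system.file("extdata", "tert_query_synthetic.fa",
                      package = "teloquest")
  as.character(Biostrings::readAAStringSet(path))[[1]]
}

#' Simulate whole-genome shotgun reads
#'
#' Uniform read sampling from both strands with per-base substitution
#' errors; `round(coverage * genome_length / read_length)` reads.
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param read_length read length (nt, <= shortest chromosome).
#' @param coverage target fold coverage (> 0).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return a tibble with `read_id`, `chromosome`, `start` (0-based),
#'   `strand`, `seq`; write with [write_fastq()].
#' @export
simulate_reads <- function(genome, read_length = 150L, coverage = 10,
                           error_rate = 0, seed = 1L) {
  genome <- as_genome(genome)
  lens <- nchar(genome)
  if (read_length > min(lens)) {
    stop("read_length exceeds the shortest chromosome", call. = FALSE)
  }
  stopifnot(coverage > 0)
  n_reads <- round(coverage * sum(lens) / read_length)
  with_seed(seed, {
    chrom <- sample(names(genome), n_reads, replace = TRUE,
                    prob = lens - read_length + 1)
    start <- floor(runif(n_reads) * (lens[chrom] - read_length + 1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (cn in unique(chrom)) {
      idx <- which(chrom == cn)
      seqs[idx] <- substring(genome[[cn]], start[idx] + 1L,
                             start[idx] + read_length)
    }
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
    }
    tibble::tibble(read_id = sprintf("read%07d", seq_len(n_reads)),
                   chromosome = chrom, start = start, strand = strand,
                   seq = unname(seqs))
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads tibble from [simulate_reads()].
#' @param path output FASTQ path.
#' @param quality constant quality character (default "I").
#' @export
write_fastq <- function(reads, path, quality = "I") {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$seq,
                           "+",
                           strrep(quality, nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an RNA-seq-like coverage track over each planted TR locus
#'
#' Per-base coverage over each planted TR transcript interval +/- 500 nt:
#' approximately `depth` inside the transcript (Gaussian noise truncated at
#' zero) and approximately zero outside.
#'
#' @param bundle a `tq_bundle` (its truth supplies the transcript
#'   intervals), or the truth `loci` tibble itself.
#' @param depth expected fold coverage inside the transcript.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param pad nt of context either side of the transcript.
#' @return a BedGraph-style tibble: `species`, `chromosome`, `pos`
#'   (0-based), `coverage`.
#' @export
simulate_coverage_track <- function(bundle, depth = 10, noise_sd = 2,
                                    seed = 1L, pad = 500L) {
  stopifnot(depth > 0)
  loci <- if (inherits(bundle, "tq_bundle")) bundle$truth$loci else bundle
  loci <- loci[loci$type == "tr" & !is.na(loci$transcript_start), ]
  if (nrow(loci) == 0L) {
    return(tibble::tibble(species = character(), chromosome = character(),
                          pos = integer(), coverage = numeric()))
  }
  with_seed(seed, dplyr::bind_rows(lapply(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    w0 <- max(0L, as.integer(lc$transcript_start) - pad)
    w1 <- as.integer(lc$transcript_end) + pad
    pos <- w0:(w1 - 1L)
    inside <- pos >= lc$transcript_start & pos < lc$transcript_end
    mu <- ifelse(inside, depth, 0)
    cov <- if (noise_sd > 0) pmax(0, rnorm(length(pos), mu, noise_sd)) else mu
    tibble::tibble(species = lc$species, chromosome = lc$chromosome,
                   pos = pos, coverage = cov)
  })))
}
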