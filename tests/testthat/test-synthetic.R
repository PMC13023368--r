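# extract a planted locus from the genome on its TR strand
locus_seq <- function(bundle, row) {
  g <- substr(bundle$genomes[[row$species]][[row$chromosome]],
              row$start + 1, row$end)
  if (row$strand == "-") g <- revcomp(g) else g
}

test_that("bundles are deterministic in the seed and vary across seeds", {
  sp <- dplyr::bind_rows(species_spec("A", "TCAGG", n_chromosomes = 2),
                         species_spec("B", "TTAGG", n_chromosomes = 2))
  b1 <- generate_dataset(bundle_spec("(A,B);", sp, seed = 42))
  b2 <- generate_dataset(bundle_spec("(A,B);", sp, seed = 42))
  b3 <- generate_dataset(bundle_spec("(A,B);", sp, seed = 43))
  expect_identical(b1$genomes, b2$genomes)
  expect_identical(b1$truth, b2$truth)
  expect_false(identical(b1$genomes, b3$genomes))
})

test_that("zero flank divergence gives byte-identical TR flanks across species", {
  sp <- dplyr::bind_rows(
    species_spec("A", "TCAGG", n_chromosomes = 2, flank_divergence = 0),
    species_spec("B", "TCAGG", n_chromosomes = 2, flank_divergence = 0),
    species_spec("C", "TTAGG", n_chromosomes = 2, flank_divergence = 0))
  b <- generate_dataset(bundle_spec("((A,B),C);", sp, seed = 9))
  tr <- b$truth$loci[b$truth$loci$type == "tr", ]
  loci <- vapply(seq_len(nrow(tr)), function(i) locus_seq(b, tr[i, ]),
                 character(1))
  f5 <- substr(loci, 1, 250)
  f3 <- substring(loci, nchar(loci) - 249)
  expect_equal(length(unique(f5)), 1L)
  expect_equal(length(unique(f3)), 1L)
})

test_that("planted templates reverse-complement to the species motif", {
  b <- make_discovery_bundle(seed = 3)
  loci <- b$truth$loci
  sp_tab <- b$truth$species
  for (i in seq_len(nrow(loci))) {
    want <- sp_tab$motif_canonical[sp_tab$species == loci$species[i]]
    expect_equal(template_to_motif(loci$template_seq[i])$canonical, want)
    # the template really sits at its recorded genomic interval
    g <- b$genomes[[loci$species[i]]][[loci$chromosome[i]]]
    tp <- substr(g, loci$template_start[i] + 1, loci$template_end[i])
    if (loci$strand[i] == "-") tp <- revcomp(tp)
    expect_equal(tp, loci$template_seq[i])
  }
  # 4-tip check of the template unit convention: TCAGG -> TGACC copies,
  # TTAGG -> TAACC copies
  units <- setNames(sp_tab$template_unit, sp_tab$species)
  expect_equal(unname(units[c("A", "C")]), c("TGACC", "TAACC"))
  expect_equal(loci$template_seq[loci$species == "A" & loci$type == "tr"],
               strrep("TGACC", 3))
})

test_that("telomere arrays sit at both termini in the right orientation", {
  b <- make_motif_bundle(seed = 4)
  g <- b$genomes$S1
  display <- "TCAGG"
  for (chrom in g) {
    n <- nchar(chrom)
    right <- substr(chrom, n - 49, n)
    left <- substr(chrom, 1, 50)
    # G-rich strand runs 5'->3' toward the 3' end at the right terminus
    arr_r <- find_tandem_arrays(right, min_copies = 4)
    arr_l <- find_tandem_arrays(left, min_copies = 4)
    expect_equal(arr_r$canonical[1], "ACCTG")
    expect_equal(arr_l$canonical[1], "ACCTG")
    expect_equal(arr_r$display[1], "TCAGG")
    # left terminus is the reverse complement: its as-is strand is C-rich
    expect_gt(nchar(gsub("[^C]", "", left)), nchar(gsub("[^G]", "", left)))
    expect_gt(nchar(gsub("[^G]", "", right)), nchar(gsub("[^C]", "", right)))
  }
})

test_that("loss-clade genomes carry no telomeric arrays at their termini", {
  b <- make_discovery_bundle(seed = 5, loss_clade = c("C", "D"))
  for (sp in c("C", "D")) {
    for (chrom in b$genomes[[sp]]) {
      n <- nchar(chrom)
      for (win in c(substr(chrom, 1, 2000), substr(chrom, n - 1999, n))) {
        arr <- find_tandem_arrays(win, min_copies = 3)
        expect_false(any(arr$canonical %in% c("ACCTG", "AACCT")))
      }
    }
  }
  expect_true(all(b$truth$loci$species %in% c("A", "B", "E")))
  expect_identical(b$truth$loss_clade, c("C", "D"))
})

test_that("read simulation honours the coverage arithmetic", {
  g <- c(chr1 = rand_dna(50000), chr2 = rand_dna(50000))
  reads <- simulate_reads(g, read_length = 100, coverage = 10, seed = 1)
  expect_equal(nrow(reads), 10000L)
  expect_error(simulate_reads(c(chr1 = rand_dna(50)), read_length = 100),
               "read_length")
})

test_that("an error-free read reproduces its source fragment exactly", {
  set.seed(31)
  g <- c(chr1 = strrep("TCAGG", 20))  # one 100-nt chromosome
  reads <- simulate_reads(g, read_length = 100, coverage = 1,
                          error_rate = 0, seed = 2)
  expect_equal(nrow(reads), 1L)
  expect_true(reads$seq %in% c(g[["chr1"]], revcomp(g[["chr1"]])))
})

test_that("substitution errors occur at the requested rate", {
  set.seed(32)
  g <- c(chr1 = rand_dna(100000))
  reads <- simulate_reads(g, read_length = 100, coverage = 10,
                          error_rate = 0.01, seed = 3)
  # compare each read to its recorded source coordinates
  n_mm <- 0L; n_base <- 0L
  for (i in seq_len(nrow(reads))) {
    src <- substr(g[["chr1"]], reads$start[i] + 1, reads$start[i] + 100)
    if (reads$strand[i] == "-") src <- revcomp(src)
    n_mm <- n_mm + sum(strsplit(src, "")[[1]] != strsplit(reads$seq[i], "")[[1]])
    n_base <- n_base + 100L
  }
  p_hat <- n_mm / n_base
  se <- sqrt(0.01 * 0.99 / n_base)
  expect_lt(abs(p_hat - 0.01), 3 * se)
})

test_that("noise-free coverage tracks are an exact step function", {
  b <- make_discovery_bundle(seed = 6)
  cov <- simulate_coverage_track(b, depth = 10, noise_sd = 0, seed = 1)
  loci <- b$truth$loci[b$truth$loci$type == "tr", ]
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    tr <- cov[cov$species == lc$species & cov$chromosome == lc$chromosome, ]
    inside <- tr$pos >= lc$transcript_start & tr$pos < lc$transcript_end
    expect_true(all(tr$coverage[inside] == 10))
    expect_true(all(tr$coverage[!inside] == 0))
    # transcript is 200 nt, so the track sums to depth x 200
    expect_equal(sum(tr$coverage), 2000)
  }
})

test_that("invalid bundle specs are rejected", {
  sp <- dplyr::bind_rows(species_spec("A", "TCAGG"), species_spec("B", "TCAGG"),
                         species_spec("C", "TCAGG"), species_spec("D", "TCAGG"))
  expect_error(bundle_spec("((A,B),(C,D)", sp), "newick")
  # B and C are not monophyletic in ((A,B),(C,D))
  expect_error(bundle_spec("((A,B),(C,D));", sp, loss_clade = c("B", "C")),
               "monophyletic")
  expect_error(species_spec("A", "TCXGG"), "non-ACGT")
  expect_error(species_spec("A", "TCAGG", chrom_length = 3000,
                            telomere_copies = 200), "chrom_length")
})
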