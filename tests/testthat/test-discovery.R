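# genome with one planted template run and guarded boundaries
planted_template_genome <- function(template = "TGACCTGACCTGACC",
                                    offset = 5000, total = 12000,
                                    seed = 51, minus = FALSE) {
  set.seed(seed)
  ch <- strsplit(rand_dna(total), "")[[1]]
  tp <- strsplit(template, "")[[1]]
  ch[(offset + 1):(offset + length(tp))] <- tp
  p <- 5
  for (i in seq(offset, offset - 7)) {
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i + p])[1]
  }
  for (j in seq(offset + length(tp) + 1, offset + length(tp) + 8)) {
    ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j - p])[1]
  }
  g <- paste(ch, collapse = "")
  if (minus) g <- revcomp(g)
  c(chr1 = g)
}

test_that("a planted template is recovered with its flanks, either strand", {
  g <- planted_template_genome()
  cand <- scan_genome_for_templates(g, "TCAGG")
  hit <- cand[cand$start == 5000, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$end, 5015L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$template_seq, "TGACCTGACCTGACC")
  expect_equal(nchar(hit$flank5), 200L)
  expect_equal(nchar(hit$flank3), 200L)
  expect_false(hit$truncated)

  # same genome reverse-complemented: same template sequence, minus strand,
  # coordinates remapped
  g_rc <- planted_template_genome(minus = TRUE)
  cand_rc <- scan_genome_for_templates(g_rc, "TCAGG")
  hit_rc <- cand_rc[cand_rc$end == 12000 - 5000, ]
  expect_equal(nrow(hit_rc), 1L)
  expect_equal(hit_rc$strand, "-")
  expect_equal(hit_rc$template_seq, hit$template_seq)
  expect_equal(hit_rc$flank5, hit$flank5)
  expect_equal(hit_rc$flank3, hit$flank3)
})

test_that("a motif with no template-like runs gives an empty candidate list", {
  set.seed(52)
  # TTTGGG-templates need 15+ nt of a specific 6-mer pattern; absent here
  g <- c(chr1 = rand_dna(5000))
  expect_equal(nrow(scan_genome_for_templates(g, "TTTGGG")), 0L)
})

test_that("concordance annotation separates matching and foreign templates", {
  g <- planted_template_genome()  # TCAGG-template
  cand <- scan_genome_for_templates(g, "TCAGG")
  cand <- annotate_concordance(cand, "TCAGG")
  expect_true(cand$motif_concordant[cand$start == 5000])
  # the same candidates judged against a TTAGG species are discordant
  cand2 <- annotate_concordance(cand, "TTAGG")
  expect_false(any(cand2$motif_concordant[cand2$start == 5000]))
  # and discordant candidates are dropped by classification
  cand2$expressed <- TRUE
  cand2$ortholog_support <- 3L
  expect_false("HIGH" %in% classify_candidates(cand2)$tier)
})

test_that("coverage boundaries recover a step track exactly", {
  track <- tibble::tibble(pos = 0:499,
                          coverage = ifelse(0:499 >= 100 & 0:499 < 300, 10, 0))
  bd <- boundary_from_coverage(track)
  expect_equal(bd$tx_start, 100L)
  expect_equal(bd$tx_end, 300L)
  expect_true(bd$expressed)

  none <- boundary_from_coverage(tibble::tibble(pos = 0:99, coverage = 0))
  expect_true(is.na(none$tx_start))
  expect_false(none$expressed)
})

test_that("noisy coverage boundaries land within 5 nt of the planted interval", {
  b <- make_discovery_bundle(seed = 53)
  cov <- simulate_coverage_track(b, depth = 10, noise_sd = 2, seed = 53)
  loci <- b$truth$loci[b$truth$loci$type == "tr", ]
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i, ]
    tr <- cov[cov$species == lc$species & cov$chromosome == lc$chromosome, ]
    bd <- boundary_from_coverage(tr, locus = c(lc$transcript_start,
                                               lc$transcript_end))
    expect_lte(abs(bd$tx_start - lc$transcript_start), 5)
    expect_lte(abs(bd$tx_end - lc$transcript_end), 5)
    expect_true(bd$expressed)
  }
})

test_that("ortholog grouping links planted orthologs and isolates decoys", {
  set.seed(54)
  anc5 <- rand_dna(200); anc3 <- rand_dna(200)
  mut <- function(s, r) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < r
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  rows <- list()
  for (sp in c("S1", "S2", "S3")) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      species = sp, candidate_id = paste0(sp, "_tr"),
      flank5 = mut(anc5, 0.08), flank3 = mut(anc3, 0.08),
      motif_concordant = TRUE)
    for (d in 1:2) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        species = sp, candidate_id = paste0(sp, "_decoy", d),
        flank5 = rand_dna(200), flank3 = rand_dna(200),
        motif_concordant = TRUE)
    }
  }
  cand <- dplyr::bind_rows(rows)
  og <- group_orthologs(cand, min_support = 2)
  grouped <- og$candidates[!is.na(og$candidates$ortholog_group), ]
  expect_setequal(grouped$candidate_id[grouped$ortholog_support >= 3],
                  c("S1_tr", "S2_tr", "S3_tr"))
  decoys <- og$candidates[grepl("decoy", og$candidates$candidate_id), ]
  expect_true(all(decoys$ortholog_support < 3))
})

test_that("identical flanks give mean group identity 1", {
  cand <- dplyr::bind_rows(lapply(c("S1", "S2"), function(sp) {
    tibble::tibble(species = sp, candidate_id = paste0(sp, "_tr"),
                   flank5 = strrep("ACGTT", 40), flank3 = strrep("GATCA", 40),
                   motif_concordant = TRUE)
  }))
  og <- group_orthologs(cand, min_support = 2)
  expect_equal(nrow(og$groups), 1L)
  expect_equal(og$groups$mean_flank_identity, 1)
  expect_true(og$groups$supported)
})

test_that("discordant candidates are excluded from grouping", {
  cand <- dplyr::bind_rows(lapply(c("S1", "S2"), function(sp) {
    tibble::tibble(species = sp, candidate_id = paste0(sp, "_tr"),
                   flank5 = strrep("ACGTT", 40), flank3 = strrep("GATCA", 40),
                   motif_concordant = sp == "S1")
  }))
  og <- group_orthologs(cand, min_support = 2)
  expect_equal(nrow(og$groups), 0L)
  expect_equal(og$candidates$ortholog_support, c(0L, 0L))
})

test_that("tier rules follow the three criteria", {
  base <- tibble::tibble(species = "S", candidate_id = sprintf("c%d", 1:4),
                         motif_concordant = c(TRUE, TRUE, TRUE, FALSE),
                         expressed = c(TRUE, NA, FALSE, TRUE),
                         ortholog_support = c(3L, 2L, 0L, 3L))
  out <- classify_candidates(base)
  expect_equal(nrow(out), 3L)  # discordant c4 dropped
  expect_equal(as.character(out$tier[out$candidate_id == "c1"]), "HIGH")
  expect_equal(as.character(out$tier[out$candidate_id == "c2"]), "MEDIUM")
  expect_equal(as.character(out$tier[out$candidate_id == "c3"]), "LOW")
})
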