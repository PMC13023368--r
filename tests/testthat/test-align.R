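test_that("Smith-Waterman reproduces hand-checked local alignments", {
  # 5 identical bases at +2 each
  hit <- smith_waterman("GGTTA", "GGTTA")
  expect_equal(hit$score, 10)
  expect_equal(c(hit$q_start, hit$q_end, hit$s_start, hit$s_end),
               c(0, 5, 0, 5))
  expect_equal(hit$identity, 1)
  # best local alignment of ACGT vs TGCA is a single matching base
  expect_equal(smith_waterman("ACGT", "TGCA")$score, 2)
  # empty input: zero-score empty hit
  expect_equal(smith_waterman("", "ACGT")$score, 0)
  expect_equal(smith_waterman("", "ACGT")$aln_len, 0)
})

test_that("Smith-Waterman matches an independent DP oracle on random pairs", {
  set.seed(21)
  for (i in 1:60) {
    a <- rand_dna(sample(5:60, 1))
    b <- rand_dna(sample(5:60, 1))
    if (i %% 3 == 0) {  # share a core so positive scores are common
      core <- rand_dna(15)
      a <- paste0(substr(a, 1, 10), core)
      b <- paste0(core, substr(b, 1, 10))
    }
    expect_equal(smith_waterman(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(22)
  for (i in 1:20) {
    core <- rand_dna(12)
    a <- paste0(rand_dna(20), core, rand_dna(5))
    b <- paste0(rand_dna(8), core, rand_dna(15))
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("seed-and-extend finds exact and planted matches", {
  set.seed(23)
  q <- rand_dna(30)
  hits <- seed_extend_search(q, c(s1 = q))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$score, 60)
  expect_equal(hits$identity, 1)
  expect_equal(c(hits$q_start, hits$q_end), c(0, 30))

  # 20-nt exact segment planted in an otherwise random 1-kb subject
  seg <- rand_dna(20)
  subj <- paste0(rand_dna(490), seg, rand_dna(490))
  q2 <- seg
  h2 <- seed_extend_search(q2, c(s1 = subj))
  expect_gte(nrow(h2), 1L)
  expect_gte(h2$score[1], 40)
  expect_lte(h2$s_start[1], 490)
  expect_gte(h2$s_end[1], 510)
})

test_that("no shared word means no hits", {
  # construct two sequences verified to share no 11-mer on either strand
  set.seed(24)
  repeat {
    a <- rand_dna(1000); b <- rand_dna(1000)
    words <- function(s) substring(s, 1:(nchar(s) - 10), 11:nchar(s))
    if (length(intersect(words(a), c(words(b), words(revcomp(b))))) == 0) break
  }
  expect_equal(nrow(seed_extend_search(a, c(s = b))), 0L)
})

test_that("minus-strand hits mirror plus-strand hits exactly", {
  set.seed(25)
  core <- rand_dna(25)
  q <- paste0(rand_dna(10), core, rand_dna(10))
  s <- paste0(rand_dna(40), core, rand_dna(40))
  hp <- seed_extend_search(q, c(s = s))
  hm <- seed_extend_search(q, c(s = revcomp(s)))
  expect_equal(nrow(hp), 1L)
  expect_equal(nrow(hm), 1L)
  expect_equal(hp$strand, "+")
  expect_equal(hm$strand, "-")
  expect_equal(hm$score, hp$score)
  expect_equal(hm$q_start, hp$q_start)
  # subject coordinates map through the reverse complement
  expect_equal(hm$s_start, nchar(s) - hp$s_end)
  expect_equal(hm$s_end, nchar(s) - hp$s_start)
})

test_that("heuristic equals full DP when a seed lies in the shared core", {
  set.seed(26)
  scheme <- scoring_scheme()
  n_checked <- 0
  for (i in 1:40) {
    core <- rand_dna(sample(15:25, 1))
    a <- paste0(rand_dna(sample(0:20, 1)), core, rand_dna(sample(0:20, 1)))
    b <- paste0(rand_dna(sample(0:20, 1)), core, rand_dna(sample(0:20, 1)))
    if (nchar(core) < scheme$word_size) next
    n_checked <- n_checked + 1
    sw <- smith_waterman(a, b, scheme)
    sch <- scheme; sch$evalue_max <- Inf
    h <- seed_extend_search(a, c(s = b), sch)
    expect_equal(max(h$score[h$strand == "+"]), sw$score,
                 info = paste(a, b))
  }
  expect_gte(n_checked, 30)
})

test_that("query shorter than the word size is rejected", {
  expect_error(seed_extend_search("ACGTACGT", c(s = rand_dna(100))),
               "word_size")
})

test_that("translated search finds a protein query in all six frames", {
  set.seed(27)
  pep <- tert_query_peptide()
  cds <- teloquest:::encode_peptide(substr(pep, 1, 60))
  for (strand in c("+", "-")) {
    for (off in 0:2) {
      s <- paste0(rand_dna(300 + off),
                  if (strand == "+") cds else revcomp(cds),
                  rand_dna(300))
      h <- seed_extend_search(substr(pep, 1, 60), c(s = s),
                              protein_scheme(), mode = "translated")
      expect_gte(nrow(h), 1L)
      expect_equal(h$strand[1], strand)
      expect_equal(sign(h$frame[1]), if (strand == "+") 1 else -1)
      # best hit covers the planted coding interval
      expect_lte(h$s_start[1], 300 + off + 3)
      expect_gte(h$s_end[1], 300 + off + 177)
    }
  }
})

test_that("E-values rank strong hits far below the cutoff", {
  set.seed(28)
  q <- rand_dna(60)
  h <- seed_extend_search(q, c(s = paste0(rand_dna(200), q, rand_dna(200))))
  expect_lt(h$evalue[1], 1e-10)
})
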