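pse <- teloquest:::PSE_CONSENSUS

# flank5 with elements planted at given upstream offsets (position -1 =
# last base before the transcript start)
plant_flank <- function(pse_at = NULL, tata_at = NULL, base = "C", n = 200) {
  ch <- rep(base, n)
  if (!is.null(pse_at)) {
    i0 <- n + pse_at + 1
    ch[i0:(i0 + nchar(pse) - 1)] <- strsplit(pse, "")[[1]]
  }
  if (!is.null(tata_at)) {
    i0 <- n + tata_at + 1
    ch[i0:(i0 + 6)] <- strsplit("TATAAAA", "")[[1]]
  }
  paste(ch, collapse = "")
}

test_that("both elements in their windows give a type3-like call", {
  cand <- tibble::tibble(flank5 = plant_flank(pse_at = -60, tata_at = -30))
  out <- scan_promoter(cand)
  expect_equal(out$promoter_type, "type3-like")
  expect_equal(out$pse_pos, -60L)
  expect_equal(out$tata_pos, -30L)
  expect_gte(out$pse_score, promoter_model()$pse_min_score)
})

test_that("featureless or single-element flanks call none / partial", {
  expect_equal(scan_promoter(tibble::tibble(flank5 = plant_flank()))$promoter_type,
               "none")
  out_tata <- scan_promoter(tibble::tibble(flank5 = plant_flank(tata_at = -28)))
  expect_equal(out_tata$promoter_type, "partial")
  expect_true(is.na(out_tata$pse_pos))
  out_pse <- scan_promoter(tibble::tibble(flank5 = plant_flank(pse_at = -55)))
  expect_equal(out_pse$promoter_type, "partial")
})

test_that("elements outside their windows are not accepted", {
  # PSE at -95 is upstream of the [-80,-40] window; TATA at -45 likewise
  out <- scan_promoter(tibble::tibble(
    flank5 = plant_flank(pse_at = -95, tata_at = -45)))
  expect_equal(out$promoter_type, "none")
})

test_that("the consensus attains the PWM maximum score", {
  m <- promoter_model()
  cand <- tibble::tibble(flank5 = plant_flank(pse_at = -60))
  out <- scan_promoter(cand, m)
  expect_equal(out$pse_score, m$pse_max_score, tolerance = 1e-9)
})

test_that("the TATA consensus is matched by IUPAC expansion", {
  # TATAWAW allows A or T at the W positions
  for (el in c("TATAAAA", "TATATAT", "TATAAAT")) {
    ch <- plant_flank()
    substr(ch, 200 - 30 + 1, 200 - 30 + 7) <- el
    out <- scan_promoter(tibble::tibble(flank5 = ch))
    expect_equal(out$promoter_type, "partial", info = el)
  }
  ch <- plant_flank()
  substr(ch, 200 - 30 + 1, 200 - 30 + 7) <- "TATACAA"  # C not allowed at W
  expect_equal(scan_promoter(tibble::tibble(flank5 = ch))$promoter_type, "none")
})

test_that("calls are invariant to the candidate's genomic position", {
  f <- plant_flank(pse_at = -60, tata_at = -30)
  cand <- tibble::tibble(flank5 = c(f, f), start = c(1000L, 5000L))
  out <- scan_promoter(cand)
  expect_equal(out$promoter_type[1], out$promoter_type[2])
  expect_equal(out$pse_pos[1], out$pse_pos[2])
})

test_that("a tss offset shifts the scanning windows coherently", {
  # elements planted relative to a transcript start 20 nt into the flank
  f <- plant_flank(pse_at = -80, tata_at = -50)  # -60/-30 relative to -20
  out <- scan_promoter(tibble::tibble(flank5 = f), tss_offset = 20L)
  expect_equal(out$promoter_type, "type3-like")
  expect_equal(out$pse_pos, -60L)
  expect_equal(out$tata_pos, -30L)
})

test_that("a user PWM file round-trips through read_pwm", {
  m0 <- teloquest:::.default_pse_pwm()
  tmp <- tempfile(fileext = ".txt")
  write.table(cbind(rownames(m0), as.data.frame(m0)), tmp,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  m1 <- read_pwm(tmp)
  expect_equal(unname(m1), unname(m0), tolerance = 1e-12)
  out <- scan_promoter(tibble::tibble(flank5 = plant_flank(pse_at = -60)),
                       promoter_model(pse_pwm = m1))
  expect_equal(out$pse_pos, -60L)
})

test_that("flanks shorter than the windows are flagged as partial scans", {
  out <- scan_promoter(tibble::tibble(flank5 = strrep("C", 50)))
  expect_true(out$promoter_partial_scan)
  expect_equal(out$promoter_type, "none")
})
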