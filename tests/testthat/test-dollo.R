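test_that("single absent clades map to one loss on their stem edge", {
  ev <- dollo_losses("((A,B),(C,D));",
                     c(A = "present", B = "present",
                       C = "absent", D = "absent"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tips_affected, "C,D")
  expect_equal(ev$n_tips_affected, 2L)

  # all present: nothing to explain
  ev0 <- dollo_losses("((A,B),(C,D));",
                      c(A = "present", B = "present",
                        C = "present", D = "present"))
  expect_equal(nrow(ev0), 0L)
})

test_that("scattered absences need one loss per maximal absent clade", {
  # caterpillar (((A,B),C),D) with B and D absent: two independent losses
  ev <- dollo_losses("(((A,B),C),D);",
                     c(A = "present", B = "absent",
                       C = "present", D = "absent"))
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$child, c("B", "D"))
})

test_that("all-absent characters lose once on the root edge", {
  ev <- dollo_losses("((A,B),C);",
                     c(A = "absent", B = "absent", C = "absent"))
  expect_equal(nrow(ev), 1L)
  expect_true(is.na(ev$parent))
  expect_equal(ev$n_tips_affected, 3L)
})

test_that("unknown tips are uninformative for clade maximality", {
  # C unknown inside an otherwise absent clade: still one loss above (C,D)
  ev <- dollo_losses("((A,B),(C,D));",
                     c(A = "present", B = "present",
                       C = "unknown", D = "absent"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tips_affected, "D")
  # logical input with NA as unknown behaves identically
  ev2 <- dollo_losses("((A,B),(C,D));",
                      c(A = TRUE, B = TRUE, C = NA, D = FALSE))
  expect_equal(ev2$tips_affected, ev$tips_affected)
})

test_that("loss counts equal the exhaustive edge-subset minimum", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    tree$tip.label <- paste0("t", seq_len(n))
    states <- sample(c("present", "absent"), n, replace = TRUE)
    if (!any(states == "present")) states[1] <- "present"
    presence <- setNames(states, tree$tip.label)
    ev <- dollo_losses(tree, presence)
    expect_equal(nrow(ev), brute_dollo_min(tree, presence),
                 info = paste(ape::write.tree(tree),
                              paste(states, collapse = ",")))
  }
})

test_that("events are invariant under consistent tip relabeling", {
  tree <- ape::read.tree(text = "((A,B),(C,D));")
  presence <- c(A = "present", B = "absent", C = "absent", D = "absent")
  ev1 <- dollo_losses(tree, presence)
  # swap labels A<->C consistently in tree and presence
  tree2 <- tree
  tree2$tip.label <- c(A = "C", B = "B", C = "A", D = "D")[tree$tip.label]
  presence2 <- setNames(presence, c("C", "B", "A", "D"))
  ev2 <- dollo_losses(tree2, presence2)
  expect_equal(nrow(ev1), nrow(ev2))
  map <- c(A = "C", B = "B", C = "A", D = "D")
  relabeled <- vapply(strsplit(ev1$tips_affected, ","), function(x) {
    paste(sort(map[x]), collapse = ",")
  }, character(1))
  expect_setequal(relabeled,
                  vapply(strsplit(ev2$tips_affected, ","), function(x) {
                    paste(sort(x), collapse = ",")
                  }, character(1)))
})

test_that("telomerase status combines the three characters correctly", {
  pm <- tibble::tibble(
    species = c("s1", "s2", "s3", "s4", "s5"),
    telomere_motif = c("absent", "present", "absent", "present", "unknown"),
    tr = c("absent", "present", "unknown", "absent", "unknown"),
    tert = c("absent", "present", "absent", "present", "unknown"))
  st <- classify_status(pm)$status
  expect_equal(st, c("putative telomerase loss", "telomerase-positive",
                     "inconclusive (missing data)",
                     "inconclusive (conflicting evidence)",
                     "inconclusive (missing data)"))
})

test_that("per-character loss mapping covers all three traits", {
  pm <- tibble::tibble(species = c("A", "B", "C", "D"),
                       telomere_motif = c("present", "present", "absent", "absent"),
                       tr = c("present", "present", "absent", "absent"),
                       tert = c("present", "present", "absent", "absent"))
  ev <- map_telomerase_losses(pm, "((A,B),(C,D));")
  expect_equal(nrow(ev), 3L)
  expect_setequal(ev$character, c("telomere_motif", "tr", "tert"))
  expect_equal(unique(ev$tips_affected), "C,D")
})
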