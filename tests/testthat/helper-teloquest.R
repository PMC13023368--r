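# shared fixtures and independent oracles for the test suite

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force canonicalization oracle: explicit enumeration of every
# rotation of the unit and of its reverse complement
brute_canonical <- function(unit) {
  rots <- function(u) {
    n <- nchar(u)
    vapply(seq_len(n), function(i) {
      paste0(substr(u, i, n), substr(u, 1, i - 1))
    }, character(1))
  }
  min(c(rots(unit), rots(revcomp(unit))))
}

# independent local-alignment score oracle (Biostrings dynamic programming;
# same affine convention: a k-gap costs gapOpening + k * gapExtension)
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

# a genome with clean planted telomeres and nothing else
make_telomere_genome <- function(motif = "TCAGG", n_chromosomes = 4,
                                 chrom_length = 20000, copies = 100,
                                 seed = 1) {
  set.seed(seed)
  display <- canonical_motif(motif)$display
  g <- character(0)
  for (i in seq_len(n_chromosomes)) {
    chrom <- rand_dna(chrom_length)
    left <- revcomp(strrep(display, copies))
    right <- strrep(display, copies)
    chrom <- paste0(left,
                    substr(chrom, nchar(left) + 1,
                           chrom_length - nchar(right)),
                    right)
    g[[paste0("chr", i)]] <- chrom
  }
  g
}

# single-species bundle matching the motif-recovery study conditions
make_motif_bundle <- function(seed, motif = "TCAGG", n_chromosomes = 4) {
  sp <- species_spec("S1", motif, n_chromosomes = n_chromosomes,
                     has_tert = FALSE, n_decoy_templates = 0)
  generate_dataset(bundle_spec("(S1);", sp, seed = seed))
}

# 5-species bundle matching the end-to-end study conditions (flank
# divergence 0.1, 10 decoy template loci per species)
make_discovery_bundle <- function(seed, loss_clade = NULL, n_chromosomes = 2,
                                  has_tert = TRUE) {
  sp <- dplyr::bind_rows(
    species_spec("A", "TCAGG", n_chromosomes = n_chromosomes, has_tert = has_tert),
    species_spec("B", "TCAGG", n_chromosomes = n_chromosomes, has_tert = has_tert),
    species_spec("C", "TTAGG", n_chromosomes = n_chromosomes, has_tert = has_tert),
    species_spec("D", "TTAGG", n_chromosomes = n_chromosomes, has_tert = has_tert),
    species_spec("E", "TTAGG", n_chromosomes = n_chromosomes, has_tert = has_tert))
  generate_dataset(bundle_spec("((A,B),((C,D),E));", sp,
                               loss_clade = loss_clade, seed = seed))
}

# exhaustive Dollo oracle: minimum number of cut edges separating exactly
# the absent tips from the root, by enumeration over all edge subsets
# (edge -> descendant-tip bitmask; subset union masks built incrementally)
brute_dollo_min <- function(tree, presence) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  pres <- presence[tips]
  if (is.logical(pres)) pres <- ifelse(pres, "present", "absent")
  absent_mask <- sum(2^(which(pres == "absent") - 1))
  present_mask <- sum(2^(which(pres == "present") - 1))
  if (absent_mask == 0) return(0L)
  E <- nrow(tree$edge)
  desc_mask <- vapply(seq_len(E), function(k) {
    node <- tree$edge[k, 2]
    below <- if (node <= n_tip) tips[node]
             else ape::extract.clade(tree, node)$tip.label
    sum(2^(match(below, tips) - 1))
  }, numeric(1))
  # treat "all informative tips absent" as one root-edge loss, as dollo_losses does
  if (present_mask == 0) return(1L)
  n_sub <- 2^E
  union_mask <- numeric(n_sub)
  popcount <- integer(n_sub)
  for (s in seq_len(n_sub - 1)) {
    low <- bitwAnd(s, -s)
    rest <- s - low
    union_mask[s + 1] <- bitwOr(union_mask[rest + 1], desc_mask[log2(low) + 1])
    popcount[s + 1] <- popcount[rest + 1] + 1L
  }
  valid <- bitwAnd(union_mask, absent_mask) == absent_mask &
           bitwAnd(union_mask, present_mask) == 0
  min(popcount[valid])
}
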