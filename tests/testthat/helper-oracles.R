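# Independent oracles used across the suite. These re-derive expected
# values from first principles (exhaustive enumeration, direct O(n^2 L)
# comparison) and never call the implementation paths they check.

# optimal global alignment score by exhaustive search over the three-state
# (diagonal / gap-in-b / gap-in-a) recursion with affine gap costs: a gap
# run of length L costs open + L * extend, end gaps included
oracle_align_score <- function(a, b, scoring = align_scoring()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      sub <- if (ca[i] == cb[j]) scoring$match else scoring$mismatch
      best <- max(best, sub + rec(i + 1, j + 1, "d"))
    }
    if (i <= length(ca)) {  # gap in b, consume a[i]
      cost <- scoring$gap_extend + if (prev != "gb") scoring$gap_open else 0
      best <- max(best, -cost + rec(i + 1, j, "gb"))
    }
    if (j <= length(cb)) {  # gap in a, consume b[j]
      cost <- scoring$gap_extend + if (prev != "ga") scoring$gap_open else 0
      best <- max(best, -cost + rec(i, j + 1, "ga"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "start")
}

# per-codon synonymous site fraction by direct enumeration of the 9
# single-base mutants against the standard genetic code, excluding mutants
# that are stop codons from the denominator
oracle_codon_sites <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  cc <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0
    n_ok <- 0
    for (bs in setdiff(bases, cc[pos])) {
      mut <- cc
      mut[pos] <- bs
      mutc <- paste(mut, collapse = "")
      if (gc_tab[[mutc]] == "*") next
      n_ok <- n_ok + 1
      if (gc_tab[[mutc]] == gc_tab[[codon]]) n_syn <- n_syn + 1
    }
    if (n_ok > 0) syn <- syn + n_syn / n_ok
  }
  c(syn, 3 - syn)
}

# mean pairwise difference count by explicit O(n^2 L) comparison
oracle_mean_pairwise_diff <- function(mat) {
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + sum(mat[i, ] != mat[j, ])
    }
  }
  total / choose(n, 2)
}

# build a site_frequency_spectrum object directly from a vector of derived
# allele counts (fully polarized, n haplotypes)
sfs_from_counts <- function(n, derived_counts) {
  unfolded <- integer(n - 1)
  for (d in derived_counts) unfolded[d] <- unfolded[d] + 1L
  structure(list(
    n = n, unfolded_counts = unfolded,
    S = length(derived_counts), seg_sites = length(derived_counts),
    eta = length(derived_counts),
    eta_s = sum(pmin(derived_counts, n - derived_counts) == 1),
    polarized_sites = length(derived_counts), unpolarized_sites = 0L,
    multiallelic_sites = 0L,
    site_counts = as.integer(derived_counts), has_outgroup = TRUE),
    class = "site_frequency_spectrum")
}
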