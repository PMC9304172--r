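# Codon-level lookup tables shared by the divergence and MK modules.
#
# Everything here is derived once from the standard genetic code
# (Biostrings::GENETIC_CODE) and cached in a package-local environment:
#  - per-codon synonymous / nonsynonymous site counts (NG86 "sites",
#    mutational paths to stop codons excluded from the denominator);
#  - 64 x 64 matrices of synonymous / nonsynonymous difference counts
#    (NG86 pathway averages, stop-containing paths excluded).

.codon_env <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic (A, C, G, T) order
#' @keywords internal
#' @noRd
all_codons <- function() {
  if (is.null(.codon_env$codons)) {
    g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                     stringsAsFactors = FALSE)
    .codon_env$codons <- paste0(g$b1, g$b2, g$b3)
  }
  .codon_env$codons
}

#' Amino acid for each codon, "*" for stop
#' @keywords internal
#' @noRd
codon_aa <- function() {
  if (is.null(.codon_env$aa)) {
    gc_tab <- Biostrings::GENETIC_CODE
    .codon_env$aa <- unname(gc_tab[all_codons()])
    names(.codon_env$aa) <- all_codons()
  }
  .codon_env$aa
}

#' Map codon strings to indices 1..64 (NA for codons with gap/N)
#' @keywords internal
#' @noRd
codon_index <- function(codons) {
  match(codons, all_codons())
}

is_stop_codon <- function(codons) {
  unname(codon_aa()[codons] == "*")
}

# Per-codon NG86 site counts. For each of the 3 positions the synonymous
# fraction is (# synonymous single-base changes) / (# non-stop single-base
# changes); positions whose every mutant is a stop contribute 0 synonymous.
# Site totals always sum to 3 per codon.
.compute_site_table <- function() {
  codons <- all_codons()
  aa <- codon_aa()
  syn <- numeric(64)
  for (ci in seq_len(64)) {
    cod <- codons[ci]
    if (aa[ci] == "*") {
      syn[ci] <- NA_real_
      next
    }
    s <- 0
    cc <- strsplit(cod, "")[[1]]
    for (pos in 1:3) {
      n_syn <- 0L
      n_ok <- 0L
      for (b in setdiff(BASES, cc[pos])) {
        mut <- cc
        mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (aa[mutc] == "*") next
        n_ok <- n_ok + 1L
        if (aa[mutc] == aa[ci]) n_syn <- n_syn + 1L
      }
      if (n_ok > 0L) s <- s + n_syn / n_ok
    }
    syn[ci] <- s
  }
  list(syn_sites = syn, nonsyn_sites = ifelse(is.na(syn), NA_real_, 3 - syn))
}

# 64 x 64 pathway-averaged difference counts. For codon pairs differing at
# k positions, average (Sd, Nd) over the k! orderings whose intermediate and
# end codons are all non-stop; NA when no stop-free ordering exists.
.compute_diff_tables <- function() {
  codons <- all_codons()
  aa <- codon_aa()
  sd_mat <- matrix(0, 64, 64)
  nd_mat <- matrix(0, 64, 64)
  chars <- strsplit(codons, "")

  step_class <- function(from, to) {
    # single-base change between non-stop codons: 1 = syn, 0 = nonsyn
    if (aa[from] == aa[to]) 1L else 0L
  }

  for (ia in seq_len(64)) {
    if (aa[ia] == "*") {
      sd_mat[ia, ] <- NA_real_
      nd_mat[ia, ] <- NA_real_
      next
    }
    for (ib in seq_len(64)) {
      if (aa[ib] == "*") {
        sd_mat[ia, ib] <- NA_real_
        nd_mat[ia, ib] <- NA_real_
        next
      }
      diff_pos <- which(chars[[ia]] != chars[[ib]])
      k <- length(diff_pos)
      if (k == 0L) next
      perms <- switch(k,
        list(diff_pos),
        list(diff_pos, rev(diff_pos)),
        {
          p <- list()
          for (i in 1:3) for (j in 1:3) for (l in 1:3)
            if (length(unique(c(i, j, l))) == 3)
              p[[length(p) + 1L]] <- diff_pos[c(i, j, l)]
          p
        })
      tot_s <- 0
      tot_n <- 0
      n_legal <- 0L
      for (ord in perms) {
        cur <- chars[[ia]]
        s <- 0L
        nn <- 0L
        legal <- TRUE
        for (pos in ord) {
          nxt <- cur
          nxt[pos] <- chars[[ib]][pos]
          nxtc <- paste(nxt, collapse = "")
          if (aa[nxtc] == "*") {
            legal <- FALSE
            break
          }
          if (step_class(paste(cur, collapse = ""), nxtc) == 1L) {
            s <- s + 1L
          } else {
            nn <- nn + 1L
          }
          cur <- nxt
        }
        if (legal) {
          tot_s <- tot_s + s
          tot_n <- tot_n + nn
          n_legal <- n_legal + 1L
        }
      }
      if (n_legal == 0L) {
        sd_mat[ia, ib] <- NA_real_
        nd_mat[ia, ib] <- NA_real_
      } else {
        sd_mat[ia, ib] <- tot_s / n_legal
        nd_mat[ia, ib] <- tot_n / n_legal
      }
    }
  }
  list(sd = sd_mat, nd = nd_mat)
}

ng86_tables <- function() {
  if (is.null(.codon_env$sites)) {
    .codon_env$sites <- .compute_site_table()
    diffs <- .compute_diff_tables()
    .codon_env$sd <- diffs$sd
    .codon_env$nd <- diffs$nd
  }
  list(syn_sites = .codon_env$sites$syn_sites,
       nonsyn_sites = .codon_env$sites$nonsyn_sites,
       sd = .codon_env$sd, nd = .codon_env$nd)
}

#' Translate a vector of codons to amino acids
#' @keywords internal
#' @noRd
translate_codons <- function(codons) {
  unname(codon_aa()[codons])
}

#' Split an in-frame nucleotide string into codons
#' @keywords internal
#' @noRd
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Reverse complement of a nucleotide string (A/C/G/T/N/-)
#' @keywords internal
#' @noRd
revcomp <- function(seq) {
  chartr("ACGTN-", "TGCAN-",
         vapply(strsplit(seq, ""), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

complement_base <- function(base) {
  chartr("ACGT", "TGCA", base)
}
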