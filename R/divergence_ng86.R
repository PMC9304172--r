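# Pairwise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
# correction. Codon "sites" exclude mutational paths to stop codons from the
# denominator; codon differences are averaged over all stop-free mutational
# orderings between the two codons.

#' Synonymous and nonsynonymous site counts for one codon
#'
#' For each of the three codon positions, the synonymous site fraction is the
#' proportion of the possible single-base changes that leave the amino acid
#' unchanged, counting only changes that do not create a stop codon. The
#' three fractions sum with their complements to exactly 3 sites per codon.
#'
#' @param codon A 3-character string over A/C/G/T; must not be a stop codon.
#' @return Numeric vector `c(syn_sites, nonsyn_sites)`, summing to 3.
#' @examples
#' codon_site_partition("TTT")  # c(1/3, 8/3)
#' codon_site_partition("ATG")  # c(0, 3)
#' @export
codon_site_partition <- function(codon) {
  idx <- codon_index(toupper(codon))
  if (is.na(idx)) stop("not a valid ungapped codon: ", codon)
  if (is_stop_codon(toupper(codon))) stop("stop codon: ", codon)
  tab <- ng86_tables()
  c(syn_sites = tab$syn_sites[idx], nonsyn_sites = tab$nonsyn_sites[idx])
}

#' Partition the differences between two codons into synonymous and
#' nonsynonymous counts
#'
#' Differences are averaged over all mutational orderings between the two
#' codons, excluding orderings that pass through a stop codon (the standard
#' Nei-Gojobori pathway rule). When at least one legal path exists,
#' `Sd + Nd` equals the number of differing positions.
#'
#' @param codon_a,codon_b 3-character strings over A/C/G/T; neither a stop.
#' @return Numeric vector `c(Sd, Nd)`, or `c(NA, NA)` when every mutational
#'   ordering passes through a stop codon.
#' @examples
#' codon_diff_partition("TTT", "TTC")  # c(1, 0)
#' codon_diff_partition("AAA", "AGA")  # c(0, 1)
#' @export
codon_diff_partition <- function(codon_a, codon_b) {
  ia <- codon_index(toupper(codon_a))
  ib <- codon_index(toupper(codon_b))
  if (is.na(ia) || is.na(ib)) {
    stop("not valid ungapped codons: ", codon_a, ", ", codon_b)
  }
  if (is_stop_codon(toupper(codon_a)) || is_stop_codon(toupper(codon_b))) {
    stop("stop codon in pair: ", codon_a, ", ", codon_b)
  }
  tab <- ng86_tables()
  c(Sd = tab$sd[ia, ib], Nd = tab$nd[ia, ib])
}

#' Nei-Gojobori dN/dS from a pairwise CDS alignment
#'
#' Counts synonymous and nonsynonymous sites and differences codon-by-codon
#' over the alignment, averages site totals over the two sequences, and
#' applies the Jukes-Cantor correction `d = -(3/4) log(1 - (4/3) p)` to the
#' per-site proportions. Codons containing a gap, `N`, or a stop in either
#' row are skipped, as are codon pairs with no stop-free mutational path.
#'
#' @param aln A `pairwise_alignment` (see [global_align()]) of in-frame CDS,
#'   or a list with elements `aligned_a` and `aligned_b`.
#' @param gene_id Optional identifier carried into the result.
#' @return A `divergence_estimate`: list with `gene_id`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `omega`, `n_codons`
#'   (codon pairs compared), `n_skipped`, and `flags` (character vector;
#'   `"saturated"` when a JC correction is out of domain). `omega` is `NA`
#'   unless `dS` is defined and positive.
#' @export
ng86_dnds <- function(aln, gene_id = NA_character_) {
  a <- gsub("-", "", aln$aligned_a)
  b <- gsub("-", "", aln$aligned_b)
  if (nchar(a) %% 3 != 0 || nchar(b) %% 3 != 0) {
    stop("ungapped sequences must be in frame (lengths multiple of 3)")
  }
  tab <- ng86_tables()

  if (!grepl("-", aln$aligned_a, fixed = TRUE) &&
      !grepl("-", aln$aligned_b, fixed = TRUE)) {
    # gap-free case: vectorised codon-pair lookup
    if (nchar(a) != nchar(b)) stop("alignment rows differ in length")
    ia <- codon_index(split_codons(a))
    ib <- codon_index(split_codons(b))
    ok <- !is.na(ia) & !is.na(ib)
    ok[ok] <- !is.na(tab$syn_sites[ia[ok]]) &
      !is.na(tab$syn_sites[ib[ok]]) &
      !is.na(tab$sd[cbind(ia[ok], ib[ok])])
    n_used <- sum(ok)
    n_skipped <- length(ia) - n_used
    S_a <- sum(tab$syn_sites[ia[ok]]); N_a <- sum(tab$nonsyn_sites[ia[ok]])
    S_b <- sum(tab$syn_sites[ib[ok]]); N_b <- sum(tab$nonsyn_sites[ib[ok]])
    Sd <- sum(tab$sd[cbind(ia[ok], ib[ok])])
    Nd <- sum(tab$nd[cbind(ia[ok], ib[ok])])
  } else {
    # gapped case: walk the alignment tracking row a's codon positions;
    # codons are compared where both rows contribute 3 ungapped bases in
    # the same columns
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    if (length(ca) != length(cb)) stop("alignment rows differ in length")
    pos_a <- cumsum(ca != "-")
    codon_of_a <- ifelse(ca == "-", NA_integer_, (pos_a - 1) %/% 3 + 1)
    n_cod_a <- nchar(a) %/% 3
    S_a <- 0; N_a <- 0; S_b <- 0; N_b <- 0; Sd <- 0; Nd <- 0
    n_used <- 0L
    n_skipped <- 0L
    for (k in seq_len(n_cod_a)) {
      cols <- which(codon_of_a == k)
      if (length(cols) != 3 || any(cb[cols] == "-")) {
        n_skipped <- n_skipped + 1L
        next
      }
      ia <- codon_index(paste(ca[cols], collapse = ""))
      ib <- codon_index(paste(cb[cols], collapse = ""))
      if (is.na(ia) || is.na(ib) ||
          is.na(tab$syn_sites[ia]) || is.na(tab$syn_sites[ib]) ||
          is.na(tab$sd[ia, ib])) {
        n_skipped <- n_skipped + 1L
        next
      }
      S_a <- S_a + tab$syn_sites[ia]; N_a <- N_a + tab$nonsyn_sites[ia]
      S_b <- S_b + tab$syn_sites[ib]; N_b <- N_b + tab$nonsyn_sites[ib]
      Sd <- Sd + tab$sd[ia, ib]; Nd <- Nd + tab$nd[ia, ib]
      n_used <- n_used + 1L
    }
  }

  S_sites <- (S_a + S_b) / 2
  N_sites <- (N_a + N_b) / 2
  flags <- character(0)
  pS <- if (S_sites > 0) Sd / S_sites else NA_real_
  pN <- if (N_sites > 0) Nd / N_sites else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -(3 / 4) * log(1 - (4 / 3) * p)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  if ((!is.na(pS) && pS >= 3 / 4) || (!is.na(pN) && pN >= 3 / 4)) {
    flags <- c(flags, "saturated")
  }
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(gene_id = gene_id,
                 S_sites = S_sites, N_sites = N_sites,
                 Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 n_codons = n_used, n_skipped = n_skipped,
                 flags = flags),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("NG86 divergence%s: dN = %s, dS = %s, omega = %s (%d codons)\n",
              if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
              format(x$dN, digits = 4), format(x$dS, digits = 4),
              format(x$omega, digits = 4), x$n_codons))
  invisible(x)
}

#' Tabulate a list of divergence estimates
#'
#' @param estimates List of `divergence_estimate` objects.
#' @return A data.frame with one row per estimate (gene_id, S_sites, N_sites,
#'   Sd, Nd, dS, dN, omega, flags).
#' @export
divergence_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(gene_id = e$gene_id, S_sites = e$S_sites, N_sites = e$N_sites,
               Sd = e$Sd, Nd = e$Nd, dS = e$dS, dN = e$dN, omega = e$omega,
               flags = paste(e$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
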