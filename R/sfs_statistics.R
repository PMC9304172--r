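# Site-frequency-spectrum statistics from per-gene multi-accession
# haplotype alignments with an outgroup: Tajima's D, Fu & Li's D* (with the
# Simonsen et al. 1995 corrected variance constants), Fay & Wu's H
# (unnormalized theta_pi - theta_H by default, or the Zeng et al. 2006
# normalized form) and Zeng's E. Profiles carry the >= 50 segregating-site
# validity rule.

#' Construct a haplotype alignment for one gene
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#'   A row named `"outgroup"` (case-insensitive) is treated as the outgroup
#'   used for polarization; the remaining rows are the ingroup haplotypes.
#' @param gene_id Gene identifier.
#' @return A `haplotype_alignment`: list with `gene_id`, `haplotypes`
#'   (character matrix, one row per ingroup haplotype) and `outgroup`
#'   (character vector or `NULL`).
#' @export
haplotype_alignment <- function(seqs, gene_id = NA_character_) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("aligned rows differ in length")
  is_og <- tolower(names(seqs)) == "outgroup"
  if (sum(is_og) > 1) stop("more than one outgroup row")
  ingroup <- seqs[!is_og]
  if (length(ingroup) < 2) stop("need at least 2 ingroup haplotypes")
  mat <- do.call(rbind, strsplit(toupper(ingroup), ""))
  rownames(mat) <- names(ingroup)
  og <- if (any(is_og)) strsplit(toupper(seqs[is_og][[1]]), "")[[1]] else NULL
  structure(list(gene_id = gene_id, haplotypes = mat, outgroup = og),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment %s: n = %d, L = %d, outgroup: %s\n",
              x$gene_id, nrow(x$haplotypes), ncol(x$haplotypes),
              if (is.null(x$outgroup)) "absent" else "present"))
  invisible(x)
}

#' Read a per-gene haplotype FASTA (ingroup rows plus optional "outgroup")
#' @param path FASTA path.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return A `haplotype_alignment`.
#' @export
read_haplotype_fasta <- function(path, gene_id = NULL) {
  if (is.null(gene_id)) {
    gene_id <- sub("\\.(fa|fasta)(\\.gz)?$", "", basename(path))
  }
  haplotype_alignment(read_fasta(path), gene_id = gene_id)
}

#' Build the site frequency spectrum from a haplotype alignment
#'
#' Sites with a gap or `N` in any used row (ingroup and outgroup when
#' present) are excluded, as are ingroup-multiallelic sites. For each
#' biallelic ingroup site the ancestral state is the outgroup allele when it
#' matches one of the two ingroup alleles; otherwise the site is counted as
#' unpolarized and excluded from the unfolded spectrum (but still counted as
#' a segregating site for the folded statistics).
#'
#' @param aln A `haplotype_alignment`.
#' @return A `site_frequency_spectrum`: list with `n`, `unfolded_counts`
#'   (length `n - 1`; class i = sites with i derived copies), `S`
#'   (polarized segregating sites), `seg_sites` (all biallelic ingroup
#'   segregating sites), `eta` (total mutations, equal to `seg_sites` under
#'   the biallelic rule), `eta_s` (minor-allele singleton count),
#'   `polarized_sites`, `unpolarized_sites`, `multiallelic_sites`,
#'   `site_counts` (allele-2 count per biallelic site, for folded sums) and
#'   `has_outgroup`.
#' @export
build_sfs <- function(aln) {
  M <- aln$haplotypes
  n <- nrow(M)
  L <- ncol(M)
  og <- aln$outgroup
  has_og <- !is.null(og)

  bad <- colSums(M == "N" | M == "-") > 0
  if (has_og) bad <- bad | og == "N" | og == "-"
  # candidate segregating columns among the clean ones
  differs <- colSums(M != matrix(M[1, ], n, L, byrow = TRUE)) > 0
  cand <- which(!bad & differs)

  unfolded <- integer(n - 1)
  site_counts <- integer(0)
  multiallelic <- 0L
  unpolarized <- 0L
  eta_s <- 0L
  for (j in cand) {
    tab <- table(M[, j])
    if (length(tab) > 2) {
      multiallelic <- multiallelic + 1L
      next
    }
    alleles <- names(tab)
    c2 <- as.integer(tab[2])
    site_counts <- c(site_counts, c2)
    if (min(tab) == 1L) eta_s <- eta_s + 1L
    if (has_og && og[j] %in% alleles) {
      derived_count <- as.integer(n - tab[og[j]])
      unfolded[derived_count] <- unfolded[derived_count] + 1L
    } else {
      unpolarized <- unpolarized + 1L
    }
  }
  S_pol <- sum(unfolded)
  structure(list(n = n,
                 unfolded_counts = unfolded,
                 S = S_pol,
                 seg_sites = length(site_counts),
                 eta = length(site_counts),
                 eta_s = eta_s,
                 polarized_sites = S_pol,
                 unpolarized_sites = unpolarized,
                 multiallelic_sites = multiallelic,
                 site_counts = site_counts,
                 has_outgroup = has_og),
            class = "site_frequency_spectrum")
}

#' @export
print.site_frequency_spectrum <- function(x, ...) {
  cat(sprintf(paste0("SFS: n = %d, segregating sites = %d ",
                     "(%d polarized, %d unpolarized), singletons = %d\n"),
              x$n, x$seg_sites, x$polarized_sites, x$unpolarized_sites,
              x$eta_s))
  invisible(x)
}

#' Constants of the frequency-spectrum test statistics for sample size n
#'
#' `a1 = sum(1/i)` and `a2 = sum(1/i^2)` for `i = 1..n-1`; the Tajima (1989)
#' variance terms `b1, b2, c1, c2, e1, e2`; the Fu & Li (1993) D* terms
#' `u_star, v_star` with the Simonsen et al. (1995) correction.
#'
#' @param n Number of haplotypes (`n >= 2`; D* terms need `n >= 4`).
#' @return Named list of constants.
#' @export
spectrum_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  u_star <- NA_real_
  v_star <- NA_real_
  if (n >= 4) {
    an1 <- a1 + 1 / n
    cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
    dn <- cn + (n - 2) / (n - 1)^2 +
      (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
    v_star <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
                 2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
    u_star <- (n / (n - 1)) * (a1 - n / (n - 1)) - v_star
  }
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2, u_star = u_star, v_star = v_star)
}

# unbiased plug-ins for theta and theta^2 used by the H and E variances
.theta_plugins <- function(S, a1, a2) {
  list(theta = S / a1, theta2 = S * (S - 1) / (a1^2 + a2))
}

#' Theta estimators from the unfolded spectrum
#'
#' Computed over the polarized sites: `theta_w = S / a1`,
#' `theta_pi = sum(2 i (n - i) S_i) / (n (n - 1))`,
#' `theta_h = sum(2 i^2 S_i) / (n (n - 1))`,
#' `theta_l = sum(i S_i) / (n - 1)`. The identity
#' `theta_pi - theta_h = 2 (theta_pi - theta_l)` holds exactly.
#'
#' @param sfs A `site_frequency_spectrum`.
#' @return List with `theta_w`, `theta_pi`, `theta_h`, `theta_l`.
#' @export
theta_estimators <- function(sfs) {
  n <- sfs$n
  i <- seq_len(n - 1)
  Si <- sfs$unfolded_counts
  a1 <- sum(1 / i)
  list(theta_w = sfs$S / a1,
       theta_pi = sum(2 * i * (n - i) * Si) / (n * (n - 1)),
       theta_h = sum(2 * i^2 * Si) / (n * (n - 1)),
       theta_l = sum(i * Si) / (n - 1))
}

#' Tajima's D
#'
#' Uses all biallelic ingroup segregating sites; polarization is not
#' required because pairwise diversity is symmetric in the two alleles.
#' `D = (theta_pi - theta_w) / sqrt(e1 S + e2 S (S - 1))` with the Tajima
#' (1989) constants.
#'
#' @param sfs A `site_frequency_spectrum`.
#' @return D, or `NA` when `S = 0` or the variance term is not positive.
#' @export
tajimas_d <- function(sfs) {
  n <- sfs$n
  S <- sfs$seg_sites
  if (S < 1 || n < 3) return(NA_real_)
  k <- spectrum_constants(n)
  cc <- sfs$site_counts
  theta_pi <- sum(2 * cc * (n - cc)) / (n * (n - 1))
  theta_w <- S / k$a1
  num <- theta_pi - theta_w
  v <- k$e1 * S + k$e2 * S * (S - 1)
  # at n = 3 the variance coefficients vanish identically; a zero
  # numerator still has the well-defined limit D = 0
  if (v <= 0) return(if (abs(num) < 1e-12) 0 else NA_real_)
  num / sqrt(v)
}

#' Fu and Li's D* (without an outgroup)
#'
#' `D* = ((n/(n-1)) eta - a1 eta_s) / sqrt(u* eta + v* eta^2)` with the
#' Simonsen et al. (1995)-corrected constants. Singletons are sites whose
#' rarer allele occurs in exactly one ingroup haplotype, so no outgroup is
#' needed.
#'
#' @param sfs A `site_frequency_spectrum`.
#' @return D*, or `NA` when `eta = 0`, `n < 4`, or the variance term is not
#'   positive.
#' @export
fu_li_d_star <- function(sfs) {
  n <- sfs$n
  eta <- sfs$eta
  if (eta < 1 || n < 4) return(NA_real_)
  k <- spectrum_constants(n)
  v <- k$u_star * eta + k$v_star * eta^2
  if (v <= 0) return(NA_real_)
  ((n / (n - 1)) * eta - k$a1 * sfs$eta_s) / sqrt(v)
}

#' Fay and Wu's H
#'
#' Unnormalized (default): `H = theta_pi - theta_h`, the classic Fay & Wu
#' (2000) form whose magnitude grows with diversity. Normalized:
#' `(theta_pi - theta_l) / sqrt(Var)` with the Zeng et al. (2006) variance,
#' plugging in `theta_w` for theta and `S (S - 1) / (a1^2 + a2)` for
#' theta squared. Both use polarized sites only.
#'
#' @param sfs A `site_frequency_spectrum`.
#' @param variant `"unnormalized"` or `"normalized"`.
#' @return H, or `NA` when there are no polarized sites (or `n < 4` /
#'   non-positive variance for the normalized variant).
#' @export
fay_wu_h <- function(sfs, variant = c("unnormalized", "normalized")) {
  variant <- match.arg(variant)
  if (sfs$polarized_sites < 1) return(NA_real_)
  th <- theta_estimators(sfs)
  if (variant == "unnormalized") {
    return(th$theta_pi - th$theta_h)
  }
  n <- sfs$n
  if (n < 4) return(NA_real_)
  k <- spectrum_constants(n)
  pl <- .theta_plugins(sfs$S, k$a1, k$a2)
  bn1 <- k$a2 + 1 / n^2  # sum_{i=1}^{n} 1/i^2
  v <- (n - 2) / (6 * (n - 1)) * pl$theta +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * pl$theta2
  if (v <= 0) return(NA_real_)
  (th$theta_pi - th$theta_l) / sqrt(v)
}

#' Zeng's E
#'
#' `E = (theta_l - theta_w) / sqrt(Var(theta_l - theta_w))` with the Zeng
#' et al. (2006) variance, over polarized sites. Sensitive to a deficit
#' (negative E) or excess (positive E) of high-frequency derived alleles
#' relative to the low-frequency classes.
#'
#' @param sfs A `site_frequency_spectrum`.
#' @return E, or `NA` when there are no polarized sites, `n < 4`, or the
#'   variance term is not positive.
#' @export
zeng_e <- function(sfs) {
  n <- sfs$n
  if (sfs$polarized_sites < 1 || n < 4) return(NA_real_)
  k <- spectrum_constants(n)
  th <- theta_estimators(sfs)
  pl <- .theta_plugins(sfs$S, k$a1, k$a2)
  bn <- k$a2
  v <- (n / (2 * (n - 1)) - 1 / k$a1) * pl$theta +
    (bn / k$a1^2 + 2 * (n / (n - 1))^2 * bn -
       2 * (n * bn - n + 1) / ((n - 1) * k$a1) -
       (3 * n + 1) / (n - 1)) * pl$theta2
  if (v <= 0) return(NA_real_)
  (th$theta_l - th$theta_w) / sqrt(v)
}

#' Per-gene neutrality profile with the segregating-site validity rule
#'
#' Computes Tajima's D, Fu & Li's D*, Fay & Wu's H and Zeng's E for one
#' gene. Estimates based on fewer than `min_seg_sites` biallelic ingroup
#' segregating sites are considered unreliable: the profile is flagged
#' invalid and carries no statistic values.
#'
#' @param aln A `haplotype_alignment`.
#' @param min_seg_sites Validity threshold, default 50.
#' @param h_variant Passed to [fay_wu_h()].
#' @return One-row data.frame: `gene_id`, `n`, `seg_sites`,
#'   `polarized_sites`, `theta_w`, `theta_pi`, `theta_h`, `theta_l`,
#'   `D`, `D_star`, `H`, `E`, `valid`.
#' @export
profile_gene <- function(aln, min_seg_sites = 50,
                         h_variant = "unnormalized") {
  sfs <- build_sfs(aln)
  valid <- sfs$seg_sites >= min_seg_sites
  if (valid) {
    th <- theta_estimators(sfs)
    out <- data.frame(
      gene_id = aln$gene_id, n = sfs$n, seg_sites = sfs$seg_sites,
      polarized_sites = sfs$polarized_sites,
      theta_w = th$theta_w, theta_pi = th$theta_pi,
      theta_h = th$theta_h, theta_l = th$theta_l,
      D = tajimas_d(sfs), D_star = fu_li_d_star(sfs),
      H = fay_wu_h(sfs, h_variant), E = zeng_e(sfs),
      valid = TRUE, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      gene_id = aln$gene_id, n = sfs$n, seg_sites = sfs$seg_sites,
      polarized_sites = sfs$polarized_sites,
      theta_w = NA_real_, theta_pi = NA_real_,
      theta_h = NA_real_, theta_l = NA_real_,
      D = NA_real_, D_star = NA_real_, H = NA_real_, E = NA_real_,
      valid = FALSE, stringsAsFactors = FALSE)
  }
  out
}
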