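# McDonald-Kreitman style statistics: per-SNP synonymous/nonsynonymous
# classification across all transcripts, assembly of Dn/Ds/Pn/Ps count
# tables, the neutrality index NI and the direction of selection DOS.

#' Classify a SNP as synonymous, nonsynonymous, ambiguous or noncoding
#'
#' The SNP is mapped into every transcript of the gene model that covers its
#' position; for each, the (strand-adjusted) ALT allele is substituted into
#' the codon and the amino acids compared. A SNP whose status differs
#' between transcripts (different reading frames) is `"ambiguous"`; a SNP
#' outside all CDS intervals is `"noncoding"`. Changes to or from a stop
#' codon count as nonsynonymous unless both codons are stops.
#'
#' @param snp One-row data.frame (or list) with `pos`, `ref`, `alt`.
#' @param model A `gene_model`.
#' @param reference_cds Named list of mRNA-sense CDS strings, one per
#'   transcript of the model.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"ambiguous"`,
#'   `"noncoding"`.
#' @export
classify_snp <- function(snp, model, reference_cds) {
  statuses <- character(0)
  for (tid in names(model$transcripts)) {
    intervals <- model$transcripts[[tid]]
    off <- cds_offset(snp$pos, intervals, model$strand)
    if (is.na(off)) next
    cds <- reference_cds[[tid]]
    if (is.null(cds)) stop("no reference CDS for transcript ", tid)
    ref_allele <- if (model$strand == "+") snp$ref else
      complement_base(snp$ref)
    alt_allele <- if (model$strand == "+") snp$alt else
      complement_base(snp$alt)
    have <- substr(cds, off, off)
    if (have != ref_allele) {
      stop("REF allele mismatch for transcript ", tid, " at CDS offset ",
           off, ": CDS has ", have, ", VCF REF maps to ", ref_allele)
    }
    codon_start <- off - (off - 1) %% 3
    codon <- substr(cds, codon_start, codon_start + 2)
    mut <- codon
    substr(mut, off - codon_start + 1, off - codon_start + 1) <- alt_allele
    aa_ref <- translate_codons(codon)
    aa_alt <- translate_codons(mut)
    statuses <- c(statuses,
                  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous")
  }
  if (length(statuses) == 0) return("noncoding")
  if (length(unique(statuses)) > 1) return("ambiguous")
  statuses[1]
}

#' Assemble a McDonald-Kreitman count table for one gene
#'
#' Polymorphism counts are per segregating site (each site once, regardless
#' of how many accessions carry the allele); ambiguous and noncoding SNPs
#' are excluded. Substitution counts come from the gene's interspecific
#' divergence estimate: the fractional Nei-Gojobori pathway sums `Nd` and
#' `Sd` rounded half-away-from-zero to integers, since MK counts are
#' contingency-table entries.
#'
#' @param gene_id Gene identifier.
#' @param snp_classes Character vector of per-segregating-site classes as
#'   returned by [classify_snp()].
#' @param divergence A `divergence_estimate` for the gene (see
#'   [ng86_dnds()]).
#' @return An `mk_table`: list with `gene_id`, `Dn`, `Ds`, `Pn`, `Ps`.
#' @export
count_mk_table <- function(gene_id, snp_classes, divergence) {
  round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  structure(list(
    gene_id = gene_id,
    Dn = as.integer(round_half_away(divergence$Nd)),
    Ds = as.integer(round_half_away(divergence$Sd)),
    Pn = sum(snp_classes == "nonsynonymous"),
    Ps = sum(snp_classes == "synonymous")),
    class = "mk_table")
}

#' Neutrality index (log odds with pseudo-counts)
#'
#' `NI = log([2 Ds + 1][2 Pn + 1] / ([2 Dn + 1][2 Ps + 1]))`. The doubled
#' counts plus one make the index finite for every table. Positive values
#' indicate an excess of nonsynonymous polymorphism (consistent with
#' purifying/weak negative selection); negative values an excess of
#' nonsynonymous fixation.
#'
#' @param t An `mk_table` or list with `Dn`, `Ds`, `Pn`, `Ps`.
#' @param log_base `"e"` (natural log, the default log-odds convention)
#'   or `"10"`.
#' @return The neutrality index (finite real).
#' @export
neutrality_index <- function(t, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  x <- (2 * t$Ds + 1) * (2 * t$Pn + 1) / ((2 * t$Dn + 1) * (2 * t$Ps + 1))
  if (log_base == "e") log(x) else log10(x)
}

#' Direction of selection
#'
#' `DOS = Dn/(Dn + Ds) - Pn/(Pn + Ps)`, in `[-1, 1]`; positive values
#' suggest adaptive fixation. Undefined (`NA`) when either margin is zero.
#'
#' @param t An `mk_table` or list with `Dn`, `Ds`, `Pn`, `Ps`.
#' @return DOS, or `NA` when `Dn + Ds == 0` or `Pn + Ps == 0`.
#' @export
direction_of_selection <- function(t) {
  if ((t$Dn + t$Ds) == 0 || (t$Pn + t$Ps) == 0) return(NA_real_)
  t$Dn / (t$Dn + t$Ds) - t$Pn / (t$Pn + t$Ps)
}

#' Tabulate MK tables with NI and DOS
#'
#' @param tables List of `mk_table` objects.
#' @param log_base Passed to [neutrality_index()].
#' @return data.frame with gene_id, Dn, Ds, Pn, Ps, NI, DOS.
#' @export
mk_table_summary <- function(tables, log_base = "e") {
  do.call(rbind, lapply(tables, function(t) {
    data.frame(gene_id = t$gene_id, Dn = t$Dn, Ds = t$Ds,
               Pn = t$Pn, Ps = t$Ps,
               NI = neutrality_index(t, log_base),
               DOS = direction_of_selection(t),
               stringsAsFactors = FALSE)
  }))
}

#' Classify the polymorphic sites of a CDS haplotype alignment
#'
#' Column-level equivalent of [classify_snp()] for in-frame per-gene
#' haplotype alignments (no gene model needed): each biallelic ingroup
#' segregating site is classified by substituting the alternative allele
#' into the codon context of the first ingroup haplotype. Changes to or
#' from a stop codon are nonsynonymous. Sites with gaps, `N`, codons
#' containing another ambiguity, or more than two alleles are skipped.
#'
#' @param aln A `haplotype_alignment` whose rows are in-frame CDS.
#' @return Character vector of `"synonymous"` / `"nonsynonymous"`, one per
#'   classified segregating site.
#' @export
classify_polymorphic_sites <- function(aln) {
  M <- aln$haplotypes
  n <- nrow(M)
  L <- ncol(M)
  if (L %% 3 != 0) stop("alignment length is not a multiple of 3")
  bad <- colSums(M == "N" | M == "-") > 0
  seg <- which(!bad &
                 colSums(M != matrix(M[1, ], n, L, byrow = TRUE)) > 0)
  classes <- character(0)
  for (j in seg) {
    alleles <- unique(M[, j])
    if (length(alleles) != 2) next
    ref <- M[1, j]
    alt <- setdiff(alleles, ref)
    cstart <- j - (j - 1) %% 3
    codon <- paste(M[1, cstart:(cstart + 2)], collapse = "")
    if (is.na(codon_index(codon))) next
    mut <- codon
    substr(mut, j - cstart + 1, j - cstart + 1) <- alt
    classes <- c(classes,
                 if (translate_codons(codon) == translate_codons(mut))
                   "synonymous" else "nonsynonymous")
  }
  classes
}
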