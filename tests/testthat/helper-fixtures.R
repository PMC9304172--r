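# Small fixture builders; everything is generated in code at test time.

random_cds_string <- function(n_codons) {
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[Biostrings::GENETIC_CODE != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# a random single-transcript gene model with its mRNA-sense CDS, placed on
# a small genomic scaffold with 1-3 CDS intervals
random_gene_fixture <- function(gene_id = "g1", strand = sample(c("+", "-"), 1)) {
  n_iv <- sample(1:3, 1)
  iv_lens <- 3 * sample(2:6, n_iv, replace = TRUE)
  gaps <- sample(3:20, n_iv, replace = TRUE)
  starts <- cumsum(gaps + c(0, iv_lens[-n_iv]))
  intervals <- data.frame(start = starts, end = starts + iv_lens - 1)
  model <- gene_model(gene_id, "chr1", strand,
                      stats::setNames(list(intervals), paste0(gene_id, ".1")))
  cds <- random_cds_string(sum(iv_lens) / 3)
  list(model = model, cds = cds)
}

write_test_vcf <- function(path, samples = c("acc1", "acc2"),
                           records, contig = "chr1") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=100000>", contig),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# haplotype alignment built from explicit row strings
aln_from_strings <- function(..., outgroup = NULL, gene_id = "g") {
  seqs <- c(...)
  names(seqs) <- paste0("hap", seq_along(seqs))
  if (!is.null(outgroup)) seqs <- c(seqs, outgroup = outgroup)
  haplotype_alignment(seqs, gene_id = gene_id)
}

# an alignment of `n` identical rows of length L with `n_seg` biallelic
# segregating sites (hap1 carries the alternative allele), plus an
# ancestral-matching outgroup
aln_with_seg_sites <- function(n, L, n_seg) {
  base <- random_cds_string(ceiling(L / 3))
  base <- substr(base, 1, L)
  rows <- rep(base, n)
  pos <- sample.int(L, n_seg)
  r1 <- strsplit(rows[1], "")[[1]]
  for (p in pos) r1[p] <- setdiff(c("A", "C", "G", "T"), r1[p])[1]
  rows[1] <- paste(r1, collapse = "")
  names(rows) <- paste0("hap", seq_len(n))
  haplotype_alignment(c(rows, outgroup = base), gene_id = "gseg")
}

# simulated per-gene statistics table of the kind the pipeline assembles:
# omega from NG86 on simulated ortholog pairs, NI/DOS from Poisson MK
# tables, D/D*/H/E from neutral coalescent spectra
simulate_statistics_profile <- function(n_genes, n = 20, theta = 20,
                                        L_codons = 200) {
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  omega <- numeric(n_genes)
  NI <- DOS <- D <- Ds <- H <- E <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    p <- simulate_ortholog_pair(L_codons, stats::rlnorm(1, log(0.25), 0.5),
                                0.1)
    omega[g] <- ng86_dnds(list(aligned_a = p$cds_a,
                               aligned_b = p$cds_b))$omega
    mk <- simulate_mk_counts(c(5, 10, 8, 10))
    NI[g] <- neutrality_index(mk)
    DOS[g] <- direction_of_selection(mk)
    a <- simulate_coalescent_gene(n, theta, L_codons * 3)
    s <- build_sfs(a)
    D[g] <- tajimas_d(s)
    Ds[g] <- fu_li_d_star(s)
    H[g] <- fay_wu_h(s)
    E[g] <- zeng_e(s)
  }
  data.frame(gene_id = gene_ids, omega = omega, NI = NI, DOS = DOS,
             D = D, D_star = Ds, H = H, E = E, stringsAsFactors = FALSE)
}
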