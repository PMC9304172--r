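# Generators for every input the pipeline consumes, with known ground
# truth: a neutral n-coalescent with infinite-sites mutation for per-gene
# haplotype alignments (plus a diverged outgroup row), spectrum skewing to
# emulate sweep-like and inbreeding-like site frequency spectra, a
# codon-level ortholog divergence generator with controllable omega,
# Poisson MK tables, and replicate-structured knockout fitness tables.

non_stop_codon_indices <- function() {
  which(codon_aa() != "*")
}

random_cds <- function(L_codons) {
  idx <- sample(non_stop_codon_indices(), L_codons, replace = TRUE)
  paste(all_codons()[idx], collapse = "")
}

#' Simulate one gene under the neutral coalescent with infinite sites
#'
#' Genealogy: exponential coalescence times with rate `choose(k, 2)` while k
#' lineages remain; mutations are Poisson on branches with rate `theta / 2`
#' per lineage per unit of coalescent time, each hitting a distinct,
#' uniformly chosen site. The expected number of segregating sites is
#' `theta * sum(1/i, i = 1..n-1)`. The outgroup row carries the ancestral
#' allele plus independent Poisson divergence mutations
#' (`outgroup_divergence` expected substitutions per site).
#'
#' @param n Number of ingroup haplotypes (>= 2).
#' @param theta Per-locus population mutation rate (> 0).
#' @param L_sites Locus length in sites; when a multiple of 3 the ancestral
#'   sequence is a stop-free CDS, so the alignment can also feed the
#'   polymorphism classifier.
#' @param seed Optional integer seed (`set.seed` when non-NULL).
#' @param outgroup_divergence Expected outgroup substitutions per site.
#' @param gene_id Identifier for the resulting alignment.
#' @return A `haplotype_alignment` with an extra `ancestral` element (the
#'   true ancestral sequence as a string).
#' @export
simulate_coalescent_gene <- function(n, theta, L_sites, seed = NULL,
                                     outgroup_divergence = 0.1,
                                     gene_id = "gene") {
  stopifnot(n >= 2, theta >= 0, L_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  lineages <- as.list(seq_len(n))
  carriers <- list()
  k <- n
  while (k > 1) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    m <- stats::rpois(1, theta / 2 * k * t_k)
    if (m > 0) {
      hit <- sample.int(k, m, replace = TRUE)
      for (j in hit) carriers[[length(carriers) + 1L]] <- lineages[[j]]
    }
    pair <- sample.int(k, 2)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    k <- k - 1L
  }
  # drop mutations carried by everyone (above the root they are invisible)
  carriers <- carriers[vapply(carriers, length, 0L) < n]
  M_mut <- length(carriers)
  if (M_mut > L_sites) {
    stop("more mutations (", M_mut, ") than sites (", L_sites,
         "); increase L_sites")
  }
  anc <- if (L_sites %% 3 == 0) random_cds(L_sites / 3) else
    paste(sample(BASES, L_sites, replace = TRUE), collapse = "")
  anc_chars <- strsplit(anc, "")[[1]]
  mat <- matrix(rep(anc_chars, each = n), nrow = n)
  if (M_mut > 0) {
    positions <- sample.int(L_sites, M_mut)
    for (i in seq_len(M_mut)) {
      derived <- sample(setdiff(BASES, anc_chars[positions[i]]), 1)
      mat[carriers[[i]], positions[i]] <- derived
    }
  }
  og <- anc_chars
  n_div <- stats::rpois(1, outgroup_divergence * L_sites)
  if (n_div > 0) {
    dpos <- sample.int(L_sites, min(n_div, L_sites))
    for (p in dpos) og[p] <- sample(setdiff(BASES, og[p]), 1)
  }
  rownames(mat) <- paste0("hap", seq_len(n))
  structure(list(gene_id = gene_id, haplotypes = mat, outgroup = og,
                 ancestral = anc),
            class = "haplotype_alignment")
}

#' Skew the site frequency spectrum of a simulated alignment
#'
#' Re-draws the derived-allele count of each polymorphic site towards the
#' singleton class (`"singleton_excess"`, sweep- or expansion-like) or the
#' `n - 1` class (`"high_freq_excess"`) with probability `intensity`,
#' reassigning carriers at random. Site count is preserved;
#' `intensity = 0` (or mode `"neutral"`) returns the alignment unchanged.
#'
#' @param aln A `haplotype_alignment` with an `ancestral` element (as
#'   produced by [simulate_coalescent_gene()]).
#' @param mode `"neutral"`, `"singleton_excess"` or `"high_freq_excess"`.
#' @param intensity Probability in `[0, 1]` that a site is moved to the
#'   target class.
#' @param seed Optional integer seed.
#' @return A `haplotype_alignment` of the same shape.
#' @export
skew_spectrum <- function(aln, mode = c("neutral", "singleton_excess",
                                        "high_freq_excess"),
                          intensity = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(intensity >= 0, intensity <= 1)
  if (mode == "neutral" || intensity == 0) return(aln)
  if (is.null(aln$ancestral)) stop("alignment has no ancestral sequence")
  if (!is.null(seed)) set.seed(seed)
  mat <- aln$haplotypes
  n <- nrow(mat)
  anc <- strsplit(aln$ancestral, "")[[1]]
  target <- if (mode == "singleton_excess") 1L else n - 1L
  seg <- which(colSums(mat != matrix(anc, n, ncol(mat), byrow = TRUE)) > 0)
  for (j in seg) {
    alleles <- unique(mat[, j])
    derived <- setdiff(alleles, anc[j])
    if (length(derived) != 1) next  # multiallelic: leave as is
    if (stats::runif(1) < intensity) {
      mat[, j] <- anc[j]
      mat[sample.int(n, target), j] <- derived
    }
  }
  out <- aln
  out$haplotypes <- mat
  out
}

#' Simulate an ortholog CDS pair with controllable omega
#'
#' Evolves a random stop-free CDS along one branch. The target number of
#' substitutions is Poisson with mean `branch_length * 3 * L_codons`;
#' candidate single-base codon changes are accepted with relative rate 1
#' when synonymous and `omega_true` when nonsynonymous, and changes
#' creating a stop codon are rejected.
#'
#' @param L_codons CDS length in codons.
#' @param omega_true True dN/dS of the generating process (>= 0).
#' @param branch_length Expected substitutions per site (before selection
#'   thinning).
#' @param seed Optional integer seed.
#' @param gene_id Identifier.
#' @return List with `gene_id`, `cds_a` (ancestral-side sequence), `cds_b`
#'   (evolved sequence), `n_subs` (accepted substitutions).
#' @export
simulate_ortholog_pair <- function(L_codons, omega_true, branch_length,
                                   seed = NULL, gene_id = "gene") {
  stopifnot(L_codons >= 2, omega_true >= 0, branch_length >= 0)
  if (!is.null(seed)) set.seed(seed)
  codons <- all_codons()
  aa <- codon_aa()
  seq_a <- sample(non_stop_codon_indices(), L_codons, replace = TRUE)
  seq_b <- seq_a
  target <- stats::rpois(1, branch_length * 3 * L_codons)
  max_rate <- max(1, omega_true)
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 1000L + 200L * target *
    ceiling(max_rate / max(omega_true, 0.01))
  # proposals are pre-drawn in batches; the acceptance decision still runs
  # sequentially because substitutions at the same codon interact
  batch <- max(64L, 4L * target)
  pow <- c(16L, 4L, 1L)
  while (accepted < target && attempts < max_attempts) {
    ci_v <- sample.int(L_codons, batch, replace = TRUE)
    pos_v <- sample.int(3L, batch, replace = TRUE)
    off_v <- sample.int(3L, batch, replace = TRUE)  # which other base
    u_v <- stats::runif(batch)
    for (t in seq_len(batch)) {
      if (accepted >= target || attempts >= max_attempts) break
      attempts <- attempts + 1L
      ci <- ci_v[t]
      pos <- pos_v[t]
      old_idx <- seq_b[ci]
      # base at position pos (0..3), codon index base-4, first base major
      cur_b <- ((old_idx - 1L) %/% pow[pos]) %% 4L
      nb <- (cur_b + off_v[t]) %% 4L  # one of the 3 other bases, uniform
      new_idx <- old_idx + (nb - cur_b) * pow[pos]
      if (aa[new_idx] == "*") next
      rate <- if (aa[new_idx] == aa[old_idx]) 1 else omega_true
      if (rate <= 0) next
      if (u_v[t] <= rate / max_rate) {
        seq_b[ci] <- new_idx
        accepted <- accepted + 1L
      }
    }
  }
  list(gene_id = gene_id,
       cds_a = paste(codons[seq_a], collapse = ""),
       cds_b = paste(codons[seq_b], collapse = ""),
       n_subs = accepted)
}

#' Simulate an MK count table with independent Poisson cells
#'
#' @param rates Numeric vector of expected `c(Dn, Ds, Pn, Ps)` (named or in
#'   that order).
#' @param seed Optional integer seed.
#' @param gene_id Identifier.
#' @return An `mk_table`.
#' @export
simulate_mk_counts <- function(rates, seed = NULL, gene_id = "gene") {
  stopifnot(length(rates) == 4, all(rates >= 0))
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rpois(4, rates)
  structure(list(gene_id = gene_id, Dn = draws[1], Ds = draws[2],
                 Pn = draws[3], Ps = draws[4]),
            class = "mk_table")
}

#' Simulate a replicate-structured knockout fitness table
#'
#' Wild-type fruit counts are Poisson around a chamber-specific mean;
#' knockout counts are Poisson around the wild-type mean times
#' `1 + gene effect` (the effect is `-effect` for candidate genes and 0
#' otherwise) times mean-one lognormal gene-level noise of (log-scale) SD
#' `noise_sd`. Each line's `area_ratio` exceeds 1.5 with probability
#' `area_gt_frac` and is missing with probability `area_missing_frac`.
#'
#' @param genes data.frame with `gene_id` and logical `candidate`.
#' @param effect Mean relative-fitness decrement for candidate genes.
#' @param noise_sd Gene-level lognormal noise SD (> 0).
#' @param n_replicates Observations per line.
#' @param n_chambers Number of growth chambers, assigned cyclically.
#' @param seed Optional integer seed.
#' @param wt_mean Baseline wild-type fruit count.
#' @param area_gt_frac,area_missing_frac Fractions of lines with
#'   `area_ratio > 1.5` and with missing `area_ratio`.
#' @return A `fitness_table` data.frame (see [read_fitness_table()]).
#' @export
simulate_fitness_table <- function(genes, effect = 0, noise_sd = 0.2,
                                   n_replicates = 5, n_chambers = 2,
                                   seed = NULL, wt_mean = 60,
                                   area_gt_frac = 0.05,
                                   area_missing_frac = 0.1) {
  stopifnot(noise_sd > 0, n_replicates >= 1, n_chambers >= 1)
  if (!is.null(seed)) set.seed(seed)
  chamber_mean <- wt_mean * exp(stats::rnorm(n_chambers, 0, 0.15))
  rows <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    eff <- if (isTRUE(genes$candidate[g])) -effect else 0
    mult <- exp(stats::rnorm(1, -noise_sd^2 / 2, noise_sd))
    u <- stats::runif(1)
    area <- if (u < area_missing_frac) NA_real_
      else if (u < area_missing_frac + area_gt_frac) stats::runif(1, 1.55, 2.5)
      else stats::runif(1, 0.8, 1.3)
    ch <- ((seq_len(n_replicates) - 1) %% n_chambers) + 1
    wt <- stats::rpois(n_replicates, chamber_mean[ch])
    ko <- stats::rpois(n_replicates, chamber_mean[ch] * (1 + eff) * mult)
    rows[[g]] <- data.frame(
      line_id = paste0("line_", genes$gene_id[g]),
      gene_id = genes$gene_id[g],
      replicate_id = paste0("rep", seq_len(n_replicates)),
      chamber_id = paste0("chamber", ch),
      ko_fruit_count = ko, wt_fruit_count = wt,
      area_ratio = area, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fitness_table", "data.frame")
  out
}

#' Simulation configuration with the study-scale defaults
#'
#' @param seed Mandatory integer seed.
#' @param n_genes Number of genes.
#' @param n_haplotypes Ingroup haplotypes per gene.
#' @param theta Per-locus population mutation rate.
#' @param L CDS length in codons.
#' @param omega_meanlog,omega_sdlog Lognormal parameters of the per-gene
#'   true omega distribution (median `exp(omega_meanlog)`).
#' @param branch_length Ortholog divergence (expected substitutions/site).
#' @param outgroup_divergence Outgroup divergence for the haplotype
#'   alignments.
#' @param sfs_mode,sfs_intensity Spectrum skew applied to every gene.
#' @param fitness_effect Mean relative-fitness decrement for candidate
#'   (essential) genes; 0 is the null model.
#' @param noise_sd,n_replicates,n_chambers Fitness-table parameters.
#' @param essential_fraction Fraction of genes labelled essential.
#' @param essential_shift Amount subtracted from essential genes' true
#'   omega (floored at 0.01).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_genes = 50, n_haplotypes = 20, theta = 20,
                       L = 200, omega_meanlog = log(0.25),
                       omega_sdlog = 0.5, branch_length = 0.1,
                       outgroup_divergence = 0.1,
                       sfs_mode = "neutral", sfs_intensity = 0,
                       fitness_effect = 0, noise_sd = 0.2,
                       n_replicates = 5, n_chambers = 2,
                       essential_fraction = 0.1, essential_shift = 0.1) {
  stopifnot(!missing(seed), is.numeric(seed), theta > 0, L >= 50,
            n_haplotypes >= 4)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes, under `outdir`: `haplotypes/<gene>.fa` (ingroup haplotypes plus
#' outgroup), `orthologs/<gene>.fa` (the gene and its simulated ortholog),
#' `gene_models.tsv` (single-transcript exon TSV), `fitness.tsv`,
#' `essential_genes.tsv`, and `manifest.tsv` recording every true
#' parameter. Essential genes' ortholog pairs are simulated with
#' `omega_true` reduced by `essential_shift`, and fitness candidate labels
#' equal the essential labels.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, the manifest data.frame.
#' @export
generate_full_dataset <- function(config, outdir, overwrite = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(outdir) && !overwrite) {
    stop("output directory exists (use overwrite = TRUE): ", outdir)
  }
  dir.create(file.path(outdir, "haplotypes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "orthologs"), showWarnings = FALSE)
  set.seed(config$seed)

  ng <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  essential <- rep(FALSE, ng)
  essential[sample.int(ng, round(config$essential_fraction * ng))] <- TRUE
  omega_true <- stats::rlnorm(ng, config$omega_meanlog, config$omega_sdlog)
  omega_true[essential] <- pmax(omega_true[essential] -
                                  config$essential_shift, 0.01)
  L_sites <- config$L * 3

  for (g in seq_len(ng)) {
    aln <- simulate_coalescent_gene(
      config$n_haplotypes, config$theta, L_sites,
      outgroup_divergence = config$outgroup_divergence,
      gene_id = gene_ids[g])
    if (config$sfs_mode != "neutral" && config$sfs_intensity > 0) {
      aln <- skew_spectrum(aln, config$sfs_mode, config$sfs_intensity)
    }
    seqs <- apply(aln$haplotypes, 1, paste, collapse = "")
    seqs <- c(seqs, outgroup = paste(aln$outgroup, collapse = ""))
    write_fasta(seqs, file.path(outdir, "haplotypes",
                                paste0(gene_ids[g], ".fa")))
    pair <- simulate_ortholog_pair(config$L, omega_true[g],
                                   config$branch_length,
                                   gene_id = gene_ids[g])
    write_fasta(stats::setNames(c(pair$cds_a, pair$cds_b),
                                c(gene_ids[g],
                                  paste0(gene_ids[g], "_ortholog"))),
                file.path(outdir, "orthologs", paste0(gene_ids[g], ".fa")))
  }

  models <- data.frame(gene_id = gene_ids,
                       transcript_id = paste0(gene_ids, ".1"),
                       chrom = gene_ids, strand = "+",
                       start = 1L, end = L_sites,
                       stringsAsFactors = FALSE)
  utils::write.table(models, file.path(outdir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- data.frame(gene_id = gene_ids, candidate = essential,
                      stringsAsFactors = FALSE)
  fitness <- simulate_fitness_table(
    genes, effect = config$fitness_effect, noise_sd = config$noise_sd,
    n_replicates = config$n_replicates, n_chambers = config$n_chambers)
  utils::write.table(fitness, file.path(outdir, "fitness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = gene_ids[essential]),
                     file.path(outdir, "essential_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- data.frame(
    gene_id = gene_ids, theta = config$theta, n = config$n_haplotypes,
    L_codons = config$L, omega_true = omega_true, essential = essential,
    fitness_effect = ifelse(essential, -config$fitness_effect, 0),
    sfs_mode = config$sfs_mode, sfs_intensity = config$sfs_intensity,
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
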