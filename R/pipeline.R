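# End-to-end orchestration: ortholog alignment and divergence, MK tables,
# SFS profiles, selection classification, the essential-gene randomisation
# test, and fitness association, with the filters at their conventional
# settings, a single top-level seed, and line-oriented logging.

#' Pipeline configuration with the conventional filter settings
#'
#' Defaults: reciprocal identity >= 75%, `0.02 < dS < 2`, `dN < 2`,
#' segregating-site validity >= 50, at least 4 fitness observations per
#' gene, area-ratio cutoff 1.5, classification thresholds `omega > 1`,
#' `DOS > 0`, `NI < 0`, `D < 0`, `D* < 0`, `H < 0`, `E < 0`, and
#' `s = 10000` randomisation draws.
#'
#' @param seed Mandatory integer seed for every stochastic stage.
#' @param mode Classification mode, `"threshold"` or `"outlier5pct"`.
#' @param s Randomisation draws.
#' @param min_identity,ds_bounds,dn_max Ortholog filters.
#' @param min_seg_sites SFS validity threshold.
#' @param min_obs Fitness observation filter.
#' @param max_area_ratio Area-ratio cutoff.
#' @param h_variant Fay & Wu's H variant, `"unnormalized"` (default) or
#'   `"normalized"`.
#' @param apply_area_filter Drop genes with area ratio above the cutoff
#'   before the fitness tests.
#' @param accession_subset Optional character vector of haplotype row names
#'   to restrict the SFS stage to (geographic-subset control).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, mode = "threshold", s = 10000,
                            min_identity = 75, ds_bounds = c(0.02, 2),
                            dn_max = 2, min_seg_sites = 50, min_obs = 4,
                            max_area_ratio = 1.5,
                            h_variant = "unnormalized",
                            apply_area_filter = FALSE,
                            accession_subset = NULL) {
  stopifnot(!missing(seed), is.numeric(seed))
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  writeLines(line, con)
  invisible(line)
}

#' Run the full analysis on a dataset directory
#'
#' Expects the layout written by [generate_full_dataset()]:
#' `orthologs/*.fa` (one pairwise FASTA per gene), `haplotypes/*.fa`
#' (ingroup haplotypes plus an `outgroup` row), `fitness.tsv`, and
#' optionally `essential_genes.tsv`. Stage order: ortholog alignment and
#' divergence with retention filters; MK tables (polymorphisms classified
#' from the haplotype alignments, substitutions from the divergence
#' estimates); SFS profiles with the segregating-site validity rule;
#' selection classification and method intersection; estimator
#' cross-correlation; the essential-gene randomisation test (when the list
#' is present); fitness aggregation and association tests. All tables are
#' written as TSV under `outdir`, with a line-oriented `run.log` and the
#' resolved configuration as YAML.
#'
#' @param dataset_dir Input directory.
#' @param outdir Output directory (created; must not exist unless
#'   `overwrite`).
#' @param config A `pipeline_config`.
#' @param overwrite Allow writing into an existing output directory.
#' @return Invisibly, a list with the per-stage results (`divergence`,
#'   `mk`, `profiles`, `stats`, `calls`, `intersection`, `correlations`,
#'   `randomisation`, `fitness`, `class_tests`, `fitness_correlations`).
#' @export
run_all <- function(dataset_dir, outdir, config, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(outdir) && !overwrite) {
    stop("output directory exists (use overwrite = TRUE): ", outdir)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  set.seed(config$seed)
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))

  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## 1. ortholog divergence -------------------------------------------------
  ortho_files <- sort(list.files(file.path(dataset_dir, "orthologs"),
                                 pattern = "\\.fa(sta)?$",
                                 full.names = TRUE))
  if (length(ortho_files) == 0) stop("no ortholog FASTAs in ", dataset_dir)
  div_rows <- vector("list", length(ortho_files))
  for (i in seq_along(ortho_files)) {
    seqs <- read_fasta(ortho_files[i])
    if (length(seqs) != 2) stop("ortholog file must have 2 records: ",
                                ortho_files[i])
    aln <- global_align(seqs[[1]], seqs[[2]])
    est <- ng86_dnds(aln, gene_id = names(seqs)[1])
    div_rows[[i]] <- cbind(divergence_table(list(est)),
                           reciprocal_identity = reciprocal_identity(aln),
                           Nd_frac = est$Nd, Sd_frac = est$Sd)
  }
  divergence <- do.call(rbind, div_rows)
  pipeline_log(con, "divergence",
               sprintf("%d ortholog pairs aligned", nrow(divergence)))
  retained <- filter_orthologs(divergence, config$min_identity,
                               config$ds_bounds, config$dn_max)
  pipeline_log(con, "divergence", sprintf(
    "%d pairs retained by identity/dS/dN filters (%d dropped)",
    nrow(retained), nrow(divergence) - nrow(retained)))
  write_tsv(divergence, "divergence.tsv")

  ## 2 + 3. haplotype alignments: MK tables and SFS profiles ---------------
  hap_files <- sort(list.files(file.path(dataset_dir, "haplotypes"),
                               pattern = "\\.fa(sta)?$", full.names = TRUE))
  mk_list <- list()
  prof_rows <- vector("list", length(hap_files))
  div_by_gene <- split(divergence, divergence$gene_id)
  for (i in seq_along(hap_files)) {
    aln <- read_haplotype_fasta(hap_files[i])
    if (!is.null(config$accession_subset)) {
      keep <- rownames(aln$haplotypes) %in% config$accession_subset
      if (sum(keep) < 2) {
        stop("accession subset leaves fewer than 2 haplotypes for ",
             aln$gene_id)
      }
      aln$haplotypes <- aln$haplotypes[keep, , drop = FALSE]
    }
    gid <- aln$gene_id
    dv <- div_by_gene[[gid]]
    if (!is.null(dv)) {
      classes <- classify_polymorphic_sites(aln)
      mk_list[[gid]] <- count_mk_table(
        gid, classes, list(Nd = dv$Nd_frac[1], Sd = dv$Sd_frac[1]))
    }
    prof_rows[[i]] <- profile_gene(aln, config$min_seg_sites,
                                   config$h_variant)
  }
  profiles <- do.call(rbind, prof_rows)
  mk <- mk_table_summary(mk_list)
  pipeline_log(con, "mk", sprintf("MK tables for %d genes", nrow(mk)))
  pipeline_log(con, "sfs", sprintf(
    "%d gene profiles, %d valid (>= %d segregating sites)",
    nrow(profiles), sum(profiles$valid), config$min_seg_sites))
  write_tsv(mk, "mk.tsv")
  write_tsv(profiles, "profiles.tsv")

  ## 4. merged statistic table and classification ---------------------------
  stats_tab <- merge(
    retained[, c("gene_id", "omega")],
    merge(mk[, c("gene_id", "NI", "DOS")],
          profiles[, c("gene_id", "D", "D_star", "H", "E")],
          by = "gene_id", all = TRUE),
    by = "gene_id", all = TRUE)
  calls <- classify_selection(stats_tab, mode = config$mode)
  n_flagged <- vapply(SELECTION_STATS, function(s)
    sum(calls[[s]], na.rm = TRUE), 0L)
  pipeline_log(con, "classify", paste(
    sprintf("%s: %d candidates", names(n_flagged), n_flagged),
    collapse = "; "))
  intersection <- intersect_methods(calls)
  pipeline_log(con, "classify", sprintf(
    "%d genes flagged by all seven methods", length(intersection)))
  write_tsv(stats_tab, "statistics.tsv")
  write_tsv(calls, "calls.tsv")
  writeLines(intersection, file.path(outdir, "intersection.txt"))
  correlations <- estimator_correlations(stats_tab)
  write_tsv(cbind(statistic = rownames(correlations$rho),
                  as.data.frame(correlations$rho)),
            "correlations.tsv")

  ## 5. essential-gene randomisation ----------------------------------------
  rand_results <- NULL
  ess_path <- file.path(dataset_dir, "essential_genes.tsv")
  if (file.exists(ess_path)) {
    essential <- utils::read.delim(ess_path,
                                   stringsAsFactors = FALSE)$gene_id
    dirs <- essential_test_directions()
    rand_list <- lapply(SELECTION_STATS, function(sname) {
      vals <- stats::setNames(stats_tab[[sname]], stats_tab$gene_id)
      if (all(is.na(vals)) ||
          length(intersect(essential, names(vals)[!is.na(vals)])) == 0) {
        return(NULL)
      }
      res <- randomisation_test(vals, essential,
                                direction = dirs[[sname]], s = config$s,
                                statistic_name = sname)
      data.frame(statistic = sname, direction = res$direction,
                 observed_median = res$observed_median,
                 n_focal = res$n_focal, n_pool = res$n_pool,
                 s = res$s, q = res$q, r = res$r, p = res$p,
                 stringsAsFactors = FALSE)
    })
    rand_results <- do.call(rbind, rand_list)
    if (!is.null(rand_results)) {
      pipeline_log(con, "randomise", sprintf(
        "%d essential genes tested against %d statistics",
        length(essential), nrow(rand_results)))
      write_tsv(rand_results, "randomisation.tsv")
    }
  } else {
    pipeline_log(con, "randomise", "no essential gene list; stage skipped")
  }

  ## 6. fitness association --------------------------------------------------
  fit_results <- NULL
  class_tests <- NULL
  fit_cors <- NULL
  fit_path <- file.path(dataset_dir, "fitness.tsv")
  if (file.exists(fit_path)) {
    ftab <- read_fitness_table(fit_path)
    gene_fit <- aggregate_gene_fitness(ftab, config$min_obs)
    pipeline_log(con, "fitness", sprintf(
      "%d genes with >= %d observations (%d replicate ratios dropped for WT = 0)",
      nrow(gene_fit), config$min_obs,
      attr(gene_fit, "n_dropped_wt_zero")))
    if (config$apply_area_filter) {
      before <- nrow(gene_fit)
      gene_fit <- area_ratio_filter(gene_fit, config$max_area_ratio)
      pipeline_log(con, "fitness", sprintf(
        "area-ratio filter (> %.2f): %d genes dropped",
        config$max_area_ratio, before - nrow(gene_fit)))
    }
    ct_list <- lapply(SELECTION_STATS, function(sname) {
      res <- tryCatch(
        suppressWarnings(compare_fitness_by_class(gene_fit, calls, sname)),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(statistic = sname, n_candidate = res$n_candidate,
                 n_other = res$n_other,
                 median_candidate = res$median_candidate,
                 median_other = res$median_other,
                 H = res$H, p = res$p, stringsAsFactors = FALSE)
    })
    class_tests <- do.call(rbind, ct_list)
    fit_cors <- correlate_fitness_with_stats(gene_fit, stats_tab)
    fit_results <- gene_fit
    write_tsv(gene_fit, "gene_fitness.tsv")
    if (!is.null(class_tests)) write_tsv(class_tests, "fitness_by_class.tsv")
    write_tsv(fit_cors, "fitness_correlations.tsv")
  } else {
    pipeline_log(con, "fitness", "no fitness table; stage skipped")
  }

  pipeline_log(con, "done", "pipeline complete")
  invisible(list(divergence = divergence, retained = retained, mk = mk,
                 profiles = profiles, stats = stats_tab, calls = calls,
                 intersection = intersection, correlations = correlations,
                 randomisation = rand_results, fitness = fit_results,
                 class_tests = class_tests,
                 fitness_correlations = fit_cors))
}
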