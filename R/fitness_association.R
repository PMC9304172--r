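# Per-gene relative fitness from knockout line replicates, the observation
# and area-ratio filters, chamber Z-scores, and the association tests
# between fitness and the selection signatures.

#' Relative fitness of one knockout observation
#'
#' Knockout fruit count divided by the wild-type fruit count of the same
#' experimental replicate. Undefined when the wild-type count is 0 (the
#' data point is dropped upstream).
#'
#' @param ko_fruits,wt_fruits Non-negative fruit counts.
#' @return `ko_fruits / wt_fruits`, or `NA` when `wt_fruits == 0`.
#' @export
relative_fitness <- function(ko_fruits, wt_fruits) {
  ifelse(wt_fruits > 0, ko_fruits / wt_fruits, NA_real_)
}

#' Aggregate replicate-level relative fitness per gene
#'
#' Computes the replicate ratios, drops undefined ones (wild type 0), and
#' averages per gene. Genes with fewer than `min_obs` defined observations
#' are excluded ("more than three observations" means at least 4).
#'
#' @param table A `fitness_table` data.frame.
#' @param min_obs Minimum defined observations per gene, default 4.
#' @return data.frame with `gene_id`, `w` (mean relative fitness), `n_obs`,
#'   `area_ratio` (the gene's maximum reported line area ratio, `NA` when
#'   never reported) and `area_ratio_ok` (`NA` when unreported).
#' @export
aggregate_gene_fitness <- function(table, min_obs = 4) {
  table$w_rep <- relative_fitness(table$ko_fruit_count, table$wt_fruit_count)
  n_dropped <- sum(is.na(table$w_rep))
  ok <- table[!is.na(table$w_rep), , drop = FALSE]
  split_rows <- split(ok, ok$gene_id)
  out <- do.call(rbind, lapply(split_rows, function(rows) {
    ar <- rows$area_ratio[!is.na(rows$area_ratio)]
    area <- if (length(ar) > 0) max(ar) else NA_real_
    data.frame(gene_id = rows$gene_id[1],
               w = mean(rows$w_rep), n_obs = nrow(rows),
               area_ratio = area,
               area_ratio_ok = if (is.na(area)) NA else area <= 1.5,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_obs >= min_obs, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_wt_zero") <- n_dropped
  out
}

#' Drop genes whose knockout line has a large area ratio
#'
#' Lines with an area ratio above `max_ratio` likely carry multiple T-DNA
#' insertions (off-target effects) and are removed; genes with a missing
#' area ratio are retained (their `area_ratio_ok` flag stays `NA`).
#'
#' @param genes data.frame from [aggregate_gene_fitness()].
#' @param max_ratio Strict upper bound, default 1.5 (exactly 1.5 is kept).
#' @return Filtered data.frame.
#' @export
area_ratio_filter <- function(genes, max_ratio = 1.5) {
  drop <- !is.na(genes$area_ratio) & genes$area_ratio > max_ratio
  genes[!drop, , drop = FALSE]
}

#' Chamber-standardised fitness Z-scores
#'
#' Standardises replicate-level relative fitness within each growth chamber
#' (population SD, i.e. the n-denominator) before gene-level averaging, to
#' remove chamber-specific phenotypic offsets. Chambers with zero variance
#' yield `NA` z-scores for their rows.
#'
#' @param table A `fitness_table` data.frame.
#' @param min_obs Minimum defined observations per gene, default 4.
#' @return data.frame with `gene_id`, `z` (mean chamber-standardised
#'   fitness) and `n_obs`.
#' @export
zscore_by_chamber <- function(table, min_obs = 4) {
  table$w_rep <- relative_fitness(table$ko_fruit_count, table$wt_fruit_count)
  ok <- table[!is.na(table$w_rep), , drop = FALSE]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  z <- stats::ave(ok$w_rep, ok$chamber_id, FUN = function(x) {
    s <- pop_sd(x)
    if (s == 0) rep(NA_real_, length(x)) else (x - mean(x)) / s
  })
  ok$z <- z
  ok <- ok[!is.na(ok$z), , drop = FALSE]
  if (nrow(ok) == 0) {
    return(data.frame(gene_id = character(0), z = numeric(0),
                      n_obs = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(ok, ok$gene_id), function(rows) {
    data.frame(gene_id = rows$gene_id[1], z = mean(rows$z),
               n_obs = nrow(rows), stringsAsFactors = FALSE)
  }))
  out <- out[out$n_obs >= min_obs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare fitness between selection candidates and non-candidates
#'
#' Two-group Kruskal-Wallis rank test of mean relative fitness between
#' genes flagged as selection candidates by one statistic and the rest.
#'
#' @param genes data.frame with `gene_id` and `w` (e.g. from
#'   [aggregate_gene_fitness()]).
#' @param calls data.frame from [classify_selection()].
#' @param statistic Which statistic's flag to use (column of `calls`).
#' @return List with `statistic`, `n_candidate`, `n_other`,
#'   `median_candidate`, `median_other`, `H` (KW chi-squared statistic) and
#'   `p`; `NULL` (with a warning) when either class is empty.
#' @export
compare_fitness_by_class <- function(genes, calls, statistic) {
  stopifnot(statistic %in% names(calls))
  merged <- merge(genes, calls[, c("gene_id", statistic)], by = "gene_id")
  flag <- merged[[statistic]]
  merged <- merged[!is.na(flag), , drop = FALSE]
  flag <- flag[!is.na(flag)]
  if (sum(flag) == 0 || sum(!flag) == 0) {
    warning("empty class for ", statistic, "; test skipped")
    return(NULL)
  }
  kw <- stats::kruskal.test(merged$w, factor(flag))
  list(statistic = statistic,
       n_candidate = sum(flag), n_other = sum(!flag),
       median_candidate = stats::median(merged$w[flag]),
       median_other = stats::median(merged$w[!flag]),
       H = unname(kw$statistic), p = kw$p.value)
}

#' Spearman correlation of fitness with each selection statistic
#'
#' Complete-case Spearman rank correlation of mean relative fitness against
#' each statistic, with raw and Benjamini-Hochberg adjusted p-values.
#'
#' @param genes data.frame with `gene_id` and `w`.
#' @param profiles data.frame with `gene_id` and statistic columns.
#' @return data.frame with `statistic`, `n`, `rho`, `p`, `p_adj`; `rho` is
#'   `NA` (flagged by `n`) when fewer than 3 complete pairs exist or a
#'   vector is constant.
#' @export
correlate_fitness_with_stats <- function(genes, profiles) {
  merged <- merge(genes, profiles, by = "gene_id")
  stats_present <- intersect(SELECTION_STATS, names(profiles))
  rows <- lapply(stats_present, function(s) {
    x <- merged$w
    y <- merged[[s]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
        length(unique(y[ok])) < 2) {
      return(data.frame(statistic = s, n = sum(ok), rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman"))
    data.frame(statistic = s, n = sum(ok), rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
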