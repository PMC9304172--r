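# Selection-candidate classification per statistic, method intersection,
# estimator cross-correlation, and the essential-gene randomisation test.

# the seven statistics and the direction in which each indicates selection
SELECTION_STATS <- c("omega", "DOS", "NI", "D", "D_star", "H", "E")

selection_directions <- function() {
  c(omega = "high", DOS = "high", NI = "low", D = "low",
    D_star = "low", H = "low", E = "low")
}

# randomisation-test tails for the essential-gene analysis: essential genes
# are expected to have LOWER dN/dS, DOS and H, and HIGHER NI, D, D* and E
essential_test_directions <- function() {
  c(omega = "lower", DOS = "lower", H = "lower",
    NI = "higher", D = "higher", D_star = "higher", E = "higher")
}

default_thresholds <- function() {
  c(omega = 1, DOS = 0, NI = 0, D = 0, D_star = 0, H = 0, E = 0)
}

#' Classify genes as selection candidates per statistic
#'
#' Threshold mode applies the conventional strict inequalities
#' (`omega > 1`, `DOS > 0`, `NI < 0`, `D < 0`, `D* < 0`, `H < 0`, `E < 0`).
#' Outlier mode flags the top 5% of each statistic's distribution in its
#' selection-indicating direction (empirical quantile with linear
#' interpolation; ties at the cutoff are included). Genes with an undefined
#' statistic get `NA` for that flag.
#'
#' @param profiles data.frame with `gene_id` and any of the statistic
#'   columns `omega`, `DOS`, `NI`, `D`, `D_star`, `H`, `E`.
#' @param mode `"threshold"` or `"outlier5pct"`.
#' @param thresholds Named numeric vector overriding the conventional
#'   thresholds (threshold mode only).
#' @param outlier_frac Tail fraction for outlier mode, default 0.05.
#' @return data.frame with `gene_id` and one logical column per statistic
#'   present, plus attribute `mode`.
#' @export
classify_selection <- function(profiles,
                               mode = c("threshold", "outlier5pct"),
                               thresholds = default_thresholds(),
                               outlier_frac = 0.05) {
  mode <- match.arg(mode)
  dirs <- selection_directions()
  stats_present <- intersect(SELECTION_STATS, names(profiles))
  out <- data.frame(gene_id = profiles$gene_id, stringsAsFactors = FALSE)
  for (s in stats_present) {
    x <- profiles[[s]]
    if (mode == "threshold") {
      thr <- thresholds[[s]]
      flag <- if (dirs[[s]] == "high") x > thr else x < thr
    } else {
      if (dirs[[s]] == "high") {
        cut <- stats::quantile(x, 1 - outlier_frac, na.rm = TRUE,
                               names = FALSE)
        flag <- x >= cut
      } else {
        cut <- stats::quantile(x, outlier_frac, na.rm = TRUE, names = FALSE)
        flag <- x <= cut
      }
    }
    out[[s]] <- flag
  }
  attr(out, "mode") <- mode
  out
}

#' Genes flagged as selection candidates by every method
#'
#' @param calls A data.frame from [classify_selection()]; all seven
#'   statistic columns must be present.
#' @return Character vector of gene ids flagged by all seven methods; genes
#'   with any undefined statistic are excluded.
#' @export
intersect_methods <- function(calls) {
  missing_cols <- setdiff(SELECTION_STATS, names(calls))
  if (length(missing_cols) > 0) {
    stop("calls lack statistics: ", paste(missing_cols, collapse = ", "))
  }
  flags <- as.matrix(calls[, SELECTION_STATS])
  all7 <- rowSums(flags, na.rm = FALSE) == length(SELECTION_STATS)
  calls$gene_id[!is.na(all7) & all7]
}

#' Pairwise Spearman correlations between estimators
#'
#' Complete-case Spearman rank correlation for each pair of statistic
#' columns; entries with fewer than 3 complete pairs are `NA`. The
#' coefficient matrix is symmetric with unit diagonal.
#'
#' @param profiles data.frame with `gene_id` and statistic columns.
#' @param stats Which columns to correlate (defaults to the seven
#'   statistics present).
#' @return List with matrices `rho` and `p`.
#' @export
estimator_correlations <- function(profiles,
                                   stats = intersect(SELECTION_STATS,
                                                     names(profiles))) {
  k <- length(stats)
  rho <- matrix(NA_real_, k, k, dimnames = list(stats, stats))
  pmat <- rho
  diag(rho) <- 1
  diag(pmat) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      x <- profiles[[stats[i]]]
      y <- profiles[[stats[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = pmat)
}

#' Randomisation test of a focal gene set against the genome background
#'
#' Draws `s` random gene subsets of the focal size (without replacement,
#' from all genes with a defined value) and compares subset medians with
#' the focal median. For `direction = "lower"` (the focal set is
#' hypothesised to have a lower median), `q` counts random subsets whose
#' median is strictly greater than the focal median; with `r = s - q`
#' (random subsets at or below the focal median, ties counted
#' conservatively), the p-value is `(r + 1) / (s + 1)`, bounded below by
#' `1 / (s + 1)`. `direction = "higher"` mirrors this.
#'
#' @param values Named numeric vector of per-gene statistic values (`NA`s
#'   allowed; genes with `NA` are excluded from both pool and focal set).
#' @param focal_genes Character vector of focal gene ids.
#' @param direction `"lower"` or `"higher"`.
#' @param s Number of random draws, default 10000.
#' @param seed Optional integer seed.
#' @param statistic_name Label carried into the result.
#' @return A `randomisation_result`: list with `statistic_name`,
#'   `direction`, `observed_median`, `n_focal`, `n_pool`, `s`, `q`, `r`,
#'   `p`.
#' @export
randomisation_test <- function(values, focal_genes,
                               direction = c("lower", "higher"),
                               s = 10000, seed = NULL,
                               statistic_name = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(s >= 1, !is.null(names(values)))
  if (!is.null(seed)) set.seed(seed)
  defined <- values[!is.na(values)]
  focal <- intersect(focal_genes, names(defined))
  if (length(focal) == 0) {
    stop("no focal genes with defined values")
  }
  m <- length(focal)
  obs <- stats::median(defined[focal])
  pool <- unname(defined)
  draw_medians <- vapply(seq_len(s), function(b) {
    stats::median(pool[sample.int(length(pool), m)])
  }, numeric(1))
  q <- if (direction == "lower") sum(draw_medians > obs) else
    sum(draw_medians < obs)
  r <- s - q
  structure(list(statistic_name = statistic_name, direction = direction,
                 observed_median = obs, n_focal = m,
                 n_pool = length(pool), s = s, q = q, r = r,
                 p = (r + 1) / (s + 1)),
            class = "randomisation_result")
}

#' @export
print.randomisation_result <- function(x, ...) {
  cat(sprintf(
    "Randomisation test%s: focal median %.4g (%d genes of %d), %s tail, s = %d, p = %.3g\n",
    if (is.na(x$statistic_name)) "" else paste0(" [", x$statistic_name, "]"),
    x$observed_median, x$n_focal, x$n_pool, x$direction, x$s, x$p))
  invisible(x)
}
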