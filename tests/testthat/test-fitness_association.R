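make_fitness_rows <- function(gene_id, ko, wt, chamber = "ch1",
                              area = NA_real_) {
  data.frame(line_id = paste0("line_", gene_id), gene_id = gene_id,
             replicate_id = paste0("rep", seq_along(ko)),
             chamber_id = chamber, ko_fruit_count = ko,
             wt_fruit_count = wt, area_ratio = area,
             stringsAsFactors = FALSE)
}

test_that("relative fitness is the within-replicate ratio", {
  expect_equal(relative_fitness(30, 40), 0.75)
  expect_equal(relative_fitness(25, 25), 1)
  expect_true(is.na(relative_fitness(10, 0)))
})

test_that("gene fitness averages replicates above the observation filter", {
  tab <- rbind(
    make_fitness_rows("g1", ko = c(8, 10, 12, 10), wt = c(10, 10, 10, 10)),
    make_fitness_rows("g2", ko = c(10, 10, 10), wt = c(10, 10, 10)),
    make_fitness_rows("g3", ko = c(10, 10, 10, 10, 10),
                      wt = c(10, 10, 10, 10, 0)))
  out <- aggregate_gene_fitness(tab)
  # mean of 4 ratios
  expect_equal(out$w[out$gene_id == "g1"], 1)
  # exactly 3 observations: excluded ("more than three" means >= 4)
  expect_false("g2" %in% out$gene_id)
  # WT = 0 replicate dropped; mean over the 4 defined ratios
  expect_equal(out$n_obs[out$gene_id == "g3"], 4)
  expect_equal(out$w[out$gene_id == "g3"], 1)
  expect_equal(attr(out, "n_dropped_wt_zero"), 1L)

  # permutation invariance over row order
  set.seed(61)
  shuffled <- tab[sample(nrow(tab)), ]
  out2 <- aggregate_gene_fitness(shuffled)
  expect_equal(out[order(out$gene_id), ], out2[order(out2$gene_id), ])
})

test_that("area-ratio filter drops strictly above 1.5, keeps missing", {
  genes <- data.frame(gene_id = c("hi", "edge", "none"),
                      w = 1, n_obs = 4,
                      area_ratio = c(1.6, 1.5, NA),
                      area_ratio_ok = c(FALSE, TRUE, NA))
  out <- area_ratio_filter(genes)
  expect_setequal(out$gene_id, c("edge", "none"))
})

test_that("chamber z-scores standardise with the population SD", {
  tab <- rbind(
    make_fitness_rows("g1", ko = c(10, 20, 30), wt = c(10, 10, 10)),
    make_fitness_rows("g2", ko = c(10, 20, 30), wt = c(10, 10, 10)))
  out <- zscore_by_chamber(tab, min_obs = 3)
  # ratios {1,2,3} within one chamber -> z = {-1.2247, 0, 1.2247};
  # both genes contribute the same values so each gene's mean z is 0
  expect_equal(out$z, c(0, 0), tolerance = 1e-6)

  # constant chamber -> undefined z, rows dropped
  flat <- make_fitness_rows("g3", ko = c(10, 10, 10, 10),
                            wt = c(10, 10, 10, 10), chamber = "ch2")
  expect_equal(nrow(zscore_by_chamber(flat, min_obs = 1)), 0)

  # two chambers with different offsets: z removes the chamber mean
  two <- rbind(
    make_fitness_rows("g4", ko = c(10, 20, 30), wt = c(10, 10, 10),
                      chamber = "chA"),
    make_fitness_rows("g5", ko = c(30, 40, 50), wt = c(10, 10, 10),
                      chamber = "chB"))
  outz <- zscore_by_chamber(two, min_obs = 3)
  expect_equal(mean(outz$z), 0, tolerance = 1e-12)
})

test_that("class comparison uses a two-group Kruskal-Wallis test", {
  genes <- data.frame(gene_id = paste0("g", 1:8),
                      w = rep(c(0.8, 1.0, 1.2, 1.0), 2))
  calls <- data.frame(gene_id = paste0("g", 1:8),
                      D = rep(c(TRUE, FALSE), each = 4))
  res <- compare_fitness_by_class(genes, calls, "D")
  # identical value sets in the two groups: H = 0, p close to 1
  expect_equal(res$H, 0, tolerance = 1e-12)
  expect_gt(res$p, 0.99)
  expect_equal(res$n_candidate, 4)

  empty <- data.frame(gene_id = paste0("g", 1:8), D = FALSE)
  expect_warning(out <- compare_fitness_by_class(genes, empty, "D"),
                 "empty class")
  expect_null(out)
})

test_that("shifted fitness classes are detected with good power", {
  set.seed(62)
  rejections <- 0
  for (rep in 1:50) {
    w <- c(rnorm(75, 0.8, 0.2), rnorm(304, 1.0, 0.2))
    genes <- data.frame(gene_id = paste0("g", 1:379), w = w)
    calls <- data.frame(gene_id = paste0("g", 1:379),
                        D = rep(c(TRUE, FALSE), c(75, 304)))
    if (compare_fitness_by_class(genes, calls, "D")$p < 0.05) {
      rejections <- rejections + 1
    }
  }
  expect_gte(rejections, 45)
})

test_that("fitness correlations report rho with BH adjustment", {
  genes <- data.frame(gene_id = paste0("g", 1:20), w = 1:20)
  profiles <- data.frame(gene_id = paste0("g", 1:20),
                         D = 1:20, H = 21:40, E = rep(1, 20))
  out <- correlate_fitness_with_stats(genes, profiles)
  expect_equal(out$rho[out$statistic == "D"], 1)
  expect_equal(out$rho[out$statistic == "H"], 1)
  # constant statistic -> undefined, flagged by NA
  expect_true(is.na(out$rho[out$statistic == "E"]))
  expect_true(all(out$p_adj >= out$p, na.rm = TRUE))
})
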