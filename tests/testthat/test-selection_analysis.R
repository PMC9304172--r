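test_that("threshold classification applies the strict inequalities", {
  profiles <- data.frame(
    gene_id = c("a", "b", "c"),
    omega = c(1.2, 1.0, NA),
    DOS = c(0.1, 0, -0.2),
    NI = c(-0.5, 0, 0.5),
    D = c(-1, 0, 1),
    D_star = c(-1, 0, 1),
    H = c(-1, 0, 1),
    E = c(-1, 0, 1))
  calls <- classify_selection(profiles, mode = "threshold")
  expect_true(calls$omega[1])
  expect_false(calls$omega[2])   # exactly 1 is not > 1
  expect_true(is.na(calls$omega[3]))
  expect_false(calls$H[2])       # exactly 0 is not < 0
  expect_true(calls$H[1])
  expect_false(calls$H[3])
})

test_that("outlier classification flags the 5% tail in each direction", {
  set.seed(51)
  x <- rnorm(200)
  profiles <- data.frame(gene_id = paste0("g", 1:200), DOS = x, D = x)
  calls <- classify_selection(profiles, mode = "outlier5pct")
  # DOS flags its top tail, D its bottom tail
  expect_true(all(x[calls$DOS] >= quantile(x, 0.95, names = FALSE)))
  expect_true(all(x[calls$D] <= quantile(x, 0.05, names = FALSE)))
  # a gene at the 96th percentile of DOS is flagged
  idx <- which(rank(x) == 192)
  expect_true(calls$DOS[idx])
})

test_that("method intersection requires all seven defined and flagged", {
  calls <- data.frame(gene_id = c("all7", "six", "invalidH"),
                      omega = TRUE, DOS = TRUE, NI = TRUE, D = TRUE,
                      D_star = TRUE, H = c(TRUE, FALSE, NA), E = TRUE)
  expect_equal(intersect_methods(calls), "all7")
  expect_error(intersect_methods(calls[, -2]), "lack")
})

test_that("estimator correlations are symmetric with unit diagonal", {
  df <- data.frame(gene_id = paste0("g", 1:30),
                   D = 1:30, H = -(1:30), E = rnorm(30))
  res <- estimator_correlations(df, stats = c("D", "H", "E"))
  expect_equal(diag(res$rho), c(D = 1, H = 1, E = 1))
  expect_equal(res$rho["D", "H"], -1)
  expect_equal(res$rho, t(res$rho))

  # fewer than 3 complete pairs -> undefined entry
  df2 <- data.frame(gene_id = paste0("g", 1:5), D = 1:5,
                    H = c(1, 2, NA, NA, NA))
  expect_true(is.na(estimator_correlations(df2,
                                           stats = c("D", "H"))$rho[1, 2]))
})

test_that("H and E are strongly anticorrelated across heterogeneous genes", {
  # between-gene variation in spectrum shape (the regime of real data,
  # where genome-wide spectra are skewed to varying degrees) drives the
  # H/E rank correlation towards -1; the variance-normalised forms share
  # the theta_L axis with opposite signs
  set.seed(52)
  H <- E <- numeric(200)
  for (i in 1:200) {
    a <- simulate_coalescent_gene(20, 20, 600)
    mode <- sample(c("singleton_excess", "high_freq_excess"), 1)
    a <- skew_spectrum(a, mode, intensity = runif(1, 0.2, 0.95))
    s <- build_sfs(a)
    H[i] <- fay_wu_h(s, "normalized")
    E[i] <- zeng_e(s)
  }
  rho <- cor(H, E, method = "spearman", use = "complete.obs")
  expect_lt(rho, -0.9)
})

test_that("randomisation p follows (r + 1) / (s + 1) with strict ties", {
  set.seed(53)
  vals <- setNames(rnorm(2000), paste0("g", 1:2000))
  # focal genes forced far below everything: every draw median is higher
  vals[1:5] <- -1000
  res <- randomisation_test(vals, paste0("g", 1:5), "lower", s = 99)
  expect_equal(res$q, 99)
  expect_equal(res$p, 1 / 100)

  # the same extreme focal set tested in the wrong direction gives p = 1
  res2 <- randomisation_test(vals, paste0("g", 1:5), "higher", s = 99)
  expect_equal(res2$q, 0)
  expect_equal(res2$p, 1)

  # arithmetic: q = 94 of s = 99 in the tested direction -> p = 6/100
  expect_equal((99 - 94 + 1) / (99 + 1), 0.06)

  expect_error(randomisation_test(vals, "absent_gene", "lower", s = 9),
               "no focal genes")
})

test_that("randomisation is reproducible for a fixed seed", {
  vals <- setNames(rnorm(500), paste0("g", 1:500))
  focal <- paste0("g", sample(500, 40))
  r1 <- randomisation_test(vals, focal, "lower", s = 200, seed = 99)
  r2 <- randomisation_test(vals, focal, "lower", s = 200, seed = 99)
  expect_identical(r1, r2)
})

test_that("null randomisation p-values are approximately uniform", {
  set.seed(54)
  vals <- setNames(rnorm(300), paste0("g", 1:300))
  s <- 199
  ps <- vapply(1:500, function(i) {
    focal <- sample(names(vals), 25)
    randomisation_test(vals, focal, "lower", s = s)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("a modest median shift is detected with high power", {
  set.seed(55)
  n_genes <- 15000
  n_focal <- 500
  hits <- 0
  for (rep in 1:100) {
    vals <- rlnorm(n_genes, log(0.25), 0.5)  # dN/dS-like distribution
    focal_idx <- sample(n_genes, n_focal)
    vals[focal_idx] <- pmax(vals[focal_idx] - 0.05, 0.001)
    names(vals) <- paste0("g", 1:n_genes)
    p <- randomisation_test(vals, paste0("g", focal_idx), "lower",
                            s = 2000)$p
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
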