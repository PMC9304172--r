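test_that("the coalescent generator is deterministic and honours theta", {
  a1 <- simulate_coalescent_gene(10, 5, 500, seed = 77)
  a2 <- simulate_coalescent_gene(10, 5, 500, seed = 77)
  expect_identical(a1, a2)

  # theta -> 0 gives no segregating sites
  a0 <- simulate_coalescent_gene(10, 0, 500, seed = 78)
  expect_equal(build_sfs(a0)$seg_sites, 0)

  # alignment shape and outgroup row
  expect_equal(dim(a1$haplotypes), c(10, 500))
  expect_equal(length(a1$outgroup), 500)
  expect_equal(nchar(a1$ancestral), 500)
})

test_that("spectrum skewing shifts the statistics in the expected way", {
  set.seed(81)
  base <- simulate_coalescent_gene(15, 10, 600)
  expect_identical(skew_spectrum(base, "singleton_excess", 0), base)
  expect_identical(skew_spectrum(base, "neutral", 0.9), base)

  D <- Ds <- H <- E <- matrix(NA_real_, 40, 2)
  for (i in 1:40) {
    a <- simulate_coalescent_gene(15, 10, 600)
    s1 <- build_sfs(skew_spectrum(a, "singleton_excess", 0.9))
    s2 <- build_sfs(skew_spectrum(a, "high_freq_excess", 0.9))
    D[i, ] <- c(tajimas_d(s1), tajimas_d(s2))
    Ds[i, ] <- c(fu_li_d_star(s1), fu_li_d_star(s2))
    H[i, ] <- c(fay_wu_h(s1), fay_wu_h(s2))
    E[i, ] <- c(zeng_e(s1), zeng_e(s2))
  }
  expect_lt(mean(D[, 1], na.rm = TRUE), 0)
  expect_lt(mean(Ds[, 1], na.rm = TRUE), 0)
  expect_lt(mean(H[, 2], na.rm = TRUE), 0)
  expect_gt(mean(E[, 2], na.rm = TRUE), 0)
})

test_that("ortholog pairs respect omega = 0 and zero branch length", {
  p0 <- simulate_ortholog_pair(100, 0, 0.1, seed = 82)
  est <- ng86_dnds(list(aligned_a = p0$cds_a, aligned_b = p0$cds_b))
  expect_equal(est$dN, 0)
  expect_gt(est$dS, 0)

  pid <- simulate_ortholog_pair(100, 1, 0, seed = 83)
  expect_identical(pid$cds_a, pid$cds_b)
  expect_equal(pid$n_subs, 0L)
})

test_that("Poisson MK tables carry the generating signal", {
  t0 <- simulate_mk_counts(c(0, 0, 0, 0), seed = 84)
  expect_equal(c(t0$Dn, t0$Ds, t0$Pn, t0$Ps), rep(0L, 4))
  expect_true(is.na(direction_of_selection(t0)))

  set.seed(85)
  dos <- vapply(1:300, function(i) {
    direction_of_selection(simulate_mk_counts(c(20, 10, 5, 10)))
  }, numeric(1))
  expect_gt(mean(dos, na.rm = TRUE), 0)  # fixation-biased rates
})

test_that("fitness tables reflect the programmed knockout effect", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:379),
                      candidate = rep(c(TRUE, FALSE), c(75, 304)))
  tab <- simulate_fitness_table(genes, effect = 0.2, noise_sd = 0.2,
                                n_replicates = 4, seed = 86)
  expect_s3_class(tab, "fitness_table")
  agg <- aggregate_gene_fitness(tab)
  # every gene passes the >3-observation filter with 4 replicates
  expect_equal(nrow(agg), 379)
  w_cand <- mean(agg$w[agg$gene_id %in% genes$gene_id[genes$candidate]])
  w_rest <- mean(agg$w[agg$gene_id %in% genes$gene_id[!genes$candidate]])
  expect_equal(w_cand, 0.8, tolerance = 0.08)
  expect_equal(w_rest, 1.0, tolerance = 0.05)
})

test_that("full datasets are complete and byte-identical for one seed", {
  cfg <- sim_config(seed = 87, n_genes = 20, n_haplotypes = 8, theta = 8,
                    L = 60)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_full_dataset(cfg, file.path(d1, "ds"))
  m2 <- generate_full_dataset(cfg, file.path(d2, "ds"))

  expect_equal(length(list.files(file.path(d1, "ds", "haplotypes"))), 20)
  expect_equal(length(list.files(file.path(d1, "ds", "orthologs"))), 20)
  expect_equal(nrow(m1), 20)
  expect_true(all(c("omega_true", "essential") %in% names(m1)))

  files <- list.files(file.path(d1, "ds"), recursive = TRUE)
  expect_setequal(files, list.files(file.path(d2, "ds"), recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, "ds", f)),
                     readLines(file.path(d2, "ds", f)), info = f)
  }
  # refusing to clobber an existing directory
  expect_error(generate_full_dataset(cfg, file.path(d1, "ds")), "exists")
})
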