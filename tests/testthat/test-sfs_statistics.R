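test_that("build_sfs tallies derived counts against the outgroup", {
  # 4 haplotypes, 2 segregating sites: site 2 has derived C in 3 copies,
  # site 3 has derived G in 1 copy (outgroup matches the ancestral state)
  aln <- aln_from_strings("TAG", "TCA", "TCA", "TCA", outgroup = "TAA")
  sfs <- build_sfs(aln)
  expect_equal(sfs$n, 4)
  expect_equal(sfs$seg_sites, 2)
  expect_equal(sfs$unfolded_counts, c(1L, 0L, 1L))
  expect_equal(sfs$S, 2)
  expect_equal(sfs$eta_s, 2)  # both sites' rarer allele is a singleton

  # outgroup showing a third allele: unpolarized but still segregating
  aln2 <- aln_from_strings("TAA", "TCA", "TCA", "TCA", outgroup = "TGA")
  sfs2 <- build_sfs(aln2)
  expect_equal(sfs2$seg_sites, 1)
  expect_equal(sfs2$unpolarized_sites, 1)
  expect_equal(sfs2$S, 0)

  # monomorphic alignment
  sfs3 <- build_sfs(aln_from_strings("TAA", "TAA", "TAA", outgroup = "TAA"))
  expect_equal(sfs3$seg_sites, 0)

  # gap or N in any used row excludes the site
  aln4 <- aln_from_strings("TAA", "TCA", "TC-", "TCA", outgroup = "TAA")
  expect_equal(build_sfs(aln4)$seg_sites, 1)
})

test_that("theta estimators reproduce the hand-evaluated spectrum", {
  sfs <- sfs_from_counts(4, c(1, 3))
  th <- theta_estimators(sfs)
  expect_equal(th$theta_pi, 1)
  expect_equal(th$theta_h, 5 / 3, tolerance = 1e-12)
  expect_equal(th$theta_l, 4 / 3, tolerance = 1e-12)
  expect_equal(th$theta_w, 2 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)

  empty <- sfs_from_counts(4, integer(0))
  th0 <- theta_estimators(empty)
  expect_equal(unlist(th0), c(theta_w = 0, theta_pi = 0, theta_h = 0,
                              theta_l = 0))
})

test_that("the theta identity holds to 1e-12 on random spectra", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    S <- sample(1:80, 1)
    sfs <- sfs_from_counts(n, sample(seq_len(n - 1), S, replace = TRUE))
    th <- theta_estimators(sfs)
    expect_lt(abs((th$theta_pi - th$theta_h) -
                    2 * (th$theta_pi - th$theta_l)), 1e-12)
  }
})

test_that("theta_pi equals brute-force mean pairwise differences", {
  set.seed(42)
  for (i in 1:50) {
    aln <- simulate_coalescent_gene(sample(5:15, 1), 5, 300,
                                    outgroup_divergence = 0)
    sfs <- build_sfs(aln)
    expect_equal(theta_estimators(sfs)$theta_pi,
                 oracle_mean_pairwise_diff(aln$haplotypes),
                 tolerance = 1e-9)
  }
})

test_that("Tajima's D vanishes, and signs follow the spectrum", {
  # 3 haplotypes AAA/AAT/ATT: theta_pi = 4/3 = theta_w
  aln <- aln_from_strings("AAA", "AAT", "ATT")
  sfs <- build_sfs(aln)
  expect_equal(sfs$seg_sites, 2)
  expect_equal(tajimas_d(sfs), 0)

  # excess singletons push D below zero; intermediates push it above
  expect_lt(tajimas_d(sfs_from_counts(20, rep(1, 60))), 0)
  expect_gt(tajimas_d(sfs_from_counts(20, rep(10, 60))), 0)
  expect_true(is.na(tajimas_d(sfs_from_counts(20, integer(0)))))
})

test_that("Fu & Li's D* responds to singleton excess", {
  expect_true(is.na(fu_li_d_star(sfs_from_counts(20, integer(0)))))
  expect_lt(fu_li_d_star(sfs_from_counts(20, rep(1, 60))), 0)
  expect_gt(fu_li_d_star(sfs_from_counts(20, rep(10, 60))), 0)
})

test_that("Fay & Wu's H matches hand values and its identity", {
  sfs <- sfs_from_counts(4, c(1, 3))
  expect_equal(fay_wu_h(sfs), 1 - 5 / 3, tolerance = 1e-12)

  set.seed(43)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    sfs_r <- sfs_from_counts(n, sample(seq_len(n - 1), 40, replace = TRUE))
    th <- theta_estimators(sfs_r)
    expect_equal(fay_wu_h(sfs_r), 2 * (th$theta_pi - th$theta_l),
                 tolerance = 1e-12)
  }
  # singleton-dominated spectra make theta_h tiny, H positive
  expect_gt(fay_wu_h(sfs_from_counts(30, rep(1, 50))), 0)
  # high-frequency derived alleles make H negative
  expect_lt(fay_wu_h(sfs_from_counts(30, rep(29, 50))), 0)
})

test_that("Zeng's E separates singleton from high-frequency spectra", {
  expect_true(is.na(zeng_e(sfs_from_counts(20, integer(0)))))
  expect_lt(zeng_e(sfs_from_counts(20, rep(1, 60))), 0)
  expect_gt(zeng_e(sfs_from_counts(20, rep(19, 60))), 0)
})

test_that("profiles apply the 50-segregating-site validity rule", {
  set.seed(44)
  p49 <- profile_gene(aln_with_seg_sites(6, 300, 49))
  expect_false(p49$valid)
  expect_true(is.na(p49$D))
  expect_equal(p49$seg_sites, 49)

  p50 <- profile_gene(aln_with_seg_sites(6, 300, 50))
  expect_true(p50$valid)
  expect_false(is.na(p50$D))

  mono <- profile_gene(aln_from_strings("AAATTT", "AAATTT",
                                        outgroup = "AAATTT"))
  expect_false(mono$valid)
})
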