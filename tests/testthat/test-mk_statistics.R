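test_that("SNPs classify by codon effect, with frame ambiguity detected", {
  iv <- data.frame(start = 1, end = 9)
  model <- gene_model("g1", "chr1", "+", list(t1 = iv))
  cds <- list(t1 = "TTTAAAGGG")

  # codon 1 position 3: TTT -> TTC (Phe/Phe)
  expect_equal(classify_snp(list(pos = 3, ref = "T", alt = "C"),
                            model, cds), "synonymous")
  # TTT -> TTA (Phe -> Leu)
  expect_equal(classify_snp(list(pos = 3, ref = "T", alt = "A"),
                            model, cds), "nonsynonymous")
  # outside the CDS
  expect_equal(classify_snp(list(pos = 50, ref = "A", alt = "C"),
                            model, cds), "noncoding")
  expect_error(classify_snp(list(pos = 3, ref = "G", alt = "C"),
                            model, cds), "mismatch")
})

test_that("conflicting frames across transcripts give ambiguous", {
  # transcript 2 starts one base later, shifting the reading frame
  model <- gene_model("g1", "chr1", "+",
                      list(t1 = data.frame(start = 1, end = 9),
                           t2 = data.frame(start = 2, end = 10)))
  genome <- "TTTCTTAGGG"
  cds <- list(t1 = substr(genome, 1, 9),    # TTT CTT AGG
              t2 = substr(genome, 2, 10))   # TTC TTA GGG
  # pos 3, T -> C: in t1 it is codon 1 position 3 (TTT -> TTC, Phe/Phe,
  # synonymous); in t2 it is codon 1 position 2 (TTC -> TCC, Phe -> Ser)
  expect_equal(classify_snp(list(pos = 3, ref = "T", alt = "C"),
                            model, cds), "ambiguous")
})

test_that("minus-strand SNPs are complemented before classification", {
  iv <- data.frame(start = 11, end = 19)
  model <- gene_model("gm", "chr1", "-", list(t1 = iv))
  cds <- list(t1 = "TTTAAAGGG")  # mRNA sense
  # mRNA offset 3 corresponds to genomic position 19 - 3 + 1 = 17;
  # mRNA T at offset 3 means genomic A on the plus strand
  expect_equal(classify_snp(list(pos = 17, ref = "A", alt = "G"),
                            model, cds), "synonymous")  # TTT -> TTC
})

test_that("MK tables count polymorphisms per site and round divergence", {
  classes <- c("synonymous", "synonymous", "synonymous",
               "nonsynonymous", "nonsynonymous", "ambiguous", "noncoding")
  t <- count_mk_table("g", classes, list(Nd = 4.0, Sd = 6.0))
  expect_equal(t$Dn, 4L)
  expect_equal(t$Ds, 6L)
  expect_equal(t$Pn, 2L)
  expect_equal(t$Ps, 3L)

  # round half away from zero
  t2 <- count_mk_table("g", character(0), list(Nd = 3.5, Sd = 2.5))
  expect_equal(t2$Dn, 4L)
  expect_equal(t2$Ds, 3L)
  expect_equal(t2$Pn, 0L)
})

test_that("NI matches direct formula evaluation and is antisymmetric", {
  expect_equal(neutrality_index(list(Dn = 3, Ds = 3, Pn = 3, Ps = 3)), 0)
  expect_equal(neutrality_index(list(Dn = 2, Ds = 3, Pn = 1, Ps = 4)),
               log(21 / 45), tolerance = 1e-12)
  expect_equal(neutrality_index(list(Dn = 1, Ds = 1, Pn = 10, Ps = 1)),
               log(7), tolerance = 1e-12)
  expect_equal(neutrality_index(list(Dn = 2, Ds = 3, Pn = 1, Ps = 4),
                                log_base = "10"),
               log10(21 / 45), tolerance = 1e-12)

  # swapping (Dn, Ds) with (Pn, Ps) flips the sign
  set.seed(31)
  for (i in 1:50) {
    cnt <- as.list(rpois(4, 8))
    names(cnt) <- c("Dn", "Ds", "Pn", "Ps")
    swapped <- list(Dn = cnt$Pn, Ds = cnt$Ps, Pn = cnt$Dn, Ps = cnt$Ds)
    expect_equal(neutrality_index(cnt), -neutrality_index(swapped),
                 tolerance = 1e-12)
  }
})

test_that("DOS matches its formula, stays in [-1, 1], opposes NI in sign", {
  expect_equal(direction_of_selection(list(Dn = 1, Ds = 1, Pn = 1, Ps = 1)),
               0)
  expect_equal(direction_of_selection(list(Dn = 2, Ds = 3, Pn = 1, Ps = 4)),
               0.2, tolerance = 1e-12)
  expect_equal(direction_of_selection(list(Dn = 5, Ds = 0, Pn = 0, Ps = 5)),
               1)
  expect_true(is.na(direction_of_selection(list(Dn = 0, Ds = 0, Pn = 1,
                                                Ps = 1))))

  set.seed(32)
  discord <- 0
  n_checked <- 0
  for (i in 1:200) {
    cnt <- as.list(20 + rpois(4, 15))
    names(cnt) <- c("Dn", "Ds", "Pn", "Ps")
    dos <- direction_of_selection(cnt)
    ni <- neutrality_index(cnt)
    expect_true(dos >= -1 && dos <= 1)
    if (dos != 0 && ni != 0) {
      n_checked <- n_checked + 1
      if (sign(dos) != -sign(ni)) discord <- discord + 1
    }
  }
  expect_lt(discord / n_checked, 0.05)
})

test_that("polymorphic sites of a CDS alignment classify like SNPs", {
  base <- "TTTAAAGGGCCC"
  rows <- c(hap1 = base, hap2 = base, hap3 = base)
  # hap2 carries TTT->TTC (syn, site 3) and AAA->ACA (nonsyn, site 5)
  s <- strsplit(base, "")[[1]]
  s[3] <- "C"; s[5] <- "C"
  rows["hap2"] <- paste(s, collapse = "")
  aln <- haplotype_alignment(rows, gene_id = "g")
  classes <- classify_polymorphic_sites(aln)
  expect_equal(sort(classes), c("nonsynonymous", "synonymous"))
})
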