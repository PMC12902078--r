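test_that("Nei-Gojobori site counts match hand enumeration for key codons", {
  expect_equal(ng_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng_site_counts("TTT", "weighted"), c(s = 0.5, n = 2.5))
  expect_equal(ng_site_counts("ATG"), c(s = 0, n = 3))
  expect_equal(ng_site_counts("ATG", "weighted"), c(s = 0, n = 3))
  expect_error(ng_site_counts("TAA"), "stop")
})

test_that("s + n = 3 for all 61 sense codons under both schemes", {
  sense <- names(GENCODE)[GENCODE != "*"]
  for (cod in sense) {
    for (sch in c("unweighted", "weighted")) {
      sn <- ng_site_counts(cod, sch)
      expect_equal(unname(sn["s"] + sn["n"]), 3, tolerance = 1e-9)
    }
  }
})

test_that("difference counts match the brute-force pathway enumerator over all codon pairs", {
  expect_equal(ng_diff_counts("GGG", "GGA"), c(Sd = 1, Nd = 0))
  expect_equal(ng_diff_counts("ATG", "ATA"), c(Sd = 0, Nd = 1))
  expect_equal(ng_diff_counts("TTT", "GTA"), c(Sd = 0.5, Nd = 1.5))
  expect_equal(ng_diff_counts("AAA", "AAA"), c(Sd = 0, Nd = 0))

  sense <- names(GENCODE)[GENCODE != "*"]
  dev_oracle <- 0
  dev_conserve <- 0
  for (a in sense) for (b in sense) {
    got <- ng_diff_counts(a, b)
    want <- bf_diff_counts(a, b)
    dev_oracle <- max(dev_oracle, abs(got - want))
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    dev_conserve <- max(dev_conserve,
                        abs(unname(got["Sd"] + got["Nd"]) - ndiff))
  }
  expect_lt(dev_oracle, 1e-12)   # all 61x61 pairs vs brute force
  expect_lt(dev_conserve, 1e-12) # Sd + Nd equals differing positions
})

test_that("Jukes-Cantor and gamma corrections match closed forms and are monotone", {
  expect_equal(jc_correct(0), 0)
  expect_equal(gamma_correct(0), 0)
  expect_equal(jc_correct(0.3), 0.3831, tolerance = 1e-4)
  expect_equal(gamma_correct(0.3, a = 1), 0.5)
  expect_equal(gamma_correct(0.3, a = 1), 0.3 / (1 - 0.4))
  expect_warning(expect_true(is.na(jc_correct(0.75))), "saturated")
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(jc_correct(p)) > 0))
  expect_true(all(diff(gamma_correct(p, 0.7)) > 0))
})

test_that("haplotype diversity matches Nei's formula including the published tally", {
  expect_equal(haplotype_diversity(rep(1, 10)), 1.0)
  expect_equal(haplotype_diversity(5), 0)
  # 16 clones, one haplotype seen twice, fourteen once
  expect_equal(round(haplotype_diversity(c(2, rep(1, 14))), 2), 0.99)
  expect_equal(haplotype_diversity(c(2, rep(1, 14))), 0.9916667,
               tolerance = 1e-6)
  expect_true(is.na(haplotype_diversity(1)))
})

test_that("pi at silent and replacement sites matches closed forms", {
  # 6 nt exon with no synonymous sites (ATG TGG), 30 nt intron: the silent
  # pool is exactly the 30 noncoding positions
  cds <- "ATGTGG"
  intr <- paste(rep("ACTGA", 6), collapse = "")
  s1 <- paste0(cds, intr)
  s2 <- mutate_at(s1, 6 + c(3, 10, 20))  # 3 intron differences
  aln <- trivial_alignment(c(a = s1, b = s2), s1)
  ann <- reference_annotation("L", "r", list(c(1, 6)))
  m <- build_site_mask(aln, ann)
  pi <- pi_by_class(aln, m)
  expect_equal(pi$pi_silent, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(round(pi$pi_silent, 4), 0.1073)
  expect_equal(pi$pi_nonsyn, 0)
  expect_equal(pi$sites_used$noncoding_sites, 30)

  ident <- pi_by_class(trivial_alignment(c(a = s1, b = s1), s1), m)
  expect_equal(ident$pi_silent, 0)
  expect_equal(ident$pi_nonsyn, 0)
})

test_that("Tajima's D matches the hand-evaluated n=4 singleton case and sign conventions", {
  a <- trivial_alignment(c(s1 = "AAA", s2 = "AAT", s3 = "AAT", s4 = "AAT"),
                         "AAA")
  td <- tajimas_d(a)
  expect_equal(td$S, 1L)
  expect_equal(td$k_hat, 0.5)
  expect_equal(td$D, -0.6123724, tolerance = 1e-6)

  mono <- trivial_alignment(c(s1 = "AAA", s2 = "AAA", s3 = "AAA", s4 = "AAA"),
                            "AAA")
  expect_true(is.na(tajimas_d(mono)$D))
  expect_error(tajimas_d(trivial_alignment(c(a = "AA", b = "AA"), "AA")),
               "n >= 4")

  # intermediate-frequency variants push D positive
  s <- paste(rep("A", 40), collapse = "")
  v <- mutate_at(s, 1:8)
  bal <- trivial_alignment(stats::setNames(c(rep(s, 3), rep(v, 3)),
                                           paste0("x", 1:6)), s)
  expect_gt(tajimas_d(bal)$D, 0)
})

test_that("divergence between groups matches closed forms", {
  cds <- "ATGTGG"
  intr <- paste(rep("ACTGA", 6), collapse = "")
  s1 <- paste0(cds, intr)
  s2 <- mutate_at(s1, 6 + c(3, 10, 20))
  aln <- trivial_alignment(c(a = s1, b = s2), s1)
  ann <- reference_annotation("L", "r", list(c(1, 6)))
  m <- build_site_mask(aln, ann)
  dv <- divergence(aln, m, "a", "b")
  expect_equal(round(dv$Ks, 4), 0.1073)
  expect_equal(dv$Ka, 0)
  expect_true(is.na(divergence(aln, m, "a", "a")$Ka_over_Ks))
  expect_equal(divergence(aln, m, "a", "a")$Ks, 0)
  expect_error(divergence(aln, m, character(0), "b"), "empty")
})

test_that("pi and K are invariant under sequence reordering", {
  loc <- random_locus(30, 45, seed = 11)
  base <- paste0(loc$cds, loc$intron)
  seqs <- c(a = base, b = mutate_at(base, c(5, 40, 100)),
            c = mutate_at(base, c(9, 60, 120)), d = mutate_at(base, 15))
  ann <- reference_annotation("L", "r", list(c(1, 90)))
  a1 <- trivial_alignment(seqs, base)
  a2 <- trivial_alignment(seqs[c(3, 1, 4, 2)], base)
  m1 <- build_site_mask(a1, ann)
  m2 <- build_site_mask(a2, ann)
  p1 <- pi_by_class(a1, m1)
  p2 <- pi_by_class(a2, m2)
  expect_equal(p1$pi_silent, p2$pi_silent)
  expect_equal(p1$pi_nonsyn, p2$pi_nonsyn)
  d1 <- divergence(a1, m1, c("a", "b"), c("c", "d"))
  d2 <- divergence(a2, m2, c("b", "a"), c("d", "c"))
  expect_equal(d1$Ks, d2$Ks)
  expect_equal(d1$Ka, d2$Ka)
})

test_that("McDonald-Kreitman cells, NI and Fisher p match a constructed table", {
  # noncoding part supplies exactly Ps = 10 and Ds = 10;
  # coding part supplies Pn = 2 and Dn = 10
  n_in <- 4
  intr_len <- 60
  intr <- paste(rep("C", intr_len), collapse = "")
  # ingroup: polymorphic at 10 intron positions (one variant each);
  # outgroup: fixed different at 10 other intron positions
  in_variant <- mutate_at(intr, 1:10, to = "T")
  out_intr <- mutate_at(intr, 21:30, to = "G")
  # coding: 12 AAA codons; outgroup AAC at codons 1-10 (Lys->Asn, nonsyn);
  # ingroup segregates Lys/Gln (AAA/CAA) at codons 11-12
  cds_in_a <- paste(rep("AAA", 12), collapse = "")
  cds_in_b <- paste(c(rep("AAA", 10), "CAA", "CAA"), collapse = "")
  cds_out <- paste(c(rep("AAC", 10), "AAA", "AAA"), collapse = "")
  seqs <- c(i1 = paste0(cds_in_a, intr), i2 = paste0(cds_in_a, in_variant),
            i3 = paste0(cds_in_b, intr), i4 = paste0(cds_in_b, intr),
            o1 = paste0(cds_out, out_intr))
  aln <- trivial_alignment(seqs, seqs[["i1"]])
  ann <- reference_annotation("L", "r", list(c(1, 36)))
  m <- build_site_mask(aln, ann)
  mk <- mk_test(aln, m, c("i1", "i2", "i3", "i4"), "o1")
  expect_equal(unname(c(mk$Pn, mk$Ps, mk$Dn, mk$Ds)), c(2, 10, 10, 10))
  expect_equal(mk$NI, (2 / 10) / (10 / 10))
  expect_equal(mk$fisher_p,
               stats::fisher.test(matrix(c(2, 10, 10, 10), 2))$p.value)
  expect_equal(mk$fisher_p, bf_fisher_p(matrix(c(2, 10, 10, 10), 2,
                                               byrow = TRUE)),
               tolerance = 1e-9)
})

test_that("MK test handles the no-difference and undefined-NI cases", {
  s <- paste0(paste(rep("AAA", 4), collapse = ""),
              paste(rep("C", 30), collapse = ""))
  aln <- trivial_alignment(c(i1 = s, i2 = s, o1 = s), s)
  m <- build_site_mask(aln, reference_annotation("L", "r", list(c(1, 12))))
  mk <- mk_test(aln, m, c("i1", "i2"), "o1")
  expect_equal(sum(mk$table), 0)
  expect_true(is.na(mk$fisher_p))
  expect_true(is.na(mk$NI))
  expect_error(mk_test(aln, m, "i1", "o1"), "ingroup")
})
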