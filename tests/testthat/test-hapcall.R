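test_that("length filter keeps reads strictly longer than 150 bp", {
  reads <- data.frame(sample = "S1",
                      sequence = c(strrep("A", 150), strrep("A", 151),
                                   strrep("A", 300)))
  kept <- filter_reads(reads)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_discarded"), 1)
  short <- data.frame(sample = "S1", sequence = rep(strrep("A", 100), 5))
  expect_warning(k2 <- filter_reads(short), "discarded")
  expect_equal(nrow(k2), 0)
  expect_warning(filter_reads(data.frame(sample = character(0),
                                         sequence = character(0))),
                 "no reads")
})

test_that("truncated reads are removed at the expected rate", {
  cfg <- sim_config(seed = 21, families = list(
    list(name = "F1", n_copies = 1, target_ks_within = 0)),
    samples = 2,
    read_sim = list(depth = 1000, sub_rate = 0, indel_rate = 0,
                    truncate_frac = 0.05, truncate_len = 120))
  tr <- simulate_family_set(cfg)
  rd <- simulate_reads(tr)
  kept <- filter_reads(rd$reads)
  frac <- nrow(kept) / nrow(rd$reads)
  expect_true(abs(frac - 0.95) < 0.02)
})

test_that("candidate posteriors follow the abundance-parent Poisson model", {
  set.seed(1)
  L <- 300
  parent <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  child <- mutate_at(parent, 57)  # k = 1
  eps <- 0.005
  lambda <- 1000 * (eps / 3) * (1 - eps)^(L - 1)
  expect_equal(lambda, 0.372, tolerance = 1e-2)

  reads <- data.frame(sample = "S1",
                      sequence = c(rep(parent, 1000), rep(child, 12)))
  cands <- call_candidates(reads, c(ref = parent),
                           error_model = list(eps = eps))
  expect_equal(nrow(cands$haps), 2)
  ch <- cands$haps[cands$haps$sequence == child, ]
  expect_equal(ch$posterior, stats::ppois(11, lambda), tolerance = 1e-6)
  expect_gt(ch$posterior, 0.999)

  # a singleton at k = 1 merges into the parent: P(N < 1) = e^-lambda <= 0.95
  reads1 <- data.frame(sample = "S1",
                       sequence = c(rep(parent, 1000), child))
  c1 <- call_candidates(reads1, c(ref = parent),
                        error_model = list(eps = eps))
  expect_equal(nrow(c1$haps), 1)
  expect_equal(sum(c1$counts), 1001)
  expect_equal(exp(-lambda), 0.689, tolerance = 1e-3)

  # a single unique sequence: one candidate with posterior 1 by convention
  cs <- call_candidates(data.frame(sample = "S1", sequence = rep(parent, 5)),
                        c(ref = parent), error_model = list(eps = eps))
  expect_equal(nrow(cs$haps), 1)
  expect_equal(cs$haps$posterior, 1)
  expect_error(call_candidates(reads1, c(ref = parent),
                               error_model = list(eps = 0)), "eps")
})

test_that("reverse-strand reads are orientation-normalized before dereplication", {
  set.seed(2)
  hap <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(hap)))
  reads <- data.frame(sample = "S1", sequence = c(rep(hap, 30), rep(rc, 30)))
  cands <- call_candidates(reads, c(ref = hap), error_model = list(eps = 0.01))
  expect_equal(nrow(cands$haps), 1)
  expect_equal(sum(cands$counts), 60)
})

test_that("validation cascade applies the published rules in order", {
  set.seed(3)
  L <- 240
  ref <- random_locus(L / 3, 0, seed = 33)$cds
  hapA <- ref
  hapB <- mutate_at(ref, c(10, 50))
  hapC <- mutate_at(ref, c(100, 140))
  counts <- matrix(c(80, 12, 8,
                     0, 30, 0), ncol = 2,
                   dimnames = list(NULL, c("S1", "S2")))
  hs <- manual_hapset(c(hapA, hapB, hapC), counts, ref_seq = ref)
  out <- apply_validation_cascade(hs, thresholds = list(min_freq = 0.15))
  expect_setequal(out$haps$sequence, c(hapA, hapB))
  expect_match(out$haps$flags[out$haps$sequence == hapB], "MULTI_SAMPLE")
  lg <- attr(out, "log")
  expect_equal(lg$rule[lg$id == "H003"], "frequency")

  # candidate with a 2-nt deletion: dropped without clone support, kept with
  del_hap <- paste0(substr(ref, 1, 99), substr(ref, 102, L))
  counts2 <- matrix(c(60, 40), ncol = 1, dimnames = list(NULL, "S1"))
  hs2 <- manual_hapset(c(hapA, del_hap), counts2, ref_seq = ref)
  out_nocl <- apply_validation_cascade(hs2)
  expect_false(del_hap %in% out_nocl$haps$sequence)
  expect_equal(attr(out_nocl, "log")$rule, "short_indel")

  out_cl <- apply_validation_cascade(hs2, clones = c(cl1 = del_hap))
  expect_true(del_hap %in% out_cl$haps$sequence)
  expect_match(out_cl$haps$flags[out_cl$haps$sequence == del_hap],
               "HAS_SHORT_INDEL")
  expect_match(out_cl$haps$flags[out_cl$haps$sequence == del_hap],
               "PCS_MATCHED")

  # novel 1-nt insertion is dropped regardless of frequency
  ins_hap <- paste0(substr(ref, 1, 120), "A", substr(ref, 121, L))
  hs3 <- manual_hapset(c(hapA, ins_hap),
                       matrix(c(10, 90), ncol = 1,
                              dimnames = list(NULL, "S1")),
                       ref_seq = ref)
  out3 <- apply_validation_cascade(hs3, clones = c(cl1 = hapA))
  expect_false(ins_hap %in% out3$haps$sequence)
})

test_that("premature stop codons are dropped unless present in a clone", {
  # reference: 30 codons without stops
  ref <- paste(rep("GCT", 30), collapse = "")
  annot <- reference_annotation("L", "r", list(c(1, 90)))
  stop_hap <- paste0("GCT", "TAA", strrep("GCT", 28))
  counts <- matrix(c(60, 40), ncol = 1, dimnames = list(NULL, "S1"))
  hs <- manual_hapset(c(ref, stop_hap), counts, ref_seq = ref)
  out <- apply_validation_cascade(hs, annot = annot)
  expect_false(stop_hap %in% out$haps$sequence)
  expect_equal(attr(out, "log")$rule, "premature_stop")
  out_cl <- apply_validation_cascade(hs, clones = c(cl = stop_hap),
                                     annot = annot)
  expect_true(stop_hap %in% out_cl$haps$sequence)
  expect_match(out_cl$haps$flags[out_cl$haps$sequence == stop_hap],
               "HAS_PREMATURE_STOP")
})

test_that("cascade errors when a sample has no reads to define frequencies", {
  ref <- strrep("ACGT", 50)
  hs <- manual_hapset(ref, matrix(c(10, 0), ncol = 2,
                                  dimnames = list(NULL, c("S1", "S2"))),
                      posterior = 0.5, ref_seq = ref)
  expect_error(apply_validation_cascade(hs), "zero reads")
})

test_that("read counts are conserved through calling and the cascade", {
  cfg <- small_two_family_cfg(31)
  tr <- simulate_family_set(cfg)
  rd <- simulate_reads(tr)
  amp <- tr$cfg$read_sim$amplicon
  ref_amp <- substr(tr$founder, amp[1], amp[2])
  fl <- filter_reads(rd$reads)
  cands <- call_candidates(fl, c(ref = ref_amp),
                           error_model = list(eps = 0.005))
  expect_equal(sum(cands$counts), nrow(fl))  # dereplication + merge conserve
  cl <- simulate_clones(tr)
  acc <- apply_validation_cascade(cands, clones = cl$clones,
                                  ref = c(ref = tr$founder), amplicon = amp)
  dropped_ids <- attr(acc, "log")$id
  expect_equal(sum(acc$counts) + sum(cands$counts[dropped_ids, , drop = FALSE]),
               sum(cands$counts))
})

test_that("raising min_freq never enlarges and adding clones never shrinks the accepted set", {
  cfg <- small_two_family_cfg(32)
  tr <- simulate_family_set(cfg)
  rd <- simulate_reads(tr)
  amp <- tr$cfg$read_sim$amplicon
  ref_amp <- substr(tr$founder, amp[1], amp[2])
  cands <- call_candidates(filter_reads(rd$reads), c(ref = ref_amp),
                           error_model = list(eps = 0.005))
  cl <- simulate_clones(tr)
  acc_lo <- apply_validation_cascade(cands, clones = cl$clones,
                                     ref = c(ref = tr$founder), amplicon = amp,
                                     thresholds = list(min_freq = 0.05))
  acc_hi <- apply_validation_cascade(cands, clones = cl$clones,
                                     ref = c(ref = tr$founder), amplicon = amp,
                                     thresholds = list(min_freq = 0.3))
  expect_true(all(acc_hi$haps$sequence %in% acc_lo$haps$sequence))
  no_cl <- apply_validation_cascade(cands, ref = c(ref = tr$founder),
                                    amplicon = amp)
  with_cl <- apply_validation_cascade(cands, clones = cl$clones,
                                      ref = c(ref = tr$founder),
                                      amplicon = amp)
  expect_true(all(no_cl$haps$sequence %in% with_cl$haps$sequence))
})

test_that("with error-free reads the accepted haplotypes equal the truth exactly", {
  cfg <- sim_config(seed = 41, families = list(
    list(name = "F1", n_copies = 3, target_ks_within = 0.12)),
    samples = 2, clone_sampling = 6,
    read_sim = list(depth = 300, sub_rate = 0, indel_rate = 0,
                    bias_sigma = 0))
  tr <- simulate_family_set(cfg)
  rd <- simulate_reads(tr)
  amp <- cfg$read_sim$amplicon
  ref_amp <- substr(tr$founder, amp[1], amp[2])
  cands <- call_candidates(filter_reads(rd$reads), c(ref = ref_amp),
                           error_model = list(eps = 1e-4))
  cl <- simulate_clones(tr)
  acc <- apply_validation_cascade(cands, clones = cl$clones,
                                  ref = c(ref = tr$founder), amplicon = amp)
  expect_setequal(acc$haps$sequence, unique(truth_sequences(tr, amp)))
})

test_that("mutation profile statistic matches hand-computed distances", {
  set.seed(77)  # aperiodic base so edit distance equals substitution count
  base <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
  s1 <- base
  s2 <- mutate_at(base, c(5, 25))           # 2 from s1
  s3 <- mutate_at(base, c(40, 44, 48, 52))  # 4 from s1, 6 from s2
  w1 <- mutate_at(base, c(60, 65, 70))      # 3 from s1
  counts <- matrix(c(10, 10, 10, 5,
                     10, 10, 10, 0), ncol = 2,
                   dimnames = list(NULL, c("S1", "S2")))
  counts[4, 2] <- 0
  hs <- manual_hapset(c(s1, s2, s3, w1), counts, ref_seq = base)
  hs$haps$n_samples <- c(2L, 2L, 2L, 1L)
  mp <- mutation_profile_statistic(hs)
  expect_equal(mp$mean_weak, 3)
  expect_equal(mp$mean_strong, mean(c(2, 2, 4)))
  expect_equal(mp$n_weak, 1)
  expect_equal(mp$n_strong, 3)

  # no weak haplotypes: strong side still reported
  hs2 <- manual_hapset(c(s1, s2, s3), counts[1:3, ], ref_seq = base)
  hs2$haps$n_samples <- c(2L, 2L, 2L)
  mp2 <- mutation_profile_statistic(hs2)
  expect_true(is.na(mp2$mean_weak))
  expect_equal(mp2$mean_strong, mean(c(2, 2, 4)))

  # fewer than two strong haplotypes: explicit null
  hs3 <- manual_hapset(c(s1, w1), matrix(c(10, 5), ncol = 1,
                                         dimnames = list(NULL, "S1")),
                       ref_seq = base)
  mp3 <- mutation_profile_statistic(hs3)
  expect_match(mp3$verdict, "undefined")
})

test_that("clone/read support correlation reproduces least-squares R^2", {
  reg <- data.frame(read_count = c(10, 20, 30), clone_count = c(1, 2, 3))
  expect_equal(suppressWarnings(correlate_clone_read_support(reg)), 1.0)
  reg2 <- data.frame(read_count = c(10, 20, 35), clone_count = c(1, 2, 3))
  # hand OLS: R^2 = Sxy^2 / (Sxx Syy) = 25^2 / (316.6667 * 2)
  expect_equal(correlate_clone_read_support(reg2), 625 / (316.66667 * 2),
               tolerance = 1e-6)
  reg3 <- data.frame(read_count = c(10, 20, 35), clone_count = c(2, 2, 2))
  expect_equal(correlate_clone_read_support(reg3), 0)
  expect_warning(
    expect_true(is.na(correlate_clone_read_support(reg3[1:2, ]))),
    "fewer than 3")
})

test_that("evidence registry joins PCS and MPS support over the amplicon segment", {
  cfg <- sim_config(seed = 43, families = list(
    list(name = "F1", n_copies = 2, target_ks_within = 0.12)),
    samples = 2, clone_sampling = 8,
    read_sim = list(depth = 200, sub_rate = 0, indel_rate = 0,
                    bias_sigma = 0))
  tr <- simulate_family_set(cfg)
  rd <- simulate_reads(tr)
  amp <- cfg$read_sim$amplicon
  ref_amp <- substr(tr$founder, amp[1], amp[2])
  cands <- call_candidates(filter_reads(rd$reads), c(ref = ref_amp),
                           error_model = list(eps = 1e-4))
  cl <- simulate_clones(tr)
  acc <- apply_validation_cascade(cands, clones = cl$clones,
                                  ref = c(ref = tr$founder), amplicon = amp)
  reg <- build_evidence_registry(acc, cl$clones, c(ref = tr$founder), amp)
  expect_true(all(reg$sources %in% c("MPS", "PCS", "MPS+PCS")))
  # every accepted haplotype drawn from a cloned copy carries both streams
  both <- reg[reg$sources == "MPS+PCS", ]
  expect_gte(nrow(both), 1)
  expect_true(all(both$read_count > 0 & both$clone_count > 0))
})
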