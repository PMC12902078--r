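test_that("synonymous distances follow the weighted-site gamma closed form", {
  # identical pair
  cds <- paste(rep("GGA", 20), collapse = "")
  aln <- trivial_alignment(c(a = cds, b = cds), cds)
  m <- build_site_mask(aln, reference_annotation("L", "r", list(c(1, 60))))
  D <- syn_distance_matrix(aln, m)
  expect_equal(unname(D["a", "b"]), 0)

  # GGA codons: third position fully synonymous; weighted s per codon:
  # all 3 third-position changes synonymous regardless of weight -> s = 1
  # per codon from position 3 (plus first-position GGA->AGA (Arg) etc. are
  # nonsynonymous). Mutate 6 of 20 third positions (transversion) and check
  # p_S = Sd / S_weighted, d = p/(1-4p/3).
  b <- cds
  for (k in 1:6) substr(b, 3 * k, 3 * k) <- "T"  # GGA->GGT synonymous
  aln2 <- trivial_alignment(c(a = cds, b = b), cds)
  D2 <- syn_distance_matrix(aln2, m)
  sW <- ng_site_counts("GGA", "weighted")[["s"]]
  p <- 6 / (20 * sW)
  expect_equal(unname(D2["a", "b"]), p / (1 - 4 * p / 3), tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly, including the 4-taxon case", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(co, D, tolerance = 1e-9)
  # split AB|CD present
  parts <- ape::prop.part(tr)
  expect_true(any(vapply(parts, function(p)
    setequal(tr$tip.label[p], c("A", "B")) ||
      setequal(tr$tip.label[p], c("C", "D")), TRUE)))

  # 3-taxon closed form
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  el <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(0.5, 1.5, 2.5))
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces random additive trees up to 12 taxa (path-length oracle)", {
  set.seed(99)
  for (z in 1:8) {
    n <- sample(4:12, 1)
    gen <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 2))
    D <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(D)
    co <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_equal(co, D, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(gen)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ agrees with the reference implementation and handles ties deterministically", {
  set.seed(10)
  n <- 7
  M <- matrix(stats::runif(n * n, 0.2, 2), n, n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  dimnames(D) <- list(letters[1:n], letters[1:n])
  tr <- nj_tree(D)
  ref <- ape::nj(stats::as.dist(D))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  # star-like equal matrix: deterministic output across runs
  E <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(E) <- 0
  expect_identical(write_newick(nj_tree(E)), write_newick(nj_tree(E)))

  # undefined entries are reported with the offending pair
  D2 <- D
  D2["a", "c"] <- NA
  D2["c", "a"] <- NA
  expect_error(nj_tree(D2), "a-c")
})

test_that("negative branch lengths are clamped to zero with the deficit logged", {
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- 0.1
  D["b", "a"] <- 0.1
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("bootstrap supports separate simulated families and are reproducible", {
  cfg <- small_two_family_cfg(55, ks_between = 0.5, n_copies = 3)
  tr <- simulate_family_set(cfg)
  al <- trivial_alignment(truth_sequences(tr), c(founder = tr$founder))
  m <- build_site_mask(al, tr$annotation)
  t1 <- bootstrap_support(al, m, B = 100, seed = 7)
  t2 <- bootstrap_support(al, m, B = 100, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))
  supp <- suppressWarnings(as.numeric(t1$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
  # the family split is strongly supported
  parts <- ape::prop.part(t1)
  labs <- t1$tip.label
  fam_split <- vapply(seq_along(parts), function(i) {
    p <- labs[parts[[i]]]
    setequal(p, c("F1.1", "F1.2", "F1.3")) ||
      setequal(p, c("F2.1", "F2.2", "F2.3"))
  }, TRUE)
  node_ids <- which(fam_split)
  expect_gte(length(node_ids), 1)
  sup_at <- as.numeric(t1$node.label[node_ids])
  expect_true(any(sup_at >= 95, na.rm = TRUE))

  # B = 1 gives supports in {0, 100}
  tb1 <- bootstrap_support(al, m, B = 1, seed = 3)
  s1 <- suppressWarnings(as.numeric(tb1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to taxon input order at fixed seed", {
  cfg <- small_two_family_cfg(56, ks_between = 0.5, n_copies = 2)
  tr <- simulate_family_set(cfg)
  seqs <- truth_sequences(tr)
  al1 <- trivial_alignment(seqs, c(founder = tr$founder))
  al2 <- trivial_alignment(seqs[rev(seq_along(seqs))],
                           c(founder = tr$founder))
  m1 <- build_site_mask(al1, tr$annotation)
  m2 <- build_site_mask(al2, tr$annotation)
  b1 <- bootstrap_support(al1, m1, ids = sort(names(seqs)), B = 50, seed = 5)
  b2 <- bootstrap_support(al2, m2, ids = sort(names(seqs)), B = 50, seed = 5)
  expect_identical(write_newick(b1), write_newick(b2))
})

test_that("simulated between-family distances exceed within-family distances", {
  cfg <- sim_config(seed = 57, families = list(
    list(name = "F1", n_copies = 2, target_ks_within = 0.1),
    list(name = "F2", n_copies = 2, target_ks_within = 0.1,
         target_ks_between = 0.6, diverge_from = "F1"),
    list(name = "F3", n_copies = 2, target_ks_within = 0.1,
         target_ks_between = 0.6, diverge_from = "F1")),
    locus_template = list(exons = c(120L, 120L, 120L), introns = c(60L, 60L)))
  tr <- simulate_family_set(cfg)
  al <- trivial_alignment(truth_sequences(tr), c(founder = tr$founder))
  m <- build_site_mask(al, tr$annotation)
  D <- syn_distance_matrix(al, m)
  fam <- tr$haplotypes$family
  within <- c(D["F1.1", "F1.2"], D["F2.1", "F2.2"], D["F3.1", "F3.2"])
  between <- D[fam[row(D)] != fam[col(D)] & upper.tri(D)]
  expect_gt(min(between), max(within))
})

test_that("newick output round-trips and quotes awkward labels", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  nwk <- write_newick(t3)
  back <- ape::read.tree(text = nwk)
  expect_setequal(back$tip.label, t3$tip.label)
  expect_equal(sort(back$edge.length), sort(t3$edge.length), tolerance = 1e-9)

  t3$tip.label[1] <- "taxon one"
  expect_match(write_newick(t3), "'taxon one'", fixed = TRUE)

  # node labels (supports) are written only when present
  expect_false(grepl(")[0-9]", write_newick(nj_tree(D3))))
  t3$node.label <- "87"
  expect_match(write_newick(t3), ")87", fixed = TRUE)

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(nj_tree(D3), f)
  expect_true(file.exists(f))
  expect_equal(length(ape::read.tree(f)$tip.label), 3)
})
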