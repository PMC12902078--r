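# Independent oracles and small fixtures shared across tests.

GENCODE <- Biostrings::GENETIC_CODE

# brute-force Nei-Gojobori pathway enumerator, written independently of the
# package implementation: recursive DFS over orderings of differing positions
bf_diff_counts <- function(a, b) {
  pa <- strsplit(a, "")[[1]]
  pb <- strsplit(b, "")[[1]]
  d <- which(pa != pb)
  if (length(d) == 0) return(c(Sd = 0, Nd = 0))
  paths <- list()
  walk <- function(cur, remaining, syn, non) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1L]] <<- c(syn, non)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- pb[p]
      if (GENCODE[[nxt]] == "*") next
      walk(nxt, setdiff(remaining, p),
           syn + (GENCODE[[nxt]] == GENCODE[[cur]]),
           non + (GENCODE[[nxt]] != GENCODE[[cur]]))
    }
  }
  walk(a, d, 0, 0)
  if (length(paths) == 0) return(c(Sd = 0, Nd = length(d)))
  m <- do.call(rbind, paths)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

# exhaustive two-tailed Fisher probability for a 2x2 table (sum of all
# hypergeometric outcomes with probability <= observed)
bf_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  p_of <- function(x) stats::dhyper(x, c1, n - c1, r1)
  p_obs <- p_of(a)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  sum(vapply(xs, p_of, 0)[vapply(xs, p_of, 0) <= p_obs * (1 + 1e-7)])
}

# random sense-codon CDS plus intron content, as plain strings
random_locus <- function(n_codons, intron_len, seed = 1) {
  set.seed(seed)
  sense <- names(GENCODE)[GENCODE != "*"]
  cds <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  intron <- paste(sample(c("A", "C", "G", "T"), intron_len, replace = TRUE),
                  collapse = "")
  list(cds = cds, intron = intron)
}

# mutate a sequence at given positions to a fixed different base
mutate_at <- function(seq, pos, to = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    choices <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- if (is.null(to)) choices[1] else to
  }
  paste(ch, collapse = "")
}

# small two-family simulation used by several modules
small_two_family_cfg <- function(seed, ks_between = 0.4, ks_within = 0.1,
                                 omega = 0.05, n_copies = 2) {
  sim_config(
    seed = seed,
    locus_template = list(exons = c(90L, 90L, 90L), introns = c(60L, 60L)),
    families = list(
      list(name = "F1", n_copies = n_copies, target_ks_within = ks_within),
      list(name = "F2", n_copies = n_copies, target_ks_within = ks_within,
           target_ks_between = ks_between, diverge_from = "F1")),
    omega = omega, samples = 2, clone_sampling = 4,
    read_sim = list(depth = 200, sub_rate = 0.005, indel_rate = 0.001))
}

# build a haplotype_set by hand (bypassing read calling)
manual_hapset <- function(seqs, counts, posterior = NULL, ref_seq = NULL,
                          flags = NULL) {
  counts <- as.matrix(counts)
  ids <- sprintf("H%03d", seq_along(seqs))
  rownames(counts) <- ids
  structure(list(
    haps = data.frame(id = ids, sequence = unname(seqs),
                      posterior = if (is.null(posterior)) rep(1, length(seqs))
                                  else posterior,
                      n_samples = as.integer(rowSums(counts > 0)),
                      total_reads = as.integer(rowSums(counts)),
                      flags = if (is.null(flags)) "" else flags),
    counts = counts,
    ref_seq = if (is.null(ref_seq)) seqs[[1]] else ref_seq),
    class = "haplotype_set")
}
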