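## Ground-truthed simulator of multi-family, multi-copy luciferase-like loci:
## codon-level family divergence with a tunable nonsynonymous/synonymous rate
## ratio (omega), recombinant alleles, clone (Sanger) sampling, and amplicon
## reads carrying substitution plus strand-biased short-indel errors.

#' Simulation configuration
#'
#' Defaults emulate the regime observed at copepod luciferase loci: three
#' paralogous families (deep split at synonymous divergence ~0.82, a younger
#' duplication at ~0.16), within-family silent diversity ~0.13-0.16, strong
#' purifying selection on amino-acid changes (omega = 0.05), clone sampling,
#' and ~360 bp amplicon reads with substitution and strand-biased 1-2 nt
#' indel errors.
#'
#' @param seed master seed; every random stage derives its own sub-stream
#'   from it, so outputs are bit-reproducible
#' @param locus_template list with integer vectors `exons` and `introns`
#'   (lengths, interleaved exon1-intron1-exon2-...); total exon length must
#'   be a multiple of 3
#' @param families list of family descriptors: `name`, `n_copies`,
#'   `target_ks_within` (silent divergence among copies),
#'   `target_ks_between` (silent divergence to the family in `diverge_from`;
#'   ignored for the first family), `diverge_from` (name of parent family,
#'   default the first family)
#' @param omega nonsynonymous/synonymous acceptance ratio of the mutator
#' @param recombinants list of `list(parent_a=, parent_b=, breakpoint=)`
#'   where parents are haplotype names (defaults to each family's first copy
#'   when a family name is given)
#' @param samples number of samples (individuals)
#' @param copies_per_sample optional number of haplotypes carried per sample
#'   (default: all haplotypes in every sample)
#' @param clone_sampling clones drawn per sample
#' @param read_sim list: `depth` (mean reads per sample), `sub_rate`,
#'   `indel_rate`, `indel_len_probs` (named probs for lengths 1 and 2),
#'   `strand_bias` (indel-rate multiplier on reverse-strand reads),
#'   `bias_sigma` (log-normal per-copy amplification bias),
#'   `amplicon` (`c(start, end)` on the locus), `truncate_frac`,
#'   `truncate_len`
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       locus_template = list(exons = c(120L, 150L, 180L, 150L, 120L),
                                             introns = c(90L, 90L, 90L, 90L)),
                       families = list(
                         list(name = "F1", n_copies = 3, target_ks_within = 0.15),
                         list(name = "F2", n_copies = 3, target_ks_within = 0.15,
                              target_ks_between = 0.82, diverge_from = "F1"),
                         list(name = "F3", n_copies = 3, target_ks_within = 0.13,
                              target_ks_between = 0.16, diverge_from = "F2")),
                       omega = 0.05,
                       recombinants = list(),
                       samples = 3,
                       copies_per_sample = NULL,
                       clone_sampling = 5,
                       read_sim = list()) {
  rs <- utils::modifyList(
    list(depth = 1000, sub_rate = 0.005, indel_rate = 0.001,
         indel_len_probs = c(`1` = 0.8, `2` = 0.2), strand_bias = 2,
         bias_sigma = 0.5, amplicon = NULL,
         truncate_frac = 0, truncate_len = 120),
    read_sim)
  ex <- as.integer(locus_template$exons)
  it <- as.integer(locus_template$introns)
  if (length(it) != length(ex) - 1L) stop("need one intron fewer than exons")
  if (sum(ex) %% 3L != 0L) stop("total exon length must be a multiple of 3")
  L <- sum(ex) + sum(it)
  if (is.null(rs$amplicon)) {
    a <- max(1L, (L - 360L) %/% 2L)
    rs$amplicon <- c(a, min(L, a + 359L))
  }
  for (r in c(rs$sub_rate, rs$indel_rate, rs$truncate_frac)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  }
  if (omega <= 0) stop("omega must be > 0")
  fam_names <- vapply(families, `[[`, "", "name")
  if (anyDuplicated(fam_names)) stop("duplicate family names")
  for (i in seq_along(families)) {
    f <- families[[i]]
    kb <- if (i == 1) 0 else f$target_ks_between
    if (is.null(kb)) stop("family ", f$name, " needs target_ks_between")
    if (kb < 0 || f$target_ks_within < 0) stop("target Ks must be >= 0")
    if (kb > 3 || f$target_ks_within > 3) {
      stop("infeasible target (Ks > 3) for family ", f$name)
    }
    families[[i]]$target_ks_between <- kb
    if (i > 1 && is.null(f$diverge_from)) families[[i]]$diverge_from <- fam_names[1]
  }
  structure(list(seed = as.integer(seed), locus_template = list(exons = ex, introns = it),
                 families = families, omega = omega, recombinants = recombinants,
                 samples = as.integer(samples), copies_per_sample = copies_per_sample,
                 clone_sampling = as.integer(clone_sampling), read_sim = rs,
                 locus_length = L),
            class = "sim_config")
}

## genomic coordinates of the template: codon position matrix and intron sites
template_layout <- function(tpl) {
  ex <- tpl$exons; it <- tpl$introns
  pos <- 1L
  exon_iv <- list(); intron_pos <- integer(0)
  for (i in seq_along(ex)) {
    exon_iv[[i]] <- c(pos, pos + ex[i] - 1L)
    pos <- pos + ex[i]
    if (i <= length(it)) {
      intron_pos <- c(intron_pos, seq.int(pos, pos + it[i] - 1L))
      pos <- pos + it[i]
    }
  }
  cds_pos <- unlist(lapply(exon_iv, function(iv) seq.int(iv[1], iv[2])))
  codon_pos <- matrix(cds_pos, ncol = 3, byrow = TRUE)
  list(exon_intervals = exon_iv, intron_pos = intron_pos, codon_pos = codon_pos)
}

## silent-pool JC distance between two character vectors on founder coords
silent_dist <- function(a, b, lay) {
  tabs <- ng_diff_tables()
  sU <- ng_site_table("unweighted")
  ia <- codon_to_index(paste0(a[lay$codon_pos[, 1]], a[lay$codon_pos[, 2]],
                              a[lay$codon_pos[, 3]]))
  ib <- codon_to_index(paste0(b[lay$codon_pos[, 1]], b[lay$codon_pos[, 2]],
                              b[lay$codon_pos[, 3]]))
  Sd <- sum(tabs$Sd[cbind(ia, ib)])
  s_sites <- sum((sU[ia] + sU[ib]) / 2)
  ncd <- sum(a[lay$intron_pos] != b[lay$intron_pos])
  p <- (Sd + ncd) / (s_sites + length(lay$intron_pos))
  jc_correct(p)
}

## codon-level mutator: accepts synonymous changes at rate 1, nonsynonymous
## at rate omega, rejects stops; introns drift at the synonymous event rate.
##
## Targeting is by a closed-form event budget rather than a
## measure-and-resample feedback loop: substitution events applied uniformly
## with uniform replacement bases form a Jukes-Cantor chain, so the expected
## JC-corrected distance equals the number of events per site. A uniform
## codon-position proposal is synonymous with probability
## s_sites / (3 n_codons), hence 3 n_codons * target proposals yield
## target * s_sites accepted synonymous events. The budget keeps the natural
## (multinomial/Poisson) dispersion of substitution counts, which downstream
## tests such as McDonald-Kreitman rely on; conditioning the stop on the
## realized distance would pin the silent counts and overdisperse the
## resulting 2x2 tables.
mutate_to_ks <- function(parent, lay, target, omega) {
  if (target <= 0) return(parent)
  cur <- parent
  n_codons <- nrow(lay$codon_pos)
  stopc <- unname(Biostrings::GENETIC_CODE[all_codons()] == "*")
  get_codon <- function(x, k) paste0(x[lay$codon_pos[k, 1]],
                                     x[lay$codon_pos[k, 2]],
                                     x[lay$codon_pos[k, 3]])
  n_prop <- ceiling(3 * n_codons * target)
  for (z in seq_len(n_prop)) {
    k <- sample.int(n_codons, 1)
    p <- sample.int(3, 1)
    gpos <- lay$codon_pos[k, p]
    old <- cur[gpos]
    newb <- sample(setdiff(BASES, old), 1)
    cod <- get_codon(cur, k)
    mut <- cod
    substr(mut, p, p) <- newb
    mi <- codon_to_index(mut)
    if (stopc[mi]) next
    syn <- codon_aa(mut) == codon_aa(cod)
    if (syn || stats::runif(1) < omega) cur[gpos] <- newb
  }
  ## neutral intron drift at the same event rate per site (multi-hits allowed)
  L_int <- length(lay$intron_pos)
  if (L_int > 0) {
    n_int <- stats::rpois(1, target * L_int)
    if (n_int > 0) {
      at <- sample(lay$intron_pos, n_int, replace = TRUE)
      for (a in at) cur[a] <- sample(setdiff(BASES, cur[a]), 1)
    }
  }
  cur
}

#' Simulate a multi-copy gene-family set with ground truth
#'
#' Draws a founder locus (sense codons only, random introns), derives family
#' master sequences by codon-level mutation until the realized silent
#' divergence to the parent family reaches its target, derives within-family
#' copies the same way, builds configured recombinants, and assigns
#' haplotypes (with per-sample log-normal amplification weights) to samples.
#'
#' @param cfg a [sim_config()]
#' @return an object of class `sim_truth`: haplotype registry, sequences,
#'   recombinant registry, per-sample assignments, annotation
#' @export
simulate_family_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- template_layout(cfg$locus_template)
  L <- cfg$locus_length
  founder <- with_seed(derive_seed(cfg$seed, "founder"), {
    chars <- character(L)
    chars[lay$intron_pos] <- sample(BASES, length(lay$intron_pos), replace = TRUE)
    cods <- sample(sense_codons(), nrow(lay$codon_pos), replace = TRUE)
    for (k in seq_len(nrow(lay$codon_pos))) {
      chars[lay$codon_pos[k, ]] <- seq_chars(cods[k])
    }
    chars
  })
  fam_names <- vapply(cfg$families, `[[`, "", "name")
  masters <- list()
  hap_seqs <- list()
  haps <- NULL
  within_of <- function(nm) {
    f <- Filter(function(x) x$name == nm, cfg$families)[[1]]
    if (f$n_copies > 1) f$target_ks_within else 0
  }
  for (i in seq_along(cfg$families)) {
    f <- cfg$families[[i]]
    parent <- if (i == 1) founder else masters[[f$diverge_from]]
    if (is.null(parent)) stop("diverge_from refers to unknown family: ", f$diverge_from)
    ## between-family targets are copy-level: subtract the expected
    ## within-family contribution of both sides (copies sit at within/2
    ## from their master, and distances are approximately additive)
    master_target <- if (i == 1) 0 else {
      max(0, f$target_ks_between - within_of(f$name) / 2 -
             within_of(f$diverge_from) / 2)
    }
    masters[[f$name]] <- with_seed(derive_seed(cfg$seed, "family", f$name),
      mutate_to_ks(parent, lay, master_target, cfg$omega))
    for (j in seq_len(f$n_copies)) {
      nm <- paste0(f$name, ".", j)
      hap_seqs[[nm]] <- if (f$n_copies == 1) masters[[f$name]] else
        with_seed(derive_seed(cfg$seed, "copy", f$name, j),
                  mutate_to_ks(masters[[f$name]], lay,
                               f$target_ks_within / 2, cfg$omega))
      haps <- rbind(haps, data.frame(name = nm, family = f$name, copy = j,
                                     is_recombinant = FALSE))
    }
  }
  recomb <- data.frame(name = character(0), parent_a = character(0),
                       parent_b = character(0), breakpoint = integer(0))
  for (r in cfg$recombinants) {
    pa <- if (r$parent_a %in% names(hap_seqs)) r$parent_a else paste0(r$parent_a, ".1")
    pb <- if (r$parent_b %in% names(hap_seqs)) r$parent_b else paste0(r$parent_b, ".1")
    nm <- if (!is.null(r$name)) r$name else paste0("R_", pa, "_", pb)
    sq <- make_recombinant(paste(hap_seqs[[pa]], collapse = ""),
                           paste(hap_seqs[[pb]], collapse = ""),
                           r$breakpoint)
    hap_seqs[[nm]] <- seq_chars(sq)
    haps <- rbind(haps, data.frame(name = nm, family = NA_character_,
                                   copy = NA_integer_, is_recombinant = TRUE))
    recomb <- rbind(recomb, data.frame(name = nm, parent_a = pa, parent_b = pb,
                                       breakpoint = as.integer(r$breakpoint)))
  }
  ## per-sample haplotype assignment with amplification bias
  assign <- NULL
  sample_ids <- paste0("S", seq_len(cfg$samples))
  for (s in sample_ids) {
    carried <- haps$name
    if (!is.null(cfg$copies_per_sample)) {
      carried <- with_seed(derive_seed(cfg$seed, "carry", s),
                           sample(haps$name, min(cfg$copies_per_sample,
                                                 length(haps$name))))
    }
    w <- with_seed(derive_seed(cfg$seed, "bias", s),
                   stats::rlnorm(length(carried), 0, cfg$read_sim$bias_sigma))
    assign <- rbind(assign, data.frame(sample = s, hap = carried,
                                       weight = w / sum(w)))
  }
  annot <- reference_annotation("simlocus", "founder", lay$exon_intervals)
  structure(list(cfg = cfg, layout = lay, annotation = annot,
                 founder = paste(founder, collapse = ""),
                 haplotypes = haps, hap_seqs = hap_seqs,
                 recombinants = recomb, sample_assign = assign),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated truth:", nrow(x$haplotypes), "haplotypes in",
      length(unique(stats::na.omit(x$haplotypes$family))), "families,",
      nrow(x$recombinants), "recombinants,", x$cfg$samples, "samples\n")
  invisible(x)
}

#' Full-length (or amplicon) truth sequences
#' @param truth a `sim_truth`
#' @param interval optional `c(start, end)` restriction (locus coordinates)
#' @return named character vector
#' @export
truth_sequences <- function(truth, interval = NULL) {
  out <- vapply(truth$hap_seqs, function(ch) {
    if (!is.null(interval)) ch <- ch[seq.int(interval[1], interval[2])]
    paste(ch, collapse = "")
  }, "")
  out
}

#' Join two aligned sequences at a breakpoint
#'
#' Returns `a[1..breakpoint]` followed by `b[(breakpoint+1)..L]` — the exact
#' structure of a single-crossover recombinant (or PCR chimera).
#'
#' @param a,b sequences of the same aligned length
#' @param breakpoint last position taken from `a`; `1 <= breakpoint < L`
#' @return character scalar
#' @examples
#' make_recombinant("AAAA", "CCCC", 2)  # "AACC"
#' @export
make_recombinant <- function(a, b, breakpoint) {
  if (nchar(a) != nchar(b)) stop("a and b must have the same aligned length")
  L <- nchar(a)
  if (breakpoint < 1 || breakpoint >= L) stop("breakpoint out of range [1, L)")
  paste0(substr(a, 1, breakpoint), substr(b, breakpoint + 1, L))
}

#' Simulate clone (Sanger) sampling
#'
#' Draws `clone_sampling` clones per sample from the sample's haplotypes with
#' the same amplification weights used for reads. Clones are error-free
#' full-length copies (Sanger sequencing treated as exact).
#'
#' @param truth a `sim_truth`
#' @param cfg the [sim_config()] (defaults to the one inside `truth`)
#' @param pool_samples optional list of character vectors; each element pools
#'   the listed samples into one template before drawing (pool-of-individuals
#'   designs)
#' @return list with `clones` (list of [seq_record()]s, evidence_source
#'   "PCS") and `clone_to_source` (data.frame)
#' @export
simulate_clones <- function(truth, cfg = truth$cfg, pool_samples = NULL) {
  if (cfg$clone_sampling < 1) stop("clone_sampling must be >= 1")
  seqs <- truth_sequences(truth)
  units <- if (is.null(pool_samples)) {
    stats::setNames(as.list(unique(truth$sample_assign$sample)),
                    unique(truth$sample_assign$sample))
  } else pool_samples
  clones <- list()
  map <- NULL
  for (u in names(units)) {
    sa <- truth$sample_assign[truth$sample_assign$sample %in% units[[u]], ]
    agg <- tapply(sa$weight, sa$hap, sum)
    hap_names <- names(agg)
    w <- as.numeric(agg) / sum(agg)
    draw <- with_seed(derive_seed(cfg$seed, "clones", u),
                      sample(hap_names, cfg$clone_sampling, replace = TRUE,
                             prob = w))
    for (i in seq_along(draw)) {
      id <- paste0("clone_", u, "_", i)
      clones[[id]] <- seq_record(id, seqs[[draw[i]]], sample_id = u,
                                 evidence_source = "PCS")
      map <- rbind(map, data.frame(clone = id, sample = u, source = draw[i]))
    }
  }
  list(clones = clones, clone_to_source = map)
}

## apply substitution and indel errors to one read (character vector in/out)
apply_read_errors <- function(chars, sub_rate, indel_rate, indel_len_probs) {
  L <- length(chars)
  nsub <- stats::rbinom(1, L, sub_rate)
  if (nsub > 0) {
    at <- sample.int(L, nsub)
    chars[at] <- vapply(chars[at], function(b) sample(setdiff(BASES, b), 1), "")
  }
  nind <- stats::rbinom(1, L, indel_rate)
  if (nind > 0) {
    for (z in seq_len(nind)) {
      pos <- sample.int(length(chars), 1)
      len <- sample(as.integer(names(indel_len_probs)), 1,
                    prob = indel_len_probs)
      if (stats::runif(1) < 0.5) {  # deletion
        keep <- setdiff(seq_along(chars), seq.int(pos, min(pos + len - 1,
                                                           length(chars))))
        chars <- chars[keep]
      } else {                      # insertion
        ins <- sample(BASES, len, replace = TRUE)
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  chars
}

#' Simulate amplicon reads
#'
#' Per sample, draws a Poisson read depth around the configured mean and
#' allocates reads to the sample's haplotypes with their amplification
#' weights. Every read covers the configured amplicon interval and receives
#' substitution errors at `sub_rate` per base and indels at `indel_rate` per
#' base (length 1 with probability 0.8, 2 with 0.2; insertion bases uniform).
#' About half the reads are reverse-strand, with the indel rate multiplied by
#' `strand_bias`; these are emitted reverse-complemented. Base qualities are
#' constant and consistent with `sub_rate`.
#'
#' @inheritParams simulate_clones
#' @return list with `reads` (data.frame: read_id, sample, sequence, quality,
#'   source, strand) and `read_to_source` (data.frame)
#' @export
simulate_reads <- function(truth, cfg = truth$cfg) {
  rs <- cfg$read_sim
  amp <- rs$amplicon
  if (amp[1] < 1 || amp[2] > cfg$locus_length) {
    stop("amplicon interval outside locus")
  }
  amp_seqs <- truth_sequences(truth, amp)
  q <- if (rs$sub_rate > 0) min(40L, round(-10 * log10(rs$sub_rate))) else 40L
  qc <- phred_to_char(q)
  out <- NULL
  for (s in unique(truth$sample_assign$sample)) {
    sa <- truth$sample_assign[truth$sample_assign$sample == s, ]
    rows <- with_seed(derive_seed(cfg$seed, "reads", s), {
      depth <- stats::rpois(1, rs$depth)
      src <- if (depth > 0) sample(sa$hap, depth, replace = TRUE, prob = sa$weight)
             else character(0)
      strand <- sample(c("+", "-"), depth, replace = TRUE)
      seqs <- character(depth)
      for (i in seq_len(depth)) {
        ind_rate <- rs$indel_rate * if (strand[i] == "-") rs$strand_bias else 1
        chars <- apply_read_errors(seq_chars(amp_seqs[[src[i]]]),
                                   rs$sub_rate, ind_rate, rs$indel_len_probs)
        seqs[i] <- paste(chars, collapse = "")
      }
      if (rs$truncate_frac > 0) {
        tr <- stats::runif(depth) < rs$truncate_frac
        seqs[tr] <- substr(seqs[tr], 1, rs$truncate_len)
      }
      if (depth == 0) NULL else {
        emitted <- ifelse(strand == "-", revcomp(seqs), seqs)
        data.frame(read_id = sprintf("%s_r%05d", s, seq_len(depth)),
                   sample = s, sequence = emitted,
                   quality = strrep(qc, nchar(emitted)),
                   source = src, strand = strand)
      }
    })
    out <- rbind(out, rows)
  }
  list(reads = out,
       read_to_source = out[, c("read_id", "sample", "source", "strand")])
}
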