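## End-to-end orchestration: simulate -> filter/call/validate -> classify ->
## diversity/divergence/MK -> tree -> annotate, with TSV/FASTA/Newick
## artifacts and a reproducible seed trail.

#' Restrict a reference annotation to an amplicon window
#'
#' Exon intervals are clipped to the window and shifted to amplicon
#' coordinates; partial codons at the window edges are trimmed so that the
#' amplicon codon layout stays in frame with the full-locus CDS.
#'
#' @param annot a [reference_annotation()]
#' @param amplicon `c(start, end)` on the annotation's reference
#' @return a [reference_annotation()] in amplicon coordinates, or `NULL`
#'   when no complete codon falls inside the window
#' @export
amplicon_annotation <- function(annot, amplicon) {
  cds <- unlist(lapply(annot$exon_intervals, function(iv) seq.int(iv[1], iv[2])))
  idx <- which(cds >= amplicon[1] & cds <= amplicon[2])
  if (length(idx) == 0) return(NULL)
  ## trim to whole codons of the original frame
  first <- idx[((idx - 1L) %% 3L) == 0L]
  last <- idx[(idx %% 3L) == 0L]
  if (length(first) == 0 || length(last) == 0) return(NULL)
  idx <- idx[idx >= min(first) & idx <= max(last)]
  if (length(idx) < 3) return(NULL)
  pos <- cds[idx] - amplicon[1] + 1L
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  reference_annotation(annot$locus, paste0(annot$reference_id, "_amplicon"),
                       lapply(runs, function(r) c(min(r), max(r))))
}

#' Default end-to-end run configuration
#'
#' All thresholds default to the published analysis settings: read length
#' > 150 bp, posterior > 0.95, within-sample frequency 15%, ts/tv bias
#' R = 2, gamma shape 1, 1000 bootstrap replicates.
#'
#' @param seed master seed
#' @param ... overrides for any top-level field
#' @return named list
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    sim = list(),            # passed to sim_config()
    min_len = 151,
    eps = NULL,              # defaults to the simulated substitution rate
    thresholds = list(posterior = 0.95, min_freq = 0.15),
    min_gain = 3,
    exclude_mosaics = TRUE,
    R = 2,
    gamma_a = 1,
    bootstrap = 1000,
    mk_outgroups = NULL      # named list family -> outgroup family
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full pipeline on simulated data
#'
#' Simulates a gene-family set, calls haplotypes from the simulated reads,
#' validates them against the simulated clones, classifies clone haplotypes
#' into families (flagging mosaics), computes per-family diversity,
#' between-family divergence, McDonald-Kreitman tests, and a bootstrapped
#' synonymous-distance NJ tree, and (optionally) writes all artifacts.
#'
#' @param cfg a [run_config()]
#' @param outdir optional output directory for FASTA/FASTQ/TSV/Newick
#'   artifacts
#' @return list with all stage results (`truth`, `clones`, `reads`,
#'   `accepted`, `registry`, `classification`, `diversity`, `divergence`,
#'   `mk`, `tree`, `config`)
#' @export
run_end_to_end <- function(cfg = run_config(), outdir = NULL) {
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  truth <- simulate_family_set(scfg)
  clones <- simulate_clones(truth)
  simreads <- simulate_reads(truth)
  amp <- scfg$read_sim$amplicon
  ref_amp <- substr(truth$founder, amp[1], amp[2])
  eps <- if (is.null(cfg$eps)) max(scfg$read_sim$sub_rate, 1e-4) else cfg$eps
  amp_annot <- amplicon_annotation(truth$annotation, amp)

  filtered <- filter_reads(simreads$reads, cfg$min_len)
  cands <- call_candidates(filtered, c(ref = ref_amp),
                           error_model = list(eps = eps))
  accepted <- apply_validation_cascade(
    cands, clones = clones$clones, ref = c(ref = truth$founder),
    amplicon = amp, annot = amp_annot, thresholds = cfg$thresholds)
  registry <- build_evidence_registry(accepted, clones$clones,
                                      c(ref = truth$founder), amp)

  ## classification of full-length clone haplotypes into families
  fams <- unique(stats::na.omit(truth$haplotypes$family))
  cl_seqs <- vapply(clones$clones, function(r) r$nucleotides, "")
  uniq <- !duplicated(cl_seqs)
  cl_seqs <- cl_seqs[uniq]
  classification <- NULL
  diag <- NULL
  if (length(fams) >= 2) {
    train <- truth_sequences(truth)
    train_fam <- truth$haplotypes$family[match(names(train),
                                               truth$haplotypes$name)]
    keep <- train_fam %in% fams[1:2]
    diag <- find_diagnostic_sites(train[keep], train_fam[keep])
    classification <- do.call(rbind, lapply(names(cl_seqs), function(id) {
      af <- assign_family(cl_seqs[[id]], diag)
      mc <- detect_mosaic(cl_seqs[[id]], diag, cfg$min_gain)
      data.frame(id = id, label = af$label, score = af$score,
                 is_mosaic = isTRUE(mc$is_mosaic),
                 breakpoint_lo = if (is.null(mc$breakpoint_interval))
                   NA_integer_ else mc$breakpoint_interval[1],
                 breakpoint_hi = if (is.null(mc$breakpoint_interval))
                   NA_integer_ else mc$breakpoint_interval[2])
    }))
  }

  ## evolutionary analyses on the true haplotype alignment (clone-backed),
  ## mosaics excluded by default
  seqs <- truth_sequences(truth)
  al <- trivial_alignment(seqs, c(founder = truth$founder))
  mask <- build_site_mask(al, truth$annotation, R = cfg$R)
  use_haps <- truth$haplotypes
  if (cfg$exclude_mosaics) use_haps <- use_haps[!use_haps$is_recombinant, ]
  fam_ids <- split(use_haps$name, use_haps$family)
  diversity <- lapply(fam_ids, function(ids) {
    if (length(ids) < 2) return(NULL)
    diversity_summary(al, mask, ids)
  })
  divergence_tab <- NULL
  if (length(fam_ids) >= 2) {
    cmb <- utils::combn(names(fam_ids), 2)
    divergence_tab <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(z) {
      dv <- divergence(al, mask, fam_ids[[cmb[1, z]]], fam_ids[[cmb[2, z]]])
      data.frame(family_a = cmb[1, z], family_b = cmb[2, z],
                 Ka = dv$Ka, Ks = dv$Ks, Ka_over_Ks = dv$Ka_over_Ks)
    }))
  }
  mk <- NULL
  if (length(fam_ids) >= 2) {
    outs <- cfg$mk_outgroups
    if (is.null(outs)) {
      nm <- names(fam_ids)
      outs <- stats::setNames(as.list(nm[c(2:length(nm), 1)]), nm)
    }
    mk <- lapply(names(fam_ids), function(f) {
      ing <- fam_ids[[f]]
      outg <- fam_ids[[outs[[f]]]][1]
      if (length(ing) < 2) return(NULL)
      mk_test(al, mask, ing, outg)
    })
    names(mk) <- names(fam_ids)
  }
  tree <- NULL
  if (length(use_haps$name) >= 3) {
    tree <- bootstrap_support(al, mask, ids = use_haps$name,
                              B = cfg$bootstrap,
                              seed = derive_seed(cfg$seed, "bootstrap"),
                              R = cfg$R, gamma_a = cfg$gamma_a)
  }

  res <- list(truth = truth, clones = clones, reads = simreads,
              filtered = filtered, candidates = cands, accepted = accepted,
              registry = registry, classification = classification,
              diagnostic_sites = diag, diversity = diversity,
              divergence = divergence_tab, mk = mk, tree = tree,
              config = cfg)
  if (!is.null(outdir)) write_report_bundle(res, outdir)
  res
}

#' Write the artifacts of an end-to-end run
#' @param res result of [run_end_to_end()]
#' @param outdir output directory (created if missing)
#' @export
write_report_bundle <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_fasta(truth_sequences(res$truth), file.path(outdir, "truth.fasta"))
  write_exon_table(res$truth$annotation, file.path(outdir, "exons.tsv"))
  write_fastq(res$reads$reads, file.path(outdir, "reads"))
  write_fasta(vapply(res$clones$clones, function(r) r$nucleotides, ""),
              file.path(outdir, "clones.fasta"))
  utils::write.table(res$reads$read_to_source,
                     file.path(outdir, "read_to_source.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$accepted$haps) > 0) {
    write_fasta(stats::setNames(res$accepted$haps$sequence,
                                res$accepted$haps$id),
                file.path(outdir, "accepted_haplotypes.fasta"))
  }
  write_registry_tsv(res$accepted, file.path(outdir, "registry.tsv"))
  utils::write.table(attr(res$accepted, "log"),
                     file.path(outdir, "cascade_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$classification)) {
    utils::write.table(res$classification,
                       file.path(outdir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  div <- res$diversity[!vapply(res$diversity, is.null, TRUE)]
  if (length(div) > 0) {
    d <- do.call(rbind, lapply(names(div), function(f) {
      x <- div[[f]]
      data.frame(family = f, n = x$n, S = x$S, Hd = x$Hd,
                 pi_silent = x$pi_silent, pi_nonsyn = x$pi_nonsyn,
                 tajima_D = x$tajima_D)
    }))
    utils::write.table(d, file.path(outdir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$divergence)) {
    utils::write.table(res$divergence, file.path(outdir, "divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  mk <- res$mk[!vapply(res$mk, is.null, TRUE)]
  if (length(mk) > 0) {
    d <- do.call(rbind, lapply(names(mk), function(f) {
      x <- mk[[f]]
      data.frame(family = f, Pn = x$Pn, Ps = x$Ps, Dn = x$Dn, Ds = x$Ds,
                 fisher_p = x$fisher_p, NI = x$NI)
    }))
    utils::write.table(d, file.path(outdir, "mk_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$tree)) {
    write_newick(res$tree, file.path(outdir, "tree.nwk"))
  }
  header <- c(sprintf("seed: %d", res$config$seed),
              sprintf("min_len: %d", res$config$min_len),
              sprintf("posterior: %.2f", res$config$thresholds$posterior),
              sprintf("min_freq: %.2f", res$config$thresholds$min_freq),
              sprintf("R: %g  gamma_a: %g  bootstrap: %d",
                      res$config$R, res$config$gamma_a, res$config$bootstrap))
  writeLines(header, file.path(outdir, "run_settings.txt"))
  invisible(outdir)
}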