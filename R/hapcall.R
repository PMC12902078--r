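## Amplicon haplotype calling: read filtering, abundance-based candidate
## calling with a Poisson error model, and the cross-evidence validation
## cascade (posterior, short-indel and premature-stop rules with clone
## exceptions, within-sample frequency rule with multi-sample/PCS rescue).

#' Length-filter amplicon reads
#'
#' Keeps reads strictly longer than `min_len - 1` bases (default: > 150 bp,
#' i.e. >= 151) and reports how many were kept and discarded.
#'
#' @param reads data.frame with columns `sample` and `sequence` (as produced
#'   by [simulate_reads()]), or a character vector
#' @param min_len minimum retained length
#' @return the filtered reads, with attributes `n_kept` and `n_discarded`
#' @export
filter_reads <- function(reads, min_len = 151) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0) {
    warning("no reads supplied")
    keep <- logical(0)
  } else {
    keep <- nchar(seqs) >= min_len
  }
  out <- if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
  if (length(seqs) > 0 && !any(keep)) warning("all reads discarded by length filter")
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

## choose orientation of unique sequences against the reference: count
## matches of evenly spaced reference 12-mers in each orientation (robust to
## the error rates seen in amplicon data); ties fall back to edit distance
orient_to_ref <- function(seqs, ref_seq) {
  L <- nchar(ref_seq)
  k <- 12L
  starts <- unique(pmax(1L, round(seq(1, L - k + 1, length.out = min(8L, L %/% k)))))
  seeds <- vapply(starts, function(s) substr(ref_seq, s, s + k - 1L), "")
  hits <- function(x) {
    n <- integer(length(x))
    for (sd in seeds) n <- n + grepl(sd, x, fixed = TRUE)
    n
  }
  rc <- revcomp(seqs)
  h_fwd <- hits(seqs)
  h_rev <- hits(rc)
  out <- ifelse(h_rev > h_fwd, rc, seqs)
  tie <- which(h_rev == h_fwd)
  if (length(tie) > 0) {
    d_fwd <- drop(utils::adist(seqs[tie], ref_seq))
    d_rev <- drop(utils::adist(rc[tie], ref_seq))
    out[tie] <- ifelse(d_rev < d_fwd, rc[tie], seqs[tie])
  }
  out
}

## is `a` obtainable from `b` by a single 1-nt insertion or deletion?
## (lengths must differ by exactly 1)
one_edit_away <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  n <- length(ca)
  mism <- which(ca != cb[seq_len(n)])
  if (length(mism) == 0) return(TRUE)      # deletion of the last base
  f <- mism[1]
  all(ca[f:n] == cb[(f + 1):(n + 1)])
}

## error-model distances from candidates to parents: exact substitution
## (Hamming) counts for equal lengths, 1 for a single short indel, and a
## conservative lower bound max(2, |length difference|) otherwise. The bound
## is exact enough for the Poisson model: at k >= 2 the expected
## error-derived count is negligible for any realistic parent abundance, so
## the accept/merge decision does not depend on the exact value.
dist_to_parents <- function(cand_seqs, parent_seqs) {
  d <- matrix(NA_real_, length(cand_seqs), length(parent_seqs))
  cl <- nchar(cand_seqs)
  for (j in seq_along(parent_seqs)) {
    pc <- seq_chars(parent_seqs[j])
    same <- which(cl == length(pc))
    if (length(same) > 0) {
      m <- matrix(unlist(strsplit(cand_seqs[same], "", fixed = TRUE)),
                  nrow = length(pc))
      d[same, j] <- colSums(m != pc)
    }
    off1 <- which(abs(cl - length(pc)) == 1L)
    for (i in off1) {
      d[i, j] <- if (one_edit_away(cand_seqs[i], parent_seqs[j])) 1 else 3
    }
    rest <- which(abs(cl - length(pc)) >= 2L)
    if (length(rest) > 0) d[rest, j] <- pmax(2, abs(cl[rest] - length(pc)))
  }
  d
}

#' Call candidate haplotypes from amplicon reads
#'
#' Reads are orientation-normalized against the reference and dereplicated
#' into exact-sequence candidates per sample. Candidates are processed in
#' decreasing abundance: for candidate `c` at edit distance `k` from the
#' nearest more-abundant accepted parent `p`, the expected count of
#' error-derived copies is `lambda = n_p (eps/3)^k (1-eps)^(L-k)`; the
#' candidate's posterior score is `P(N < n_c)` under `N ~ Poisson(lambda)`.
#' Candidates with posterior `<= merge_threshold` are merged into their
#' parent. The most abundant candidate of each sample is always accepted
#' (posterior 1 by convention).
#'
#' @param reads data.frame with columns `sample` and `sequence`
#'   (length-filtered, primer-trimmed)
#' @param ref amplicon reference sequence (character or [seq_record()])
#' @param error_model list with `eps`, the per-base substitution error rate
#' @param merge_threshold posterior at or below which candidates merge into
#'   their parent
#' @return an object of class `haplotype_set`: `haps` (data.frame: id,
#'   sequence, posterior, n_samples, total_reads, flags) and `counts`
#'   (haplotype x sample read-count matrix)
#' @export
call_candidates <- function(reads, ref, error_model = list(eps = 0.005),
                            merge_threshold = 0.95) {
  eps <- error_model$eps
  if (is.null(eps) || eps <= 0 || eps >= 1) stop("error_model$eps must be in (0, 1)")
  ref_seq <- unname(as_seqs(ref)[1])
  stopifnot(is.data.frame(reads), all(c("sample", "sequence") %in% names(reads)))
  ## orientation-normalize unique sequences once, then re-dereplicate
  uniq <- unique(reads$sequence)
  oriented <- stats::setNames(orient_to_ref(uniq, ref_seq), uniq)
  reads$sequence <- unname(oriented[reads$sequence])
  samples <- sort(unique(reads$sample))
  per_sample <- list()
  for (s in samples) {
    tab <- table(reads$sequence[reads$sample == s])
    o <- order(as.integer(tab), decreasing = TRUE)
    seqs <- names(tab)[o]
    n <- as.integer(tab)[o]
    acc_seq <- character(0); acc_n <- integer(0); acc_post <- numeric(0)
    ## process abundance tiers in decreasing order; parents for a tier are
    ## the strictly more abundant accepted candidates
    for (cval in unique(n)) {
      idx <- which(n == cval)
      parents <- which(acc_n > cval)
      if (length(parents) == 0) {
        ## tier with no more-abundant parent (incl. the most abundant
        ## candidate): accepted, posterior 1 by convention
        acc_seq <- c(acc_seq, seqs[idx])
        acc_n <- c(acc_n, n[idx])
        acc_post <- c(acc_post, rep(1, length(idx)))
        next
      }
      D <- dist_to_parents(seqs[idx], acc_seq[parents])
      nearest <- max.col(-D, ties.method = "first")
      j <- parents[nearest]
      k <- D[cbind(seq_along(idx), nearest)]
      L <- nchar(acc_seq)[j]
      lambda <- acc_n[j] * (eps / 3)^k * (1 - eps)^(L - k)
      post <- stats::ppois(cval - 1, lambda)
      accept <- post > merge_threshold
      for (z in which(!accept)) acc_n[j[z]] <- acc_n[j[z]] + cval
      acc_seq <- c(acc_seq, seqs[idx[accept]])
      acc_n <- c(acc_n, rep(cval, sum(accept)))
      acc_post <- c(acc_post, post[accept])
    }
    per_sample[[s]] <- data.frame(sequence = acc_seq, count = acc_n,
                                  posterior = acc_post)
  }
  all_seqs <- unique(unlist(lapply(per_sample, `[[`, "sequence")))
  counts <- matrix(0L, nrow = length(all_seqs), ncol = length(samples),
                   dimnames = list(NULL, samples))
  posterior <- rep(0, length(all_seqs))
  for (s in samples) {
    ix <- match(per_sample[[s]]$sequence, all_seqs)
    counts[ix, s] <- per_sample[[s]]$count
    posterior[ix] <- pmax(posterior[ix], per_sample[[s]]$posterior)
  }
  o <- order(rowSums(counts), decreasing = TRUE)
  all_seqs <- all_seqs[o]; counts <- counts[o, , drop = FALSE]
  posterior <- posterior[o]
  ids <- sprintf("H%03d", seq_along(all_seqs))
  rownames(counts) <- ids
  haps <- data.frame(id = ids, sequence = all_seqs, posterior = posterior,
                     n_samples = as.integer(rowSums(counts > 0)),
                     total_reads = as.integer(rowSums(counts)),
                     flags = "", stringsAsFactors = FALSE)
  structure(list(haps = haps, counts = counts, ref_seq = ref_seq),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", nrow(x$haps), "candidates over",
      ncol(x$counts), "samples;", sum(x$counts), "reads\n")
  invisible(x)
}

## indel events of a sequence relative to a reference: data.frame
## (type, ref_pos, length, bases); ref_pos = first deleted reference
## position for deletions, reference position preceding the insertion for
## insertions.
indel_events <- function(seqs, ref_seq) {
  seqs <- as_seqs(seqs)
  empty <- data.frame(type = character(0), ref_pos = integer(0),
                      length = integer(0), bases = character(0))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unname(seqs)), Biostrings::DNAString(ref_seq),
    type = "global", substitutionMatrix = submat,
    gapOpening = 8, gapExtension = 1)
  ind <- Biostrings::indel(pa)
  dels <- Biostrings::deletion(ind)   # aligned-column coordinates
  inss <- Biostrings::insertion(ind)  # aligned-column coordinates
  out <- vector("list", length(seqs))
  names(out) <- names(seqs)
  for (z in seq_along(seqs)) {
    d <- dels[[z]]
    i <- inss[[z]]
    if (length(d) == 0 && length(i) == 0) { out[[z]] <- empty; next }
    ds <- BiocGenerics::start(d); dw <- BiocGenerics::width(d)
    is_ <- BiocGenerics::start(i); iw <- BiocGenerics::width(i)
    ins_before <- function(col) if (length(is_)) sum(iw[is_ < col]) else 0L
    del_before <- function(col) if (length(ds)) sum(dw[ds < col]) else 0L
    ev <- empty
    for (k in seq_along(ds)) {
      ev <- rbind(ev, data.frame(type = "del",
                                 ref_pos = ds[k] - ins_before(ds[k]),
                                 length = dw[k], bases = ""))
    }
    for (k in seq_along(is_)) {
      patpos <- is_[k] - del_before(is_[k])
      ev <- rbind(ev, data.frame(
        type = "ins",
        ref_pos = (is_[k] - ins_before(is_[k])) - 1L,
        length = iw[k],
        bases = substr(seqs[[z]], patpos, patpos + iw[k] - 1L)))
    }
    out[[z]] <- ev[order(ev$ref_pos), , drop = FALSE]
  }
  out
}

indel_key <- function(ev) {
  if (nrow(ev) == 0) return(character(0))
  paste(ev$type, ev$ref_pos, ev$length, ev$bases, sep = ":")
}

## extract the amplicon segment of full-length sequences: direct substring
## for sequences colinear with the reference (same length), anchored
## alignment otherwise (indel-bearing clones)
extract_amplicon_segments <- function(seqs, ref_full, amplicon) {
  seqs <- as_seqs(seqs)
  out <- character(length(seqs))
  names(out) <- names(seqs)
  same <- nchar(seqs) == nchar(ref_full)
  out[same] <- substr(seqs[same], amplicon[1], amplicon[2])
  if (any(!same)) {
    aln <- suppressWarnings(anchor_align(seqs[!same], c(ref = ref_full)))
    amp_cols <- which(!is.na(aln$col_ref) & aln$col_ref >= amplicon[1] &
                        aln$col_ref <= amplicon[2])
    for (id in aln$ids) {
      row <- aln$mat[id, amp_cols]
      out[id] <- paste(row[row != "-"], collapse = "")
    }
  }
  out[nchar(out) > 0]
}

## premature-stop codon positions of a candidate projected on the reference
## frame; returns integer vector of codon indices (relative to the mask)
stop_codon_positions <- function(seq, ref_seq, annot) {
  aln <- if (nchar(seq) == nchar(ref_seq)) {
    trivial_alignment(stats::setNames(seq, "x"), c(ref = ref_seq))
  } else {
    suppressWarnings(anchor_align(stats::setNames(seq, "x"), c(ref = ref_seq)))
  }
  mask <- build_site_mask(aln, annot)
  if (nrow(mask$codon_cols) == 0) return(integer(0))
  cods <- vapply(seq_len(nrow(mask$codon_cols)), function(k) {
    paste(aln$mat["x", mask$codon_cols[k, ]], collapse = "")
  }, "")
  which(!is.na(match(cods, all_codons())) &
          Biostrings::GENETIC_CODE[cods] == "*")
}

#' Apply the haplotype validation cascade
#'
#' Sequential evidence filters on called candidates:
#' \enumerate{
#'   \item drop candidates with posterior score at or below
#'     `thresholds$posterior`;
#'   \item drop candidates carrying a short (1-2 nt) indel relative to the
#'     reference, unless an identical indel (type, position, length, bases)
#'     occurs in a supplied clone;
#'   \item drop candidates whose projected CDS contains a premature stop
#'     codon, unless the same stop occurs in a clone (requires `annot`);
#'   \item drop candidates below `thresholds$min_freq` of the reads of every
#'     sample they occur in, unless their sequence matches a clone over the
#'     amplicon segment (PCS match) or they occur in two or more samples.
#' }
#' Without clones the indel/stop exceptions are unavailable but the cascade
#' still runs. Every drop is logged with the rule that fired.
#'
#' @param cands a `haplotype_set` from [call_candidates()]
#' @param clones clone sequences: list of [seq_record()]s or named character
#'   vector, full-length (extracted over `amplicon`) or amplicon-length
#' @param ref full locus reference (character); used to extract the clone
#'   amplicon segment when `amplicon` is given
#' @param amplicon optional `c(start, end)` of the sequenced segment on `ref`
#' @param annot optional [reference_annotation()] on the amplicon reference
#'   (enables the premature-stop rule)
#' @param thresholds list with `posterior` and `min_freq`
#' @return the accepted `haplotype_set`, with updated `flags` and attributes
#'   `log` (data.frame of drops) and `clone_matches`
#' @export
apply_validation_cascade <- function(cands, clones = NULL, ref = NULL,
                                     amplicon = NULL, annot = NULL,
                                     thresholds = list(posterior = 0.95,
                                                       min_freq = 0.15)) {
  stopifnot(inherits(cands, "haplotype_set"))
  thresholds <- utils::modifyList(list(posterior = 0.95, min_freq = 0.15),
                                  thresholds)
  haps <- cands$haps
  counts <- cands$counts
  ref_amp <- cands$ref_seq
  log_entries <- list()
  drop <- function(ids, rule, detail = "") {
    if (length(ids) == 0) return(invisible())
    log_entries[[length(log_entries) + 1L]] <<-
      data.frame(id = ids, rule = rule, detail = detail)
    keep <- !haps$id %in% ids
    haps <<- haps[keep, , drop = FALSE]
    counts <<- counts[keep, , drop = FALSE]
  }
  add_flag <- function(ids, flag) {
    ix <- haps$id %in% ids
    haps$flags[ix] <<- ifelse(haps$flags[ix] == "", flag,
                              paste(haps$flags[ix], flag, sep = ";"))
  }
  ## clone amplicon segments
  clone_segs <- character(0)
  clone_indel_keys <- character(0)
  clone_stop_pos <- integer(0)
  if (!is.null(clones) && length(clones) > 0) {
    cl <- as_seqs(clones)
    if (!is.null(amplicon) && !is.null(ref)) {
      ref_full <- unname(as_seqs(ref)[1])
      clone_segs <- unique(unname(extract_amplicon_segments(cl, ref_full,
                                                            amplicon)))
    } else {
      clone_segs <- unique(unname(cl))
    }
    ev <- indel_events(stats::setNames(clone_segs,
                                       paste0("cs", seq_along(clone_segs))),
                       ref_amp)
    clone_indel_keys <- unique(unlist(lapply(ev, indel_key)))
    if (!is.null(annot)) {
      clone_stop_pos <- unique(unlist(lapply(clone_segs, stop_codon_positions,
                                             ref_seq = ref_amp, annot = annot)))
    }
  }
  ## stage 1: posterior
  bad <- haps$id[haps$posterior <= thresholds$posterior]
  if (length(bad)) drop(bad, "posterior",
                        sprintf("<= %.2f", thresholds$posterior))
  ## frequency denominators: post-posterior-stage read totals per sample
  totals <- colSums(counts)
  if (any(colSums(cands$counts) > 0 & totals == 0)) {
    stop("a sample has zero reads after the posterior stage; frequencies undefined")
  }
  ## stage 2: short indels (candidates matching the reference length are
  ## treated as indel-free; indels change the candidate length)
  with_len_diff <- haps$id[nchar(haps$sequence) != nchar(ref_amp)]
  if (length(with_len_diff) > 0) {
    ev <- indel_events(stats::setNames(haps$sequence[haps$id %in% with_len_diff],
                                       with_len_diff), ref_amp)
    bad_ids <- character(0); bad_detail <- character(0)
    for (id in with_len_diff) {
      e <- ev[[id]]
      short <- e[e$length <= 2, , drop = FALSE]
      if (nrow(short) == 0) next
      keys <- indel_key(short)
      if (all(keys %in% clone_indel_keys)) {
        add_flag(id, "HAS_SHORT_INDEL")
        add_flag(id, "PCS_INDEL_MATCHED")
      } else {
        bad_ids <- c(bad_ids, id)
        bad_detail <- c(bad_detail, paste(setdiff(keys, clone_indel_keys),
                                          collapse = ","))
      }
    }
    drop(bad_ids, "short_indel", bad_detail)
  }
  ## stage 3: premature stops (requires annotation)
  if (!is.null(annot) && nrow(haps) > 0) {
    bad_ids <- character(0); bad_detail <- character(0)
    for (id in haps$id) {
      sp <- stop_codon_positions(haps$sequence[haps$id == id], ref_amp, annot)
      if (length(sp) == 0) next
      if (all(sp %in% clone_stop_pos)) {
        add_flag(id, "HAS_PREMATURE_STOP")
      } else {
        bad_ids <- c(bad_ids, id)
        bad_detail <- c(bad_detail, paste(sp, collapse = ","))
      }
    }
    drop(bad_ids, "premature_stop", bad_detail)
  }
  ## stage 4: within-sample frequency with PCS / multi-sample rescue
  if (nrow(haps) > 0) {
    freq <- sweep(counts, 2, pmax(totals, 1), "/")
    pcs_matched <- haps$sequence %in% clone_segs
    add_flag(haps$id[pcs_matched], "PCS_MATCHED")
    add_flag(haps$id[haps$n_samples >= 2], "MULTI_SAMPLE")
    max_freq <- apply(freq, 1, max)
    above <- max_freq >= thresholds$min_freq
    rescued <- !above & (pcs_matched | haps$n_samples >= 2)
    add_flag(haps$id[rescued], "WEAKLY_SUPPORTED")
    bad <- !above & !rescued
    drop(haps$id[bad], "frequency",
         sprintf("max freq %.3f < %.2f", max_freq[bad], thresholds$min_freq))
  }
  out <- structure(list(haps = haps, counts = counts, ref_seq = ref_amp),
                   class = "haplotype_set")
  attr(out, "log") <- if (length(log_entries) > 0) {
    do.call(rbind, log_entries)
  } else {
    data.frame(id = character(0), rule = character(0), detail = character(0))
  }
  attr(out, "clone_matches") <- clone_segs
  out
}

#' Compare mutation profiles of weakly and strongly supported haplotypes
#'
#' Strong haplotypes are those observed in two or more independent samples or
#' matched by both clone (PCS) and read (MPS) evidence; weak haplotypes are
#' the rest. For each weak haplotype the distance to its nearest strong
#' haplotype is computed; for each strong haplotype, the distance to its
#' nearest other strong haplotype. Similar means indicate that weakly
#' supported haplotypes are not error derivatives (errors would sit closer to
#' a strong parent).
#'
#' @param haps a `haplotype_set` (after the cascade; flags populated)
#' @return list with `mean_weak`, `se_weak`, `n_weak`, `mean_strong`,
#'   `se_strong`, `n_strong`, `p_value` (two-sided Welch), `verdict`
#' @export
mutation_profile_statistic <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  h <- haps$haps
  strong <- h$n_samples >= 2 | grepl("PCS_MATCHED", h$flags)
  if (sum(strong) < 2) {
    return(list(mean_weak = NA_real_, se_weak = NA_real_, n_weak = sum(!strong),
                mean_strong = NA_real_, se_strong = NA_real_,
                n_strong = sum(strong), p_value = NA_real_,
                verdict = "undefined: fewer than 2 strong haplotypes"))
  }
  ss <- h$sequence[strong]
  ws <- h$sequence[!strong]
  dmat_ss <- utils::adist(ss, ss)
  diag(dmat_ss) <- NA
  d_strong <- apply(dmat_ss, 1, min, na.rm = TRUE)
  d_weak <- if (length(ws) > 0) {
    apply(utils::adist(ws, ss), 1, min)
  } else numeric(0)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  p <- if (length(d_weak) > 1 && length(d_strong) > 1 &&
           (stats::sd(d_weak) > 0 || stats::sd(d_strong) > 0)) {
    stats::t.test(d_weak, d_strong)$p.value
  } else NA_real_
  verdict <- if (length(d_weak) == 0) {
    "no weak haplotypes"
  } else if (!is.na(p) && p < 0.05 && mean(d_weak) < mean(d_strong)) {
    "weak haplotypes closer to strong ones than expected: possible artefacts"
  } else {
    "mutation profiles comparable: consistent with true alleles"
  }
  list(mean_weak = if (length(d_weak)) mean(d_weak) else NA_real_,
       se_weak = se(d_weak), n_weak = length(d_weak),
       mean_strong = mean(d_strong), se_strong = se(d_strong),
       n_strong = length(d_strong), p_value = p, verdict = verdict)
}

#' Build the evidence registry joining clone (PCS) and read (MPS) support
#'
#' Haplotype identity between evidence streams is evaluated over the shared
#' (amplicon) segment: a clone supports an MPS haplotype when its amplicon
#' segment is identical to the haplotype sequence.
#'
#' @param haps accepted `haplotype_set`
#' @param clones clone sequences (see [apply_validation_cascade()])
#' @param ref full locus reference
#' @param amplicon `c(start, end)` of the amplicon on `ref`
#' @return data.frame: haplotype id, segment sequence, read_count,
#'   clone_count, n_samples, sources
#' @export
build_evidence_registry <- function(haps, clones = NULL, ref = NULL,
                                    amplicon = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  clone_seg <- character(0)
  if (!is.null(clones) && length(clones) > 0) {
    cl <- as_seqs(clones)
    if (!is.null(amplicon) && !is.null(ref)) {
      ref_full <- unname(as_seqs(ref)[1])
      clone_seg <- unname(extract_amplicon_segments(cl, ref_full, amplicon))
    } else {
      clone_seg <- unname(cl)
    }
  }
  reg <- data.frame(id = haps$haps$id, sequence = haps$haps$sequence,
                    read_count = haps$haps$total_reads,
                    clone_count = vapply(haps$haps$sequence,
                                         function(s) sum(clone_seg == s), 0L),
                    n_samples = haps$haps$n_samples)
  ## clones not matching any MPS haplotype get PCS-only rows
  extra <- setdiff(unique(clone_seg), haps$haps$sequence)
  if (length(extra) > 0) {
    reg <- rbind(reg, data.frame(
      id = sprintf("PCS%03d", seq_along(extra)), sequence = extra,
      read_count = 0L,
      clone_count = vapply(extra, function(s) sum(clone_seg == s), 0L),
      n_samples = 0L))
  }
  reg$sources <- ifelse(reg$read_count > 0 & reg$clone_count > 0, "MPS+PCS",
                        ifelse(reg$read_count > 0, "MPS", "PCS"))
  rownames(reg) <- NULL
  reg
}

#' Correlation between clone and read support across haplotypes
#'
#' Ordinary least squares of clone count on read count over registry entries
#' carrying both kinds of evidence; returns the coefficient of determination.
#'
#' @param registry data.frame from [build_evidence_registry()] (needs columns
#'   `clone_count` and `read_count`)
#' @return R squared; `NA` with a warning for fewer than 3 usable points, 0
#'   when the clone counts have zero variance
#' @export
correlate_clone_read_support <- function(registry) {
  use <- !is.na(registry$clone_count) & !is.na(registry$read_count)
  d <- registry[use, ]
  if (nrow(d) < 3) {
    warning("fewer than 3 haplotypes with both evidence types; R^2 undefined")
    return(NA_real_)
  }
  if (stats::var(d$clone_count) == 0) return(0)
  summary(stats::lm(clone_count ~ read_count, data = d))$r.squared
}
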