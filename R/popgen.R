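## Codon-aware population genetics: distance corrections, nucleotide
## diversity at silent/replacement sites, Tajima's D, haplotype diversity,
## divergence between groups, and the McDonald-Kreitman test.
##
## Conventions: complete deletion (any column carrying a gap or non-ACGT
## base in any analysed sequence is removed, codons dropped whole);
## unweighted Nei-Gojobori counting for diversity/divergence/MK; the
## ts/tv-weighted scheme is used for phylogenetic synonymous distances.

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) ln(1 - 4p/3)` for an observed proportion of differences `p`.
#'
#' @param p observed proportion of differing sites, `0 <= p < 0.75`
#' @return corrected distance; `NA` with a warning at saturation (`p >= 0.75`)
#' @export
jc_correct <- function(p) {
  out <- ifelse(p < 0 | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  if (anyNA(out) && any(p >= 0.75, na.rm = TRUE)) {
    warning("p >= 0.75: distance saturated, reported as NA")
  }
  out
}

#' Gamma-corrected Jukes-Cantor distance
#'
#' Allows rate variation across sites with gamma shape `a`:
#' `d = (3/4) a ((1 - 4p/3)^(-1/a) - 1)`; `a = 1` reduces to
#' `d = p / (1 - 4p/3)`.
#'
#' @inheritParams jc_correct
#' @param a gamma shape parameter (> 0)
#' @export
gamma_correct <- function(p, a = 1) {
  stopifnot(a > 0)
  out <- ifelse(p < 0 | p >= 0.75, NA_real_,
                0.75 * a * ((1 - 4 * p / 3)^(-1 / a) - 1))
  if (anyNA(out) && any(p >= 0.75, na.rm = TRUE)) {
    warning("p >= 0.75: distance saturated, reported as NA")
  }
  out
}

#' Haplotype diversity (sample-size corrected)
#'
#' `Hd = n/(n-1) (1 - sum (c_i/n)^2)` for haplotype counts `c_i`,
#' `n = sum c_i`.
#'
#' @param counts integer vector of haplotype counts
#' @return Hd in `[0, 1]`; `NA` when `n < 2`
#' @examples
#' haplotype_diversity(c(2, rep(1, 14)))  # 0.9917 -> prints as 0.99
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

## ---- internal: complete-deletion data preparation -------------------------

## Restrict an alignment+mask to usable material for a set of members:
## noncoding columns where all members have ACGT, and codons whose three
## columns are clean and whose member codons are all sense codons.
popgen_data <- function(aln, mask, ids = NULL) {
  mat <- aln$mat
  if (!is.null(ids)) mat <- mat[ids, , drop = FALSE]
  n <- nrow(mat)
  ok_col <- apply(mat, 2, function(cc) all(cc %in% BASES))
  nc_cols <- mask$noncoding_cols[ok_col[mask$noncoding_cols]]
  codon_idx <- matrix(integer(0), nrow = n, ncol = 0)
  coding_cols <- integer(0)
  if (nrow(mask$codon_cols) > 0) {
    keep <- vapply(seq_len(nrow(mask$codon_cols)),
                   function(j) all(ok_col[mask$codon_cols[j, ]]), TRUE)
    cols <- mask$codon_cols[keep, , drop = FALSE]
    if (nrow(cols) > 0) {
      cidx <- matrix(NA_integer_, n, nrow(cols))
      for (j in seq_len(nrow(cols))) {
        cidx[, j] <- codon_to_index(
          paste0(mat[, cols[j, 1]], mat[, cols[j, 2]], mat[, cols[j, 3]]))
      }
      stopc <- unname(Biostrings::GENETIC_CODE[all_codons()] == "*")
      ok_codon <- !apply(cidx, 2, function(z) any(stopc[z]))
      codon_idx <- cidx[, ok_codon, drop = FALSE]
      cols <- cols[ok_codon, , drop = FALSE]
      coding_cols <- as.vector(cols)
    }
  }
  list(mat = mat, n = n, ids = rownames(mat), nc_cols = nc_cols,
       codon_idx = codon_idx, all_cols = sort(c(nc_cols, coding_cols)))
}

## per-pair proportions of difference at silent and nonsynonymous sites
pair_class_p <- function(pd, i, j) {
  tabs <- ng_diff_tables()
  sU <- ng_site_table("unweighted")
  ncd <- if (length(pd$nc_cols)) {
    sum(pd$mat[i, pd$nc_cols] != pd$mat[j, pd$nc_cols])
  } else 0
  k <- ncol(pd$codon_idx)
  if (k > 0) {
    ia <- pd$codon_idx[i, ]
    ib <- pd$codon_idx[j, ]
    Sd <- sum(tabs$Sd[cbind(ia, ib)])
    Nd <- sum(tabs$Nd[cbind(ia, ib)])
    s_sites <- sum((sU[ia] + sU[ib]) / 2)
    n_sites <- 3 * k - s_sites
  } else {
    Sd <- 0; Nd <- 0; s_sites <- 0; n_sites <- 0
  }
  sil_sites <- length(pd$nc_cols) + s_sites
  list(p_sil = if (sil_sites > 0) (ncd + Sd) / sil_sites else NA_real_,
       p_nonsyn = if (n_sites > 0) Nd / n_sites else NA_real_,
       sil_sites = sil_sites, nonsyn_sites = n_sites)
}

#' Nucleotide diversity at silent and nonsynonymous sites
#'
#' Nei's pi computed separately for the silent pool (noncoding columns plus
#' synonymous coding positions, unweighted Nei-Gojobori site fractions) and
#' for nonsynonymous positions. Proportions are Jukes-Cantor corrected per
#' pair, then averaged over all pairs.
#'
#' @param aln an `anchored_alignment` (or [trivial_alignment()])
#' @param mask a [build_site_mask()] result
#' @param ids optional subset of member ids
#' @return list with `pi_silent`, `pi_nonsyn` and `sites_used`
#' @export
pi_by_class <- function(aln, mask, ids = NULL) {
  pd <- popgen_data(aln, mask, ids)
  if (pd$n < 2) stop("need at least 2 sequences")
  ps <- c(); pn <- c()
  for (i in seq_len(pd$n - 1)) for (j in seq.int(i + 1, pd$n)) {
    pr <- pair_class_p(pd, i, j)
    ps <- c(ps, pr$p_sil)
    pn <- c(pn, pr$p_nonsyn)
  }
  sites <- pair_class_p(pd, 1, if (pd$n > 1) 2 else 1)
  list(pi_silent = mean(jc_correct(ps), na.rm = TRUE),
       pi_nonsyn = mean(jc_correct(pn), na.rm = TRUE),
       sites_used = list(silent_sites = sites$sil_sites,
                         nonsyn_sites = sites$nonsyn_sites,
                         noncoding_sites = length(pd$nc_cols)))
}

#' Tajima's D
#'
#' Standardized difference between the mean-pairwise-difference and the
#' segregating-sites estimators of theta (Tajima 1989), computed over all
#' usable (non-excluded, complete-deletion) columns.
#'
#' @inheritParams pi_by_class
#' @return list with `D`, `S`, `k_hat` and `n`; `D` is `NA` when `S = 0`
#' @export
tajimas_d <- function(aln, mask = NULL, ids = NULL) {
  if (is.null(mask)) {
    mat <- aln$mat
    if (!is.null(ids)) mat <- mat[ids, , drop = FALSE]
    use <- which(apply(mat, 2, function(cc) all(cc %in% BASES)))
  } else {
    pd <- popgen_data(aln, mask, ids)
    mat <- pd$mat
    use <- pd$all_cols
  }
  n <- nrow(mat)
  if (n < 4) stop("Tajima's D requires n >= 4 sequences")
  sub <- mat[, use, drop = FALSE]
  seg <- apply(sub, 2, function(cc) length(unique(cc)) > 1)
  S <- sum(seg)
  if (S == 0) {
    return(list(D = NA_real_, S = 0L, k_hat = 0, n = n))
  }
  k <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    k <- k + sum(sub[i, ] != sub[j, ])
    np <- np + 1
  }
  k_hat <- k / np
  i1 <- seq_len(n - 1)
  a1 <- sum(1 / i1)
  a2 <- sum(1 / i1^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, S = as.integer(S), k_hat = k_hat, n = n)
}

#' Diversity summary for a group of sequences
#'
#' Bundles n, segregating sites, haplotype diversity, silent/nonsynonymous
#' nucleotide diversity and Tajima's D for one gene family.
#'
#' @inheritParams pi_by_class
#' @return an object of class `diversity_summary`
#' @export
diversity_summary <- function(aln, mask, ids = NULL) {
  pd <- popgen_data(aln, mask, ids)
  pi <- pi_by_class(aln, mask, ids)
  sub <- pd$mat[, pd$all_cols, drop = FALSE]
  hapc <- table(apply(sub, 1, paste, collapse = ""))
  S <- sum(apply(sub, 2, function(cc) length(unique(cc)) > 1))
  td <- if (pd$n >= 4 && S > 0) tajimas_d(aln, mask, ids)$D else NA_real_
  structure(list(n = pd$n, S = as.integer(S),
                 Hd = haplotype_diversity(as.integer(hapc)),
                 pi_silent = pi$pi_silent, pi_nonsyn = pi$pi_nonsyn,
                 tajima_D = td, sites_used = pi$sites_used),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("n=%d  S=%d  Hd=%.3f  pi_sil=%.4f  pi_nonsyn=%.4f  Tajima D=%s\n",
              x$n, x$S, x$Hd, x$pi_silent, x$pi_nonsyn,
              ifelse(is.na(x$tajima_D), "NA", sprintf("%.3f", x$tajima_D))))
  invisible(x)
}

#' Divergence between two groups (Ka, Ks)
#'
#' Mean over all between-group pairs of Jukes-Cantor corrected per-class
#' distances: Ks from the silent pool (noncoding + synonymous), Ka from
#' nonsynonymous positions. Saturated pairs are excluded from the mean with
#' a warning.
#'
#' @inheritParams pi_by_class
#' @param group_a,group_b member id vectors
#' @return an object of class `divergence_summary` with `Ka`, `Ks`,
#'   `Ka_over_Ks`
#' @export
divergence <- function(aln, mask, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  pd <- popgen_data(aln, mask, c(group_a, group_b))
  ia <- match(group_a, pd$ids)
  ib <- match(group_b, pd$ids)
  ks <- c(); ka <- c()
  for (i in ia) for (j in ib) {
    pr <- pair_class_p(pd, i, j)
    ks <- c(ks, jc_correct(pr$p_sil))
    ka <- c(ka, jc_correct(pr$p_nonsyn))
  }
  if (anyNA(ks) || anyNA(ka)) warning("saturated pairs excluded from K means")
  sites <- pair_class_p(pd, ia[1], ib[1])
  Ks <- mean(ks, na.rm = TRUE)
  Ka <- mean(ka, na.rm = TRUE)
  structure(list(Ka = Ka, Ks = Ks,
                 Ka_over_Ks = if (!is.na(Ks) && Ks > 0) Ka / Ks else NA_real_,
                 groups = c(a = paste(group_a, collapse = ","),
                            b = paste(group_b, collapse = ",")),
                 sites_used = list(silent_sites = sites$sil_sites,
                                   nonsyn_sites = sites$nonsyn_sites)),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Ka=%.4f  Ks=%.4f  Ka/Ks=%s\n", x$Ka, x$Ks,
              ifelse(is.na(x$Ka_over_Ks), "NA", sprintf("%.3f", x$Ka_over_Ks))))
  invisible(x)
}

#' McDonald-Kreitman test
#'
#' Contrasts silent vs replacement changes that are polymorphic within the
#' ingroup against those fixed between ingroup and outgroup. The silent pool
#' includes noncoding positions. Sites segregating in the ingroup count once
#' as polymorphic even when also divergent. Fixed differences are classified
#' by Nei-Gojobori pathway averaging between the ingroup and outgroup
#' majority codons (restricted to the fixed positions); polymorphic changes
#' are classified single-site in the ingroup majority-codon context.
#' Fractional counts are rounded to the nearest integer per cell, then a
#' two-tailed Fisher's exact test is applied.
#'
#' @inheritParams pi_by_class
#' @param ingroup,outgroup member id vectors (ingroup n >= 2, outgroup n >= 1)
#' @return an object of class `mk_result` with `Pn`, `Ps`, `Dn`, `Ds`,
#'   `fisher_p`, `NI`
#' @export
mk_test <- function(aln, mask, ingroup, outgroup) {
  if (length(ingroup) < 2) stop("ingroup must have >= 2 sequences")
  if (length(outgroup) < 1) stop("outgroup must have >= 1 sequence")
  pd <- popgen_data(aln, mask, c(ingroup, outgroup))
  ii <- match(ingroup, pd$ids)
  io <- match(outgroup, pd$ids)
  Pn <- 0; Ps <- 0; Dn <- 0; Ds <- 0
  ## noncoding sites -> silent pool
  for (cc in pd$nc_cols) {
    si <- unique(pd$mat[ii, cc])
    so <- unique(pd$mat[io, cc])
    if (length(si) > 1) {
      Ps <- Ps + length(si) - 1
    } else if (length(so) == 1 && si != so) {
      Ds <- Ds + 1
    }
  }
  ## coding codons
  tabs <- ng_diff_tables()
  cods <- all_codons()
  stopc <- unname(Biostrings::GENETIC_CODE[cods] == "*")
  for (j in seq_len(ncol(pd$codon_idx))) {
    ci <- pd$codon_idx[ii, j]
    co <- pd$codon_idx[io, j]
    maj <- as.integer(names(which.max(table(ci))))
    maj_cod <- cods[maj]
    in_states <- lapply(1:3, function(p) unique(substr(cods[ci], p, p)))
    out_states <- lapply(1:3, function(p) unique(substr(cods[co], p, p)))
    ## fixed positions: monomorphic both sides, different states
    fixed <- which(vapply(1:3, function(p) {
      length(in_states[[p]]) == 1 && length(out_states[[p]]) == 1 &&
        in_states[[p]] != out_states[[p]]
    }, TRUE))
    if (length(fixed) > 0) {
      b <- maj_cod
      for (p in fixed) substr(b, p, p) <- out_states[[p]]
      bi <- codon_to_index(b)
      if (stopc[bi] || stopc[maj]) {
        Dn <- Dn + length(fixed)
      } else {
        Ds <- Ds + tabs$Sd[maj, bi]
        Dn <- Dn + tabs$Nd[maj, bi]
      }
    }
    ## polymorphic positions in the ingroup, majority-codon context
    for (p in 1:3) {
      states <- in_states[[p]]
      if (length(states) < 2) next
      for (x in setdiff(states, substr(maj_cod, p, p))) {
        mut <- maj_cod
        substr(mut, p, p) <- x
        mi <- codon_to_index(mut)
        if (stopc[mi] || codon_aa(mut) != codon_aa(maj_cod)) {
          Pn <- Pn + 1
        } else {
          Ps <- Ps + 1
        }
      }
    }
  }
  tab <- matrix(round(c(Pn, Dn, Ps, Ds)), nrow = 2,
                dimnames = list(c("polymorphic", "fixed"),
                                c("nonsynonymous", "silent")))
  fp <- if (sum(tab) > 0) stats::fisher.test(tab)$p.value else NA_real_
  NI <- if (tab["polymorphic", "silent"] > 0 && tab["fixed", "nonsynonymous"] > 0) {
    (tab["polymorphic", "nonsynonymous"] / tab["polymorphic", "silent"]) /
      (tab["fixed", "nonsynonymous"] / tab["fixed", "silent"])
  } else NA_real_
  structure(list(Pn = tab[1, 1], Ps = tab[1, 2], Dn = tab[2, 1], Ds = tab[2, 2],
                 fisher_p = fp, NI = NI, table = tab),
            class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  cat("McDonald-Kreitman 2x2:\n")
  print(x$table)
  cat(sprintf("Fisher two-tailed p=%s  NI=%s\n",
              ifelse(is.na(x$fisher_p), "NA", format(x$fisher_p, digits = 3)),
              ifelse(is.na(x$NI), "NA", format(x$NI, digits = 3))))
  invisible(x)
}
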