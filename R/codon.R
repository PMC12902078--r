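## Codon-level machinery: genetic code access, transition/transversion
## classification, and Nei-Gojobori synonymous/nonsynonymous counting.

.lucfam_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' All 64 codons in fixed lexicographic order
#' @return character vector of 64 codons
#' @keywords internal
all_codons <- function() {
  if (is.null(.lucfam_cache$codons)) {
    g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                     stringsAsFactors = FALSE)
    .lucfam_cache$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .lucfam_cache$codons
}

#' Translate a codon to its amino acid (one-letter, "*" for stop)
#' @param codon character scalar, one of the 64 DNA codons
#' @keywords internal
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

is_stop_codon <- function(codon) {
  codon_aa(codon) == "*"
}

sense_codons <- function() {
  cods <- all_codons()
  cods[Biostrings::GENETIC_CODE[cods] != "*"]
}

#' Is a single-base change a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine (C<->T)
#' exchanges; all other exchanges are transversions.
#' @param a,b single bases
#' @return logical
#' @export
is_transition <- function(a, b) {
  purine <- c("A", "G")
  (a %in% purine) == (b %in% purine) & a != b
}

#' Nei-Gojobori potential synonymous/nonsynonymous site counts for one codon
#'
#' Counts the fraction of the three possible single-base changes at each codon
#' position that are synonymous, summed over positions. Under the unweighted
#' scheme every change has weight 1; under the weighted ("modified"
#' Nei-Gojobori) scheme transitions receive weight `R` and transversions
#' weight 1, reflecting a transition/transversion mutation bias. Changes that
#' create a stop codon count as nonsynonymous. For every sense codon
#' `s + n == 3`.
#'
#' @param codon one of the 61 sense codons
#' @param scheme "unweighted" or "weighted"
#' @param R transition/transversion weight used by the weighted scheme
#' @return named numeric vector `c(s = ..., n = ...)`
#' @examples
#' ng_site_counts("TTT")               # s = 1/3
#' ng_site_counts("TTT", "weighted")   # s = 1/2
#' @export
ng_site_counts <- function(codon, scheme = c("unweighted", "weighted"), R = 2) {
  scheme <- match.arg(scheme)
  if (!codon %in% all_codons()) stop("not a DNA codon: ", codon)
  if (is_stop_codon(codon)) stop("stop codon has no site counts: ", codon)
  aa0 <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    w_syn <- 0
    w_tot <- 0
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      w <- if (scheme == "weighted" && is_transition(substr(codon, pos, pos), b)) R else 1
      w_tot <- w_tot + w
      ## changes creating stops are nonsynonymous by convention
      if (!is_stop_codon(mut) && codon_aa(mut) == aa0) w_syn <- w_syn + w
    }
    s <- s + w_syn / w_tot
  }
  c(s = s, n = 3 - s)
}

## small permutation enumerator (k <= 3 here)
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Nei-Gojobori synonymous/nonsynonymous difference counts between two codons
#'
#' All mutational pathways between the codons (orderings of the differing
#' positions) are enumerated; pathways passing through a stop codon are
#' discarded and the synonymous/nonsynonymous step counts are averaged
#' equally over the surviving pathways. If every pathway passes through a
#' stop, all differences are counted as nonsynonymous. Always
#' `Sd + Nd ==` number of differing positions.
#'
#' @param codon_a,codon_b sense codons
#' @return named numeric vector `c(Sd = ..., Nd = ...)`
#' @examples
#' ng_diff_counts("GGG", "GGA")  # Sd = 1 (Gly/Gly)
#' ng_diff_counts("TTT", "GTA")  # Sd = 0.5, Nd = 1.5
#' @export
ng_diff_counts <- function(codon_a, codon_b) {
  for (cd in c(codon_a, codon_b)) {
    if (!cd %in% all_codons()) stop("not a DNA codon: ", cd)
    if (is_stop_codon(cd)) stop("stop codon not allowed: ", cd)
  }
  d <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(d)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  syn_tot <- 0
  n_valid <- 0
  for (ord in .perms(d)) {
    cur <- codon_a
    syn <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop_codon(nxt)) { ok <- FALSE; break }
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1
      cur <- nxt
    }
    if (ok) { syn_tot <- syn_tot + syn; n_valid <- n_valid + 1 }
  }
  if (n_valid == 0) return(c(Sd = 0, Nd = k))
  sd <- syn_tot / n_valid
  c(Sd = sd, Nd = k - sd)
}

## ---- cached lookup tables over the 64-codon index space ------------------
## Codon index = position in all_codons(); entries involving stop codons are NA.

codon_to_index <- function(codons) {
  match(codons, all_codons())
}

ng_site_table <- function(scheme = "unweighted", R = 2) {
  key <- paste0("sites_", scheme, "_", R)
  if (is.null(.lucfam_cache[[key]])) {
    cods <- all_codons()
    s <- rep(NA_real_, 64)
    for (i in seq_along(cods)) {
      if (!is_stop_codon(cods[i])) s[i] <- ng_site_counts(cods[i], scheme, R)[["s"]]
    }
    .lucfam_cache[[key]] <- s
  }
  .lucfam_cache[[key]]
}

ng_diff_tables <- function() {
  if (is.null(.lucfam_cache$diff_Sd)) {
    cods <- all_codons()
    sense <- which(Biostrings::GENETIC_CODE[cods] != "*")
    Sd <- matrix(NA_real_, 64, 64)
    Nd <- matrix(NA_real_, 64, 64)
    for (i in sense) for (j in sense) {
      if (i == j) { Sd[i, j] <- 0; Nd[i, j] <- 0; next }
      if (j < i) { Sd[i, j] <- Sd[j, i]; Nd[i, j] <- Nd[j, i]; next }
      dc <- ng_diff_counts(cods[i], cods[j])
      Sd[i, j] <- dc[["Sd"]]
      Nd[i, j] <- dc[["Nd"]]
    }
    .lucfam_cache$diff_Sd <- Sd
    .lucfam_cache$diff_Nd <- Nd
  }
  list(Sd = .lucfam_cache$diff_Sd, Nd = .lucfam_cache$diff_Nd)
}
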