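## Gene-family assignment via diagnostic sites, and mosaic (recombinant)
## allele detection by a single-breakpoint minimum-discordance scan.

#' Find diagnostic sites between two gene families
#'
#' A diagnostic site is an alignment column fixed within each family but
#' different between them. Columns where any sequence carries a gap or
#' ambiguous base are skipped.
#'
#' @param seqs named character vector of aligned, equal-length sequences
#' @param families factor/character of family labels, parallel to `seqs`;
#'   exactly two levels
#' @return an object of class `diagnostic_sites`: data.frame with `column`,
#'   `allele_a`, `allele_b`, plus attributes `family_a`, `family_b`
#' @export
find_diagnostic_sites <- function(seqs, families) {
  seqs <- as_seqs(seqs)
  families <- as.character(families)
  stopifnot(length(seqs) == length(families))
  levs <- unique(families)
  if (length(levs) != 2) stop("exactly two families required")
  for (lv in levs) {
    if (sum(families == lv) < 2) {
      warning("family ", lv, " has < 2 sequences; 'fixed' means unanimous")
    }
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must be aligned to equal length")
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L,
                byrow = TRUE)
  a <- mat[families == levs[1], , drop = FALSE]
  b <- mat[families == levs[2], , drop = FALSE]
  clean <- apply(mat, 2, function(cc) all(cc %in% BASES))
  fixed_a <- apply(a, 2, function(cc) length(unique(cc)) == 1)
  fixed_b <- apply(b, 2, function(cc) length(unique(cc)) == 1)
  diag_col <- which(clean & fixed_a & fixed_b & a[1, ] != b[1, ])
  out <- data.frame(column = diag_col,
                    allele_a = a[1, diag_col],
                    allele_b = b[1, diag_col])
  structure(out, class = c("diagnostic_sites", "data.frame"),
            family_a = levs[1], family_b = levs[2])
}

## per-site family votes of a sequence over the diagnostic columns:
## "A"/"B"/NA (not covered or third allele)
site_votes <- function(seq, diag) {
  ch <- seq_chars(seq)
  v <- rep(NA_character_, nrow(diag))
  cov <- diag$column <= length(ch)
  at <- ch[diag$column[cov]]
  v[cov] <- ifelse(at == diag$allele_a[cov], "A",
                   ifelse(at == diag$allele_b[cov], "B", NA))
  v
}

#' Assign a haplotype to a gene family by diagnostic-site votes
#'
#' Each covered diagnostic column votes for one family; the label is the
#' majority family when its vote fraction reaches `min_score`, otherwise
#' "ambiguous" (exact ties are always ambiguous). With no informative column
#' covered the result is "unassigned".
#'
#' @param seq haplotype sequence aligned on the diagnostic columns
#' @param diag a [find_diagnostic_sites()] result
#' @param min_score vote fraction below which the call is "ambiguous"
#' @return list with `label`, `score`, `votes` (per-site label vector)
#' @export
assign_family <- function(seq, diag, min_score = 0.8) {
  seq <- unname(as_seqs(seq)[1])
  v <- site_votes(seq, diag)
  nA <- sum(v == "A", na.rm = TRUE)
  nB <- sum(v == "B", na.rm = TRUE)
  if (nA + nB == 0) {
    return(list(label = "unassigned", score = NA_real_, votes = v))
  }
  score <- max(nA, nB) / (nA + nB)
  label <- if (nA == nB || score < min_score) "ambiguous" else
    if (nA > nB) attr(diag, "family_a") else attr(diag, "family_b")
  list(label = label, score = score, votes = v)
}

#' Detect a mosaic (recombinant) haplotype
#'
#' Scans all single breakpoints between adjacent covered diagnostic sites,
#' labelling the left and right segments independently with the family that
#' minimizes discordance. The haplotype is called mosaic when the two-segment
#' labelling removes at least `min_gain` discordant sites compared with the
#' best single-family labelling.
#'
#' @inheritParams assign_family
#' @param min_gain minimum discordance reduction to call a mosaic
#' @return an object of class `mosaic_call`: `is_mosaic`,
#'   `breakpoint_interval` (columns of the adjacent diagnostic sites
#'   flanking the inferred breakpoint), `segment_labels`,
#'   `discordance_single`, `discordance_two_segment`, `evaluable`
#' @export
detect_mosaic <- function(seq, diag, min_gain = 3) {
  seq <- unname(as_seqs(seq)[1])
  v <- site_votes(seq, diag)
  cov <- which(!is.na(v))
  if (length(cov) < 4) {
    return(structure(list(is_mosaic = FALSE, breakpoint_interval = NULL,
                          segment_labels = NULL,
                          discordance_single = NA_integer_,
                          discordance_two_segment = NA_integer_,
                          evaluable = FALSE),
                     class = "mosaic_call"))
  }
  lab <- v[cov]
  cols <- diag$column[cov]
  m <- length(lab)
  isA <- lab == "A"
  disc_single <- min(sum(!isA), sum(isA))
  ## prefix counts of A-votes; two-segment discordance for breakpoint after
  ## site i with left label L and right label R
  cumA <- cumsum(isA)
  best <- list(d = Inf, i = NA, labs = NULL)
  for (i in seq_len(m - 1)) {
    leftA <- cumA[i]; leftB <- i - leftA
    rightA <- cumA[m] - leftA; rightB <- (m - i) - rightA
    for (ll in c("A", "B")) for (rl in c("A", "B")) {
      d <- (if (ll == "A") leftB else leftA) +
           (if (rl == "A") rightB else rightA)
      if (d < best$d) best <- list(d = d, i = i, labs = c(ll, rl))
    }
  }
  fam <- c(A = attr(diag, "family_a"), B = attr(diag, "family_b"))
  gain <- disc_single - best$d
  structure(list(is_mosaic = gain >= min_gain && best$labs[1] != best$labs[2],
                 breakpoint_interval = c(cols[best$i], cols[best$i + 1]),
                 segment_labels = unname(fam[best$labs]),
                 discordance_single = as.integer(disc_single),
                 discordance_two_segment = as.integer(best$d),
                 evaluable = TRUE),
            class = "mosaic_call")
}

#' @export
print.mosaic_call <- function(x, ...) {
  if (!x$evaluable) {
    cat("Mosaic call: not evaluable (< 4 diagnostic sites covered)\n")
  } else {
    cat(sprintf("Mosaic call: %s (discordance %d -> %d%s)\n",
                if (x$is_mosaic) "MOSAIC" else "not mosaic",
                x$discordance_single, x$discordance_two_segment,
                if (x$is_mosaic) sprintf("; breakpoint in columns [%d, %d], %s|%s",
                                         x$breakpoint_interval[1],
                                         x$breakpoint_interval[2],
                                         x$segment_labels[1],
                                         x$segment_labels[2]) else ""))
  }
  invisible(x)
}

#' Variants shared exclusively by a group of haplotypes
#'
#' Columns where every group member carries the same allele and no
#' background haplotype carries it — the signature of variants inherited
#' from a single ancestral (e.g. recombination) event.
#'
#' @param group,background named character vectors of aligned sequences
#' @return integer vector of columns (with the shared allele as names)
#' @export
find_exclusive_shared_variants <- function(group, background) {
  group <- as_seqs(group)
  background <- as_seqs(background)
  if (length(group) == 0 || length(background) == 0) {
    stop("group and background must be non-empty")
  }
  L <- unique(nchar(c(group, background)))
  if (length(L) != 1) stop("sequences must be aligned to equal length")
  g <- matrix(unlist(strsplit(group, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  b <- matrix(unlist(strsplit(background, "", fixed = TRUE)), ncol = L,
              byrow = TRUE)
  hit <- vapply(seq_len(L), function(j) {
    al <- unique(g[, j])
    length(al) == 1 && al %in% BASES && !any(b[, j] == al)
  }, TRUE)
  out <- which(hit)
  names(out) <- g[1, out]
  out
}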