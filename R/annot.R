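## Annotation projection onto haplotypes and enumeration of ORF-preserving
## alternative splice motifs (GT donors / AG acceptors).

#' Project reference exon/intron structure onto a haplotype
#'
#' Maps the reference exon boundaries through the alignment columns to
#' haplotype coordinates. A boundary falling inside a deletion snaps to the
#' nearest retained haplotype position toward the exon interior; an exon
#' fully deleted in the haplotype is reported empty and flagged. The
#' presence of the canonical GT/AG dinucleotides at each projected intron
#' end is verified.
#'
#' @param aln an `anchored_alignment` containing the haplotype
#' @param annot a [reference_annotation()] on the alignment's reference
#' @param id member id of the haplotype in `aln`
#' @return list with `exons` (data.frame: exon, start, end, deleted) and
#'   `introns` (data.frame: intron, start, end, donor_gt, acceptor_ag),
#'   both in haplotype coordinates
#' @export
project_annotation <- function(aln, annot, id) {
  row <- aln$mat[id, ]
  hap_coord <- cumsum(row != "-")        # haplotype position at each column
  col_of_ref <- match(seq_len(nchar(aln$ref_seq)), aln$col_ref)
  hap_seq <- ungap_member(aln, id)
  map_boundary <- function(ref_pos, inward, lo, hi) {
    ## walk from ref_pos toward the exon interior until the haplotype
    ## retains a base
    pos <- ref_pos
    while (pos >= lo && pos <= hi) {
      cc <- col_of_ref[pos]
      if (!is.na(cc) && row[cc] != "-") return(hap_coord[cc])
      pos <- pos + inward
    }
    NA_integer_
  }
  ex <- annot$exon_intervals
  exons <- data.frame(exon = seq_along(ex),
                      start = NA_integer_, end = NA_integer_,
                      deleted = FALSE)
  for (i in seq_along(ex)) {
    s <- map_boundary(ex[[i]][1], +1L, ex[[i]][1], ex[[i]][2])
    e <- map_boundary(ex[[i]][2], -1L, ex[[i]][1], ex[[i]][2])
    if (is.na(s) || is.na(e) || s > e) {
      exons$deleted[i] <- TRUE
    } else {
      exons$start[i] <- s
      exons$end[i] <- e
    }
  }
  introns <- NULL
  for (i in seq_len(length(ex) - 1)) {
    if (exons$deleted[i] || exons$deleted[i + 1]) next
    s <- exons$end[i] + 1L
    e <- exons$start[i + 1] - 1L
    if (s > e) next
    introns <- rbind(introns, data.frame(
      intron = i, start = s, end = e,
      donor_gt = substr(hap_seq, s, s + 1L) == "GT",
      acceptor_ag = substr(hap_seq, e - 1L, e) == "AG"))
  }
  list(exons = exons,
       introns = if (is.null(introns)) {
         data.frame(intron = integer(0), start = integer(0), end = integer(0),
                    donor_gt = logical(0), acceptor_ag = logical(0))
       } else introns)
}

## positions of all starts of `motif` within [center-window, center+window]
motif_positions <- function(seq, motif, center, window) {
  lo <- max(1L, center - window)
  hi <- min(nchar(seq) - nchar(motif) + 1L, center + window)
  if (lo > hi) return(integer(0))
  region <- substr(seq, lo, hi + nchar(motif) - 1L)
  m <- gregexpr(motif, region, fixed = TRUE)[[1]]
  if (m[1] < 0) return(integer(0))
  as.integer(m) + lo - 1L
}

#' Enumerate alternative splice-motif combinations
#'
#' Finds all GT dinucleotide starts within `window` of the expected donor
#' position and all AG starts within `window` of the expected acceptor
#' position. For every donor x acceptor pair, the implied intron (from the
#' GT through the AG) is spliced out and the pair is flagged
#' frame-preserving when the spliced length change relative to the expected
#' intron is a multiple of 3, and stop-free when the spliced sequence
#' contains no stop codon in the reading frame anchored at `cds_start`.
#' A combination is valid when both flags hold.
#'
#' @param seq haplotype (genomic) sequence
#' @param expected_donor expected position of the intron's first base (the G
#'   of the 5' GT)
#' @param expected_acceptor expected start of the terminal AG dinucleotide
#' @param window search half-width around the expected positions
#' @param cds_start position of `seq` where the upstream reading frame
#'   starts (codon boundary)
#' @return list with `donors`, `acceptors`, `pairs` (data.frame: donor,
#'   acceptor, frame_preserving, premature_stop, valid) and `n_valid`
#' @export
enumerate_splice_candidates <- function(seq, expected_donor, expected_acceptor,
                                        window = 60, cds_start = 1) {
  seq <- unname(as_seqs(seq)[1])
  L <- nchar(seq)
  stopifnot(expected_donor >= 1, expected_acceptor + 1 <= L,
            expected_donor < expected_acceptor, window >= 0)
  donors <- motif_positions(seq, "GT", expected_donor, window)
  acceptors <- motif_positions(seq, "AG", expected_acceptor, window)
  ref_intron_len <- expected_acceptor + 2L - expected_donor
  pairs <- expand.grid(donor = donors, acceptor = acceptors)
  pairs <- pairs[pairs$donor + 2L <= pairs$acceptor, , drop = FALSE]
  if (nrow(pairs) > 0) {
    res <- lapply(seq_len(nrow(pairs)), function(z) {
      d <- pairs$donor[z]; a <- pairs$acceptor[z]
      intron_len <- a + 2L - d
      frame_ok <- (intron_len - ref_intron_len) %% 3L == 0L
      spliced <- paste0(substr(seq, cds_start, d - 1L),
                        substr(seq, a + 2L, L))
      ncod <- nchar(spliced) %/% 3L
      has_stop <- FALSE
      if (ncod > 0) {
        cods <- substring(spliced, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
        has_stop <- any(Biostrings::GENETIC_CODE[cods] == "*", na.rm = TRUE)
      }
      c(frame_ok, has_stop)
    })
    res <- do.call(rbind, res)
    pairs$frame_preserving <- res[, 1]
    pairs$premature_stop <- res[, 2]
    pairs$valid <- pairs$frame_preserving & !pairs$premature_stop
  } else {
    pairs$frame_preserving <- logical(0)
    pairs$premature_stop <- logical(0)
    pairs$valid <- logical(0)
  }
  rownames(pairs) <- NULL
  list(donors = donors, acceptors = acceptors, pairs = pairs,
       n_valid = sum(pairs$valid))
}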