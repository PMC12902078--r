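## Core domain types: sequence records, reference annotations,
## reference-anchored alignments, and site-class masks.

#' Create a sequence record
#'
#' Light container for a sequence with its provenance: a cloned (Sanger)
#' haplotype, an amplicon read, a reference, or a simulated truth sequence.
#'
#' @param id sequence identifier
#' @param nucleotides IUPAC DNA string (may contain gaps when aligned)
#' @param sample_id sample the sequence was observed in
#' @param qualities optional integer vector of per-base Phred scores
#' @param evidence_source one of "PCS", "MPS", "REF", "SIM"
#' @return an object of class `seq_record`
#' @export
seq_record <- function(id, nucleotides, sample_id = NA_character_,
                       qualities = NULL,
                       evidence_source = c("SIM", "PCS", "MPS", "REF")) {
  evidence_source <- match.arg(evidence_source)
  stopifnot(is.character(nucleotides), length(nucleotides) == 1)
  if (nchar(nucleotides) == 0) stop("nucleotides must be non-empty")
  if (!is.null(qualities) && length(qualities) != nchar(nucleotides)) {
    stop("qualities must have the same length as nucleotides")
  }
  structure(list(id = id, sample_id = sample_id,
                 nucleotides = toupper(nucleotides), qualities = qualities,
                 evidence_source = evidence_source),
            class = "seq_record")
}

## coerce seq_record / character / DNAStringSet collections to a named
## character vector of sequences
as_seqs <- function(x) {
  if (inherits(x, "seq_record")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "seq_record"))) {
    out <- vapply(x, function(r) r$nucleotides, "")
    names(out) <- vapply(x, function(r) r$id, "")
    return(out)
  }
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (is.character(x)) {
    if (length(x) == 0) return(stats::setNames(character(0), character(0)))
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("cannot interpret sequences of class ", paste(class(x), collapse = "/"))
}

#' Create a reference annotation
#'
#' Describes the exon/intron layout of a locus reference, an optional
#' restriction of the analysed segment, and optional extra exclusion
#' intervals (regions left out of all evolutionary statistics, e.g. a
#' locus segment whose boundaries cannot be determined).
#'
#' @param locus locus name
#' @param reference_id reference sequence identifier
#' @param exon_intervals list of 1-based inclusive `c(start, end)` intervals,
#'   sorted and non-overlapping, in transcription order on the plus strand
#' @param analysed_segment optional `c(start, end)` restriction
#' @param exclusions optional list of intervals excluded from analyses
#' @return an object of class `reference_annotation`
#' @export
reference_annotation <- function(locus, reference_id, exon_intervals,
                                 analysed_segment = NULL, exclusions = list()) {
  ex <- lapply(exon_intervals, function(x) as.integer(x[1:2]))
  if (length(ex) == 0) stop("at least one exon required")
  starts <- vapply(ex, `[`, 1L, 1)
  ends <- vapply(ex, `[`, 1L, 2)
  if (any(starts > ends)) stop("exon start exceeds end")
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] <= ends[-length(ends)])) {
    stop("exons must be sorted and non-overlapping")
  }
  if (sum(ends - starts + 1L) < 3L) stop("concatenated exon length must be >= 3")
  structure(list(locus = locus, reference_id = reference_id,
                 exon_intervals = ex,
                 analysed_segment = if (!is.null(analysed_segment))
                   as.integer(analysed_segment[1:2]) else NULL,
                 exclusions = lapply(exclusions, function(x) as.integer(x[1:2]))),
            class = "reference_annotation")
}

#' Anchor-align sequences to a reference
#'
#' Aligns each sequence globally to an ungapped reference (affine gap
#' penalties) and merges the pairwise alignments on reference coordinates.
#' Insertions relative to the reference become extra columns appended after
#' the reference position where they occur, in input order. Ungapping any
#' member row recovers its input sequence exactly. Sequences with less than
#' `min_identity` percent identity to the reference over their aligned span
#' are flagged unalignable and excluded with a warning.
#'
#' @param seqs sequences: named character vector, `DNAStringSet`, or list of
#'   [seq_record()]s
#' @param ref reference: single ungapped sequence (character or `seq_record`)
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   positive)
#' @param type `Biostrings::pairwiseAlignment` type; "global" for full-length
#'   members, "global-local" for reads shorter than the reference
#' @param min_identity percent identity below which a member is dropped
#' @return an object of class `anchored_alignment`
#' @export
anchor_align <- function(seqs, ref, match = 2, mismatch = -3,
                         gap_open = 8, gap_extend = 1,
                         type = "global", min_identity = 50) {
  seqs <- as_seqs(seqs)
  if (length(seqs) == 0) stop("no sequences to align")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  ref_id <- if (inherits(ref, "seq_record")) ref$id else
    if (!is.null(names(ref))) names(ref)[1] else "ref"
  ref_seq <- unname(as_seqs(ref)[1])
  if (grepl("-", ref_seq, fixed = TRUE)) stop("reference must be ungapped")
  L <- nchar(ref_seq)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch)
  base_at_ref <- list()
  ins_after <- list()
  unaligned <- character(0)
  keep_ids <- character(0)
  ## one vectorized alignment call for the whole set
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unname(seqs)), Biostrings::DNAString(ref_seq),
    type = type, substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pids <- Biostrings::pid(pa)
  pats <- as.character(Biostrings::alignedPattern(pa))
  subs <- as.character(Biostrings::alignedSubject(pa))
  starts <- Biostrings::start(Biostrings::subject(pa))
  for (z in seq_along(seqs)) {
    id <- names(seqs)[z]
    if (pids[z] < min_identity) {
      warning("sequence ", id, " is unalignable (<", min_identity,
              "% identity); excluded")
      unaligned <- c(unaligned, id)
      next
    }
    p <- seq_chars(pats[z])
    s <- seq_chars(subs[z])
    ## subject() start is only meaningful for local-in-subject types; for
    ## global alignments the aligned subject spans the whole reference
    offset <- if (sum(s != "-") == L) 0L else starts[z] - 1L
    bases <- rep("-", L)
    ins <- list()
    r <- offset
    for (i in seq_along(s)) {
      if (s[i] != "-") {
        r <- r + 1L
        bases[r] <- p[i]
      } else if (p[i] != "-") {
        key <- as.character(r)
        ins[[key]] <- paste0(if (is.null(ins[[key]])) "" else ins[[key]], p[i])
      }
    }
    keep_ids <- c(keep_ids, id)
    base_at_ref[[id]] <- bases
    ins_after[[id]] <- ins
  }
  if (length(keep_ids) == 0) stop("no alignable sequences")
  ## column layout: [insertions after pos p] interleaved with ref columns
  ins_len <- integer(L + 1L)  # index p+1 = insertions after ref pos p
  for (id in keep_ids) {
    for (key in names(ins_after[[id]])) {
      p <- as.integer(key)
      ins_len[p + 1L] <- max(ins_len[p + 1L], nchar(ins_after[[id]][[key]]))
    }
  }
  ncol_total <- L + sum(ins_len)
  col_ref <- integer(0)
  for (p in 0:L) {
    if (ins_len[p + 1L] > 0) col_ref <- c(col_ref, rep(NA_integer_, ins_len[p + 1L]))
    if (p < L) col_ref <- c(col_ref, p + 1L)
  }
  stopifnot(length(col_ref) == ncol_total)
  ref_chars <- seq_chars(ref_seq)
  ref_row <- ifelse(is.na(col_ref), "-", ref_chars[col_ref])
  mat <- matrix("-", nrow = length(keep_ids), ncol = ncol_total,
                dimnames = list(keep_ids, NULL))
  ## column indices by role
  ref_col_idx <- which(!is.na(col_ref))           # ref position p -> column
  ins_cols <- vector("list", L + 1L)
  pos <- 1L
  for (p in 0:L) {
    if (ins_len[p + 1L] > 0) {
      ins_cols[[p + 1L]] <- seq.int(pos, length.out = ins_len[p + 1L])
      pos <- pos + ins_len[p + 1L]
    }
    if (p < L) pos <- pos + 1L
  }
  for (id in keep_ids) {
    mat[id, ref_col_idx] <- base_at_ref[[id]]
    for (key in names(ins_after[[id]])) {
      p <- as.integer(key)
      chars <- seq_chars(ins_after[[id]][[key]])
      mat[id, ins_cols[[p + 1L]][seq_along(chars)]] <- chars
    }
  }
  structure(list(ref_id = ref_id, ref_seq = ref_seq, ids = keep_ids,
                 mat = mat, ref_row = ref_row, col_ref = col_ref,
                 excluded = rep(FALSE, ncol_total), unaligned = unaligned),
            class = "anchored_alignment")
}

#' Build an anchored alignment from already-aligned, equal-length sequences
#'
#' Fast path for sequence sets that are colinear with the reference (no
#' indels), e.g. simulated truth haplotypes: column `i` maps to reference
#' position `i` directly, with no pairwise alignment step.
#'
#' @param seqs named character vector (or `DNAStringSet`/`seq_record` list)
#'   of sequences, all the same length as `ref`
#' @param ref ungapped reference of the same length
#' @return an `anchored_alignment`
#' @export
trivial_alignment <- function(seqs, ref) {
  seqs <- as_seqs(seqs)
  ref_id <- if (inherits(ref, "seq_record")) ref$id else
    if (!is.null(names(ref))) names(ref)[1] else "ref"
  ref_seq <- unname(as_seqs(ref)[1])
  L <- nchar(ref_seq)
  if (any(nchar(seqs) != L)) stop("all sequences must match the reference length")
  mat <- do.call(rbind, lapply(seqs, seq_chars))
  rownames(mat) <- names(seqs)
  structure(list(ref_id = ref_id, ref_seq = ref_seq, ids = names(seqs),
                 mat = mat, ref_row = seq_chars(ref_seq),
                 col_ref = seq_len(L), excluded = rep(FALSE, L),
                 unaligned = character(0)),
            class = "anchored_alignment")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat("Anchored alignment on", x$ref_id, "-", length(x$ids), "members,",
      ncol(x$mat), "columns (", sum(is.na(x$col_ref)), "insertion,",
      sum(x$excluded), "excluded )\n")
  invisible(x)
}

#' Recover the ungapped input sequence of an alignment member
#' @param aln an `anchored_alignment`
#' @param id member id
#' @return character scalar
#' @export
ungap_member <- function(aln, id) {
  row <- aln$mat[id, ]
  paste(row[row != "-"], collapse = "")
}

#' Exclude primer-site columns from an anchored alignment
#'
#' Columns mapping to the given reference intervals (typically the priming
#' sites of the amplicon) are marked excluded so that downstream statistics
#' ignore them. Overlapping spans are unioned.
#'
#' @param aln an `anchored_alignment`
#' @param primer_spans list of `c(start, end)` reference intervals
#' @return the alignment with updated exclusion flags
#' @export
trim_primer_regions <- function(aln, primer_spans) {
  if (length(primer_spans) == 0) return(aln)
  L <- nchar(aln$ref_seq)
  u <- interval_union(primer_spans)
  if (any(u[, 1] < 1L) || any(u[, 2] > L)) {
    stop("primer span outside reference [1, ", L, "]")
  }
  spans <- lapply(seq_len(nrow(u)), function(i) u[i, ])
  hit <- !is.na(aln$col_ref) & in_intervals(ifelse(is.na(aln$col_ref), 0L,
                                                   aln$col_ref), spans)
  aln$excluded <- aln$excluded | hit
  aln
}

#' Build a site-class mask from an annotation
#'
#' Classifies every alignment column as coding, noncoding or excluded, and
#' assembles the codon layout of the coding part: column triplets, frame
#' offsets, and per-codon potential synonymous-site fractions of the
#' reference under the unweighted and the transition/transversion-weighted
#' Nei-Gojobori schemes. Columns outside the analysed segment, inside
#' exclusion intervals or primer spans, and insertion columns are excluded;
#' codons spanning any excluded column are dropped whole.
#'
#' @param aln an `anchored_alignment`
#' @param annot a [reference_annotation()]
#' @param R transition/transversion weight for the weighted scheme
#' @return an object of class `site_mask`
#' @export
build_site_mask <- function(aln, annot, R = 2) {
  L <- nchar(aln$ref_seq)
  for (iv in annot$exon_intervals) {
    if (iv[1] < 1L || iv[2] > L) {
      stop("exon [", iv[1], ",", iv[2], "] outside reference length ", L)
    }
  }
  col_ref <- aln$col_ref
  nc <- length(col_ref)
  cls <- rep("excluded", nc)
  refpos <- ifelse(is.na(col_ref), 0L, col_ref)
  in_exon <- in_intervals(refpos, annot$exon_intervals) & !is.na(col_ref)
  cls[!is.na(col_ref)] <- ifelse(in_exon[!is.na(col_ref)], "coding", "noncoding")
  if (!is.null(annot$analysed_segment)) {
    seg <- annot$analysed_segment
    cls[!is.na(col_ref) & (refpos < seg[1] | refpos > seg[2])] <- "excluded"
  }
  if (length(annot$exclusions) > 0) {
    cls[!is.na(col_ref) & in_intervals(refpos, annot$exclusions)] <- "excluded"
  }
  cls[aln$excluded] <- "excluded"
  ## codon layout over concatenated exons
  cds_ref <- unlist(lapply(annot$exon_intervals, function(iv) seq.int(iv[1], iv[2])))
  n_codons <- length(cds_ref) %/% 3L
  col_of_ref <- match(seq_len(L), col_ref)
  codon_cols <- matrix(0L, nrow = 0, ncol = 3)
  for (k in seq_len(n_codons)) {
    cols <- col_of_ref[cds_ref[(3L * k - 2L):(3L * k)]]
    if (any(is.na(cols))) next
    if (all(cls[cols] == "coding")) {
      codon_cols <- rbind(codon_cols, cols)
    } else {
      cls[cols][cls[cols] == "coding"] <- "excluded"
    }
  }
  ## incomplete terminal codon columns, if any
  if (length(cds_ref) %% 3L != 0) {
    rest <- col_of_ref[cds_ref[(3L * n_codons + 1L):length(cds_ref)]]
    cls[rest[!is.na(rest)]] <- "excluded"
  }
  ## reference codons; drop codons whose reference codon is not a sense codon
  keep <- logical(nrow(codon_cols))
  codon_ref <- character(nrow(codon_cols))
  for (k in seq_len(nrow(codon_cols))) {
    cod <- paste(aln$ref_row[codon_cols[k, ]], collapse = "")
    codon_ref[k] <- cod
    keep[k] <- cod %in% sense_codons()
    if (!keep[k]) cls[codon_cols[k, ]] <- "excluded"
  }
  codon_cols <- codon_cols[keep, , drop = FALSE]
  codon_ref <- codon_ref[keep]
  idx <- codon_to_index(codon_ref)
  s_unw <- ng_site_table("unweighted")[idx]
  s_wtd <- ng_site_table("weighted", R)[idx]
  ## coding columns not in any retained codon are excluded
  coding_cols <- sort(unique(as.vector(codon_cols)))
  cls[setdiff(which(cls == "coding"), coding_cols)] <- "excluded"
  rownames(codon_cols) <- NULL
  structure(list(col_class = cls,
                 codon_cols = codon_cols,
                 codon_ref = codon_ref,
                 s_unweighted = s_unw, s_weighted = s_wtd, R = R,
                 noncoding_cols = which(cls == "noncoding"),
                 ref_id = aln$ref_id),
            class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat("Site mask on", x$ref_id, "-", sum(x$col_class == "coding"),
      "coding columns in", nrow(x$codon_cols), "codons,",
      length(x$noncoding_cols), "noncoding,",
      sum(x$col_class == "excluded"), "excluded\n")
  invisible(x)
}
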