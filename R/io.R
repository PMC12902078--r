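## File I/O: FASTA/FASTQ via Biostrings, exon-interval tables (TSV or GFF3),
## YAML run configuration, and TSV report writers.

#' Read sequences from a FASTA file
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#' @param seqs named character vector
#' @param path file path
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(as_seqs(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read amplicon reads from a FASTQ file
#' @param path file path
#' @param sample_id sample label attached to every read
#' @return data.frame with columns read_id, sample, sequence, quality
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sample = sample_id,
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)))
}

#' Write reads to FASTQ files, one per sample
#' @param reads data.frame from [simulate_reads()]
#' @param dir output directory
#' @return paths of the written files
#' @export
write_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in unique(reads$sample)) {
    d <- reads[reads$sample == s, ]
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(d$sequence),
      Biostrings::PhredQuality(d$quality))
    names(x) <- d$read_id
    p <- file.path(dir, paste0(s, ".fastq"))
    Biostrings::writeQualityScaledXStringSet(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a reference annotation from an exon-interval table
#'
#' The table is a 4-column TSV (locus, reference_id, start, end), one row
#' per exon, 1-based inclusive coordinates.
#'
#' @param path TSV path
#' @param locus optional locus to select when the table holds several
#' @inheritParams reference_annotation
#' @return a [reference_annotation()]
#' @export
read_exon_table <- function(path, locus = NULL, analysed_segment = NULL,
                            exclusions = list()) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  stopifnot(all(c("locus", "reference_id", "start", "end") %in% names(d)))
  if (is.null(locus)) locus <- d$locus[1]
  d <- d[d$locus == locus, , drop = FALSE]
  if (nrow(d) == 0) stop("no exons for locus ", locus)
  d <- d[order(d$start), ]
  reference_annotation(locus, d$reference_id[1],
                       lapply(seq_len(nrow(d)), function(i)
                         c(d$start[i], d$end[i])),
                       analysed_segment = analysed_segment,
                       exclusions = exclusions)
}

#' Write an annotation as an exon-interval TSV
#' @param annot a [reference_annotation()]
#' @param path output path
#' @export
write_exon_table <- function(annot, path) {
  d <- data.frame(locus = annot$locus, reference_id = annot$reference_id,
                  start = vapply(annot$exon_intervals, `[`, 0L, 1),
                  end = vapply(annot$exon_intervals, `[`, 0L, 2))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exon intervals from a GFF3 file
#'
#' Only `exon` features are used; other feature types are ignored.
#'
#' @param path GFF3 path
#' @param locus locus name for the resulting annotation
#' @inheritParams reference_annotation
#' @return a [reference_annotation()]
#' @export
read_gff3_exons <- function(path, locus = NULL, analysed_segment = NULL,
                            exclusions = list()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 8]
  ex <- Filter(function(x) x[3] == "exon", f)
  if (length(ex) == 0) stop("no exon features in ", path)
  ref_id <- ex[[1]][1]
  iv <- lapply(ex, function(x) c(as.integer(x[4]), as.integer(x[5])))
  iv <- iv[order(vapply(iv, `[`, 0L, 1))]
  reference_annotation(if (is.null(locus)) ref_id else locus, ref_id, iv,
                       analysed_segment = analysed_segment,
                       exclusions = exclusions)
}

#' Read a YAML run configuration
#'
#' Top-level keys mirror the arguments of [sim_config()] and the module
#' thresholds (posterior, min_freq, min_len, R, gamma_a, bootstrap).
#'
#' @param path YAML file
#' @return named list
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write the haplotype-by-sample registry as TSV
#' @param haps a `haplotype_set`
#' @param path output path
#' @export
write_registry_tsv <- function(haps, path) {
  d <- cbind(haps$haps, as.data.frame(haps$counts))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}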