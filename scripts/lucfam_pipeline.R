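#!/usr/bin/env Rscript

# Thin command-line wrapper over the lucfam package.
#
#   Rscript scripts/lucfam_pipeline.R simulate --config cfg.yaml --outdir d
#   Rscript scripts/lucfam_pipeline.R run-all  --config cfg.yaml --outdir d
#   Rscript scripts/lucfam_pipeline.R run-all  --seed 7 --outdir d
#
# The YAML config mirrors the arguments of lucfam::run_config(); omitted
# fields keep the published defaults (>150 bp, posterior 0.95, 15%, R = 2,
# gamma shape 1, 1000 bootstrap replicates).

suppressMessages(library(lucfam))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: lucfam_pipeline.R <simulate|run-all> [--config cfg.yaml] ",
       "[--seed N] --outdir DIR")
}
cmd <- args[1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
outdir <- get_arg("--outdir", "lucfam_out")
cfg_file <- get_arg("--config")
seed <- as.integer(get_arg("--seed", "1"))

cfg <- run_config(seed = seed)
if (!is.null(cfg_file)) {
  cfg <- utils::modifyList(cfg, read_run_config(cfg_file))
}

if (cmd == "simulate") {
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  truth <- simulate_family_set(scfg)
  clones <- simulate_clones(truth)
  rd <- simulate_reads(truth)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth_sequences(truth), file.path(outdir, "truth.fasta"))
  write_exon_table(truth$annotation, file.path(outdir, "exons.tsv"))
  write_fasta(vapply(clones$clones, function(r) r$nucleotides, ""),
              file.path(outdir, "clones.fasta"))
  write_fastq(rd$reads, file.path(outdir, "reads"))
  utils::write.table(rd$read_to_source,
                     file.path(outdir, "read_to_source.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat("simulated", nrow(truth$haplotypes), "haplotypes,",
      nrow(rd$reads), "reads ->", outdir, "\n")
} else if (cmd == "run-all") {
  res <- run_end_to_end(cfg, outdir)
  cat("pipeline complete:", nrow(res$accepted$haps),
      "accepted haplotypes ->", outdir, "\n")
} else {
  stop("unknown command: ", cmd)
}
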