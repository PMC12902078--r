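# lucfam

Haplotype calling and molecular evolution of multi-copy gene families, built
for the situation found at copepod luciferase loci: a nominally single locus
that is in fact a small family of paralogous copies, sampled through two
imperfect evidence streams — full-length haplotypes from PCR/cloning/Sanger
sequencing (PCS) and deep amplicon reads over a shorter segment (MPS).

The package provides, end to end:

* **`synthdata`** — a ground-truthed simulator of paralogous families
  (codon-level mutator with synonymous/nonsynonymous rate ratio ω, stop
  codons rejected, neutral introns), recombinant alleles, clone sampling,
  and amplicon reads with substitution plus strand-biased 1–2 nt indel
  errors.
* **`hapcall`** — abundance-based candidate calling with a Poisson error
  model (candidate at edit distance *k* from a more abundant parent *p* has
  expected error count λ = n_p (ε/3)^k (1−ε)^(L−k); posterior score
  P(N < n_c), merge at ≤ 0.95) and a validation cascade: posterior > 0.95,
  short indels and premature stops only if matched in a clone, and a 15%
  within-sample frequency rule with clone-identity or multi-sample rescue.
* **`famassign`** — diagnostic-site family assignment and mosaic
  (recombinant) detection by a single-breakpoint minimum-discordance scan.
* **`popgen`** — Nei–Gojobori site and difference counting (unweighted and
  ts/tv-weighted with R = 2) implemented from first principles, π at silent
  (synonymous + noncoding) and replacement sites with Jukes–Cantor
  correction, haplotype diversity Hd, Tajima's D, K_A/K_S divergence, and
  the McDonald–Kreitman test with Fisher's exact p and neutrality index
  NI = (P_n/P_s)/(D_n/D_s).
* **`phylo`** — synonymous-distance matrices (modified Nei–Gojobori, gamma
  shape 1), Saitou–Nei neighbor joining, codon-resampling bootstrap, Newick
  output (ape-compatible `phylo` objects).
* **`annot`** — exon/intron projection onto haplotypes and enumeration of
  ORF-preserving alternative GT/AG splice-motif combinations.

The methods vignette (`vignettes/gene-family-analysis.Rmd`) documents the
models, conventions and design choices in detail.

## Worked example

Simulate three luciferase-like families (a deep duplication at K_S ≈ 0.8, a
younger one at ≈ 0.16, ω = 0.05), sequence them with realistic error rates,
and run the full pipeline:

```r
library(lucfam)

cfg <- run_config(seed = 7,
  sim = list(
    families = list(
      list(name = "Luc1", n_copies = 2, target_ks_within = 0.15),
      list(name = "Luc2", n_copies = 2, target_ks_within = 0.15,
           target_ks_between = 0.8, diverge_from = "Luc1"),
      list(name = "Luc3", n_copies = 2, target_ks_within = 0.13,
           target_ks_between = 0.16, diverge_from = "Luc2")),
    samples = 3, clone_sampling = 8,
    read_sim = list(depth = 800, sub_rate = 0.01, indel_rate = 0.005)),
  bootstrap = 200)
res <- run_end_to_end(cfg, outdir = "lucfam_out")

res$accepted
#> Haplotype set: 4 candidates over 3 samples; 7 reads

for (f in names(res$diversity)) { cat(f, ": "); print(res$diversity[[f]]) }
#> Luc1 : n=2  S=81  Hd=1.000  pi_sil=0.1531  pi_nonsyn=0.0129  Tajima D=NA
#> Luc2 : n=2  S=79  Hd=1.000  pi_sil=0.1543  pi_nonsyn=0.0074  Tajima D=NA
#> Luc3 : n=2  S=57  Hd=1.000  pi_sil=0.1078  pi_nonsyn=0.0056  Tajima D=NA

res$divergence
#>   family_a family_b          Ka        Ks Ka_over_Ks
#> 1     Luc1     Luc2 0.052582139 0.8705468 0.06040128
#> 2     Luc1     Luc3 0.053590486 0.8764751 0.06114319
#> 3     Luc2     Luc3 0.008347463 0.1475005 0.05659278

res$mk$Luc2
#> McDonald-Kreitman 2x2:
#>             nonsynonymous silent
#> polymorphic             4     75
#> fixed                   3     34
#> Fisher two-tailed p=0.678  NI=0.604

write_newick(res$tree)
#> (Luc2.2:0.03857927241,(Luc3.2:0,(Luc1.1:0,Luc1.2:0.1355584082)100:1.197145855)50:0.06929406123,(Luc2.1:0.1232440216,Luc3.1:0.09421891086)58:0.04189562153);
```

Reading the output: every accepted MPS haplotype is clone-backed
(`res$registry` adds two PCS-only haplotypes that never reached the read
threshold — stringent read filtering recovering fewer alleles than cloning
is exactly the behaviour seen in real amplicon studies of these loci).
Silent diversity within families (~0.11–0.15) is 10–30× the replacement
diversity, and the divergence table recovers the simulated duplication
order: Luc2–Luc3 (K_S 0.15) split after the deep Luc1–Luc2 duplication
(K_S 0.87). The NJ tree on synonymous distances separates the Luc1 family
with bootstrap support 100; the shallow Luc2/Luc3 split is harder at this
within-family diversity, visible in its lower supports. The MK table for
Luc2 shows no departure from neutrality (the generator applies the same ω
to polymorphism and divergence).

Per-stage artifacts (truth FASTA, per-sample FASTQ, clone FASTA, candidate
audit log, haplotype-by-sample registry TSV, diversity/divergence/MK TSVs,
Newick tree, run settings) are written to `outdir`.

A thin command-line wrapper over the same functions is available:

```sh
Rscript scripts/lucfam_pipeline.R run-all --seed 7 --outdir lucfam_out
Rscript scripts/lucfam_pipeline.R simulate --config cfg.yaml --outdir sim_out
```

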