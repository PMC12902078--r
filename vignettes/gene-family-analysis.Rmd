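---
title: "Characterizing multi-copy gene families from clone and amplicon evidence"
author: "lucfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing multi-copy gene families from clone and amplicon evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lucfam)
```

## The problem

Copepod luciferase genes occur as small families of paralogous copies.
A single individual can carry many distinct alleles of what is nominally one
locus, and two evidence streams are typically available: full-length
haplotypes recovered by PCR, cloning and Sanger sequencing (PCS), and deep
amplicon reads over a shorter segment (MPS). Neither stream is trustworthy
alone — cloning samples few molecules, and amplicon sequencing drowns true
alleles in substitution and indel errors — so haplotypes must be called by
combining abundance, cross-sample recurrence, and clone support. Once
haplotypes are established, the questions are evolutionary: how diverse is
each family at silent versus amino-acid-changing positions, how far apart
are families at synonymous sites (which dates the duplications), do the data
reject neutral evolution, and are apparent family-mixing alleles true
recombinants or PCR chimeras?

`lucfam` implements this entire analysis as composable R functions, together
with a ground-truthed simulator so that every stage can be validated without
any external data.

## The simulator and what it does (and does not) emulate

`sim_config()` / `simulate_family_set()` generate a founder locus (sense
codons only, random introns) and derive gene families by a codon-level
mutator: synonymous changes are always accepted, nonsynonymous changes are
accepted with probability $\omega$, and changes creating stop codons are
rejected. Introns drift neutrally at the synonymous event rate. The defaults
mirror the regime observed at copepod luciferase loci: three families, a
deep split at synonymous divergence $K_S \approx 0.8$ and a younger one at
$\approx 0.16$, within-family silent diversity $\pi_S \approx 0.13$–$0.15$,
and $\omega = 0.05$ (nonsynonymous diversity one to two orders of magnitude
below silent diversity). Samples receive all haplotypes with log-normal
amplification weights; clones are error-free full-length draws (Sanger
treated as exact); reads cover a ~360 bp amplicon and carry substitutions at
rate $\varepsilon$ plus 1–2 nt indels at rate $\iota$, doubled on
reverse-strand reads to emulate the strand-biased indel artefact of
semiconductor sequencing.

**Divergence targeting.** Substitution events applied at uniform positions
with uniform replacement bases form a Jukes–Cantor chain, so the expected
JC-corrected distance equals the applied events per site. The mutator
therefore converts a target $K_S$ directly into a proposal budget
($3 n_{codons} \cdot K_S$ proposals; a uniform proposal is synonymous with
probability $s/(3 n_{codons})$) instead of measuring realized distance and
resampling until it matches. We first implemented the measure-and-stop
alternative and rejected it: conditioning on the realized silent distance
pins the silent substitution count of every lineage, overdisperses the
McDonald–Kreitman 2×2 tables, and inflated the MK false-positive rate to
roughly twice its nominal level. The closed-form budget keeps realized
$K_S$ within about 5% of target while preserving the natural
multinomial/Poisson dispersion that contingency-table tests assume.
Between-family targets are interpreted at the copy level: copies sit at
$\pi_S/2$ from their family master, so the master-to-master budget is
reduced by both families' within-family contributions.

Deliberate simplifications: no selection on introns, no indel evolution
between true haplotypes (configured deletions aside), no PCR chimera
formation by default, error-free clones, flat quality scores consistent with
$\varepsilon$, and no flow-space (homopolymer) error structure. Passing the
recovery tests therefore shows that the pipeline is correct under a clean
substitution+indel error model — not that it is robust to chimeric clones or
homopolymer-length miscalls in real Ion Torrent data.

## Haplotype calling and the validation cascade

Reads longer than 150 bp (`filter_reads()`, boundary read as $\ge$ 151) are
orientation-normalized and dereplicated per sample. Candidates are processed
in decreasing abundance (`call_candidates()`): a candidate $c$ at edit
distance $k$ from its nearest more-abundant accepted parent $p$ has expected
error-derived count
$\lambda = n_p (\varepsilon/3)^k (1-\varepsilon)^{L-k}$, and its posterior
score is $P(N < n_c)$ under $N \sim \mathrm{Poisson}(\lambda)$; candidates
at or below 0.95 merge into their parent. The most abundant candidate per
sample is always accepted. Distances are exact substitution counts between
equal-length sequences; for length-mismatched pairs a single short indel is
detected exactly (edit distance 1) and anything further is bounded below by
2, which cannot change an accept/merge decision because $\lambda$ at
$k \ge 2$ is negligible for any realistic parent abundance.

`apply_validation_cascade()` then applies, in order: the posterior
threshold (0.95); exclusion of candidates with 1–2 nt indels unless an
identical indel (type, position, length, bases) occurs in a clone;
exclusion of premature stop codons unless matched in a clone; and a 15%
within-sample frequency rule with two rescues — sequence identity to a clone
over the amplicon segment, or occurrence in $\ge 2$ samples. Frequency
denominators are the post-posterior-stage read totals per sample (the
choice is logged in the audit trail so users can recompute under the
pre-filter convention). Every drop is logged with the rule that fired.

Two diagnostics mirror how such calls are audited in practice:
`mutation_profile_statistic()` compares the distance of weakly supported
haplotypes to their nearest strong haplotype against strong-to-strong
distances (error derivatives would sit unusually close to a parent), and
`correlate_clone_read_support()` reports the OLS $R^2$ between clone and
read counts across the evidence registry.

## Family assignment and mosaic alleles

Diagnostic sites (`find_diagnostic_sites()`) are columns fixed within each
of two families and different between them. Assignment is by per-site
majority vote with a configurable ambiguity threshold (default 0.8; exact
ties are always ambiguous). Mosaic detection (`detect_mosaic()`) scans every
single breakpoint between adjacent covered diagnostic sites and labels the
two segments independently; a haplotype is mosaic when two-segment labelling
removes at least `min_gain = 3` discordant sites relative to the best
single-family labelling. The gain threshold of 3 follows the observation
that convincingly recombinant alleles share several exclusive variants in
their foreign segment (`find_exclusive_shared_variants()` recovers such
variants). Fewer than 4 covered diagnostic sites yields an explicit
not-evaluable result rather than a call. Mosaic-flagged haplotypes are
excluded from diversity, divergence, MK and tree inputs by default, since
their two segments have different evolutionary histories.

## Codon-aware population genetics

All statistics are built on Nei–Gojobori counting implemented from first
principles and checked exhaustively against a brute-force pathway
enumerator:

* `ng_site_counts()` — potential synonymous site fractions per codon, with
  an unweighted scheme and a transition/transversion-weighted ("modified")
  scheme (default bias $R = 2$); mutations to stop codons count as
  nonsynonymous; $s + n = 3$ for every sense codon.
* `ng_diff_counts()` — observed synonymous/nonsynonymous differences per
  codon pair, averaged equally over mutational pathways that avoid stop
  codons; $S_d + N_d$ equals the number of differing positions.
* `jc_correct()` / `gamma_correct()` — multiple-hit corrections; the gamma
  variant with shape 1 reduces to $d = p/(1 - 4p/3)$.

Conventions, chosen to match the common desktop implementations of these
statistics: complete deletion (any column with a gap or ambiguous base in
any analysed sequence is removed, and codons are dropped whole, which keeps
$s + n$ conservation exact); unweighted counting for diversity, divergence
and MK, with the weighted scheme reserved for phylogenetic synonymous
distances; JC correction applied per pair and then averaged. The silent
class pools synonymous coding positions with noncoding (intron) columns.
Tajima's *D* is computed over all usable sites of the analysed segment and
reported as an explicit null when no site segregates. `mk_test()` classifies
fixed differences by pathway averaging between ingroup and outgroup majority
codons restricted to the fixed positions, classifies polymorphic changes
single-site in the ingroup majority-codon context, counts sites that are
both segregating and divergent once (as polymorphic), rounds fractional
counts per cell, and applies a two-tailed Fisher exact test; the neutrality
index $NI = (P_n/P_s)/(D_n/D_s)$ is reported when defined. The exact
rounding/pathway policy used by reference desktop software for MK cells is
undocumented; integer rounding at the table level is this package's choice.

## Synonymous-distance phylogenetics

`syn_distance_matrix()` computes pairwise synonymous $p$-distances
($\sum S_d / \sum s$ under the weighted scheme) with gamma correction
(shape 1). `nj_tree()` is a Saitou–Nei neighbor-joining implementation with
the Studier–Keppler criterion; ties break to the lowest-index pair, negative
branch lengths clamp to zero with the deficit recorded, and the output is an
ape-compatible unrooted `phylo` object (NJ on any additive matrix reproduces
the generating topology and path lengths exactly, which the tests verify on
random trees up to 12 taxa). `bootstrap_support()` resamples codon columns
with replacement — the resampling unit is the codon, which preserves the
structure synonymous distances are computed from — recomputes matrix and
tree per replicate, skips saturated replicates (counted in a log attribute),
and reports supports as percentages of successful replicates.
`write_newick()` emits branch lengths, optional integer support labels, and
single-quotes labels containing spaces or Newick metacharacters.

## Annotation projection and splice-motif enumeration

`project_annotation()` maps reference exon boundaries through an anchored
alignment onto each haplotype; boundaries landing in deletions snap toward
the exon interior, fully deleted exons are flagged, and GT/AG presence at
projected intron ends is verified. `enumerate_splice_candidates()`
enumerates GT donors and AG acceptors within a window (default 60 nt,
covering the alternative motifs observed around poorly conserved intron
boundaries) of their expected positions and counts donor×acceptor
combinations that preserve the reading frame (spliced length change
$\equiv 0 \bmod 3$) without introducing a stop codon. The function only
enumerates; it never selects a combination, because absent mRNA evidence the
true boundary is undetermined.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout, matching GenBank feature
  convention; plus strand only, with reverse-complement normalization at
  read intake.
* Pairwise anchoring uses affine-gap global alignment (match 2, mismatch
  −3, gap open −8, extend −1, configurable); traceback tie-breaking is that
  of the alignment backend, and the contract tested is exact ungap
  round-trip of every member.
* Sub-stream seeds derive from the master seed by hashing (sample, stage)
  labels, so adding a sample never perturbs another sample's stream and all
  outputs are byte-reproducible at fixed seed.
* The analysed segment and excluded regions (e.g. an exon whose boundaries
  cannot be fixed) are explicit annotation fields, never hard-coded.
* IUPAC ambiguity codes and gaps trigger complete deletion in population
  genetics; saturated distances ($p \ge 0.75$) are flagged undefined, and NJ
  refuses matrices with undefined entries, naming the offending pairs.

## Problem sizes used in the automated checks

The simulation-recovery tests run at desk scale: loci of 90–240 codons with
60–90 nt introns, 2–3 families of 2–3 copies, read depths of 150–1000 per
sample, 20 seeds for parameter recovery and haplotype-calling truth
recovery, and 200 seeds for the MK type-I error check. These sizes give
sampling error comfortably inside the tested tolerances (15% relative for
$\pi_S$ and $K_S$, $\omega$-hat below 0.15 at true 0.05, $\ge 95$%
haplotype recovery with $\le 5$% false calls, MK rejection $\le 7$% at
$\alpha = 0.05$).

## Known limitations

Distances between length-mismatched candidates beyond one indel are bounded
rather than computed exactly (see above for why this is safe for the
accept/merge decision). The error model is per-base i.i.d.; real
homopolymer-driven indels cluster. Family assignment is defined for two
families at a time (the multi-family case proceeds pairwise). Mosaic
detection considers a single breakpoint; multi-crossover recombinants
are out of scope, as are maximum-likelihood dN/dS and ML/Bayesian trees.
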