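---
title: "Homozygote-anchored MHC class IIa haplotype inference and selection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygote-anchored MHC class IIa haplotype inference and selection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliphase)
```

## The problem

The ruminant MHC class IIa region carries the classical antigen-presenting
loci *DRB1*, duplicated *DQA* genes (*DQA1*, *DQA2*, *DQA2-like*) and
duplicated *DQB* genes (*DQB1*, *DQB2*, *DQB2-like*), all in strong linkage
disequilibrium. Genotyping them directly is hard for two reasons. First,
primers are rarely locus-specific: the DQA2 reaction co-amplifies
DQA2-like, and the DQB reactions cross-amplify each other's targets
depending on which alleles are present, so a direct Sanger read of a
diploid's PCR product superposes up to four alleles into one
ambiguity-coded consensus. Second, some haplotypes lack a locus entirely
(null haplotypes), so a locus-specific reaction legitimately returns
nothing.

`ampliphase` implements the combinatorial strategy used to characterise
such haplotypes in a closed island sheep population, as a reusable, tested
pipeline:

1. **Deconvolution.** An observed IUPAC consensus is explained by the
   cardinality-minimal sets of known alleles whose positionwise
   superposition reproduces it *exactly* — a genotype is called only when
   every observed variant is accounted for.
2. **Homozygote anchoring.** Individuals homozygous at an anchor locus
   (*DRB1*) carry one haplotype twice, so every allele their DQ assays
   reveal belongs to that haplotype. Anchor alleles shared by several
   haplotypes are split by partitioning the anchored individuals'
   downstream profiles; rare anchor alleles without homozygotes are
   recovered by subtracting a known partner haplotype from heterozygotes.
3. **Phylogenetic locus assignment.** DQB alleles that cannot be assigned
   to a locus by their primers are placed on a K80/neighbour-joining
   bootstrap phylogeny and assigned to the reference cluster that contains
   them.
4. **Selection analysis.** Exon-2 allele alignments are scanned for
   positive selection with pairwise Nei–Gojobori dN/dS and GY94 codon
   site models (M1a/M2a and M7/M8) compared by likelihood ratio tests,
   with naive-empirical-Bayes and FEL-style per-site classification.

## The deconvolution rule

For aligned, equal-length amplicons the observed consensus at position
$i$ is the IUPAC code of the set union of the co-amplified alleles' bases
at $i$. A candidate subset $S$ *explains* an observation $O$ iff
$\mathrm{union}(S) = O$ positionwise — not merely
$\mathrm{union}(S) \subseteq O$. The strict equality encodes the calling
rule that all variants must be accounted for: a heterozygote's observed
`R` must be produced by the explanation, not just permitted by it.

`explain_mixture()` prunes candidates with a compatibility bitmask test,
then enumerates subsets in increasing size up to `kmax` (default 4, the
largest mixture two fully cross-amplifying loci can produce in a diploid;
the combined DQB2/DQB2-like assay uses 5 to accommodate the three-DQB
haplotype), stopping at the first size with an exact explanation. All
minimal explanations are reported: ambiguity is surfaced, not resolved
arbitrarily, because the original workflow resolved such cases by further
sequencing. Alleles identical over the assayed region are collapsed into
an ambiguity group *before* the search, so indistinguishability yields a
confidently *called* group (e.g. the two DQB1\*07 alleles identical
throughout exon 2) rather than a spurious ambiguous status. An observed
`N` is treated as missing data and excluded from both compatibility and
equality checks.

Statuses are exhaustive values, not errors: `no_product` (null locus),
`uncallable_frameshift` (length-polymorphic mixture, the situation a 1-bp
deletion allele creates under a full-exon assay — handled in the lab by
switching to a primer downstream of the deletion, and modelled here the
same way), `novel_suspected` (no explanation over the database), `called`,
`ambiguous`.

## Haplotype inference

`find_anchor_homozygotes()` lists individuals whose anchor call is a
single allele. `extend_haplotypes()` collects the anchored individuals'
profiles over the DQA assays; set-minimal profiles become candidate
haplotypes, every profile must decompose as a union of at most two
candidates, and a composite profile with no matching homozygote
contributes a derived complement candidate. This reproduces both observed
kinds of anchor sharing: one DRB1 allele on two haplotypes with disjoint
DQ contents, detected as two internally consistent groups.

`subtract_heterozygotes()` recovers haplotypes whose anchor allele never
occurs homozygous: in an individual `{rare, partner}` whose partner allele
anchors exactly one fully known haplotype, the partner's alleles are
removed from each called set and the residue is assigned to the rare
haplotype. Because a partner may share alleles with the rare haplotype
(two haplotypes here share their entire DQ2-like complement), single
residues can be silently incomplete; the implementation therefore pools
residues across all usable individuals by union and re-verifies
`pooled ∪ partner = observed` for every individual, raising a conflict
only when that check fails. Individuals whose observation does not
contain the putative partner's profile are discarded rather than
misused — this matters when a shared anchor allele's second haplotype has
not yet been characterised.

The same two mechanisms run again for the DQB stage, using individuals
homozygous for the entire partial haplotype (anchor + DQA), in the
original screening order. `min_support` defaults to 4 anchored
individuals (the per-allele homozygote count used in the original
design); extensions below it are emitted but flagged `low_confidence`
rather than suppressed, and anchors with *no* homozygotes fall back to
subtraction.

`validate_haplotypes()` closes the loop: an individual is consistent with
a haplotype pair iff for *every* assay the expected product (superposition
of the pair's alleles, or no product on a doubly null locus) matches the
observation exactly. `haplotype_frequencies()` gives haplotype and
per-locus allele frequencies plus anchor-locus and full-haplotype
homozygosity; an individual admitting several consistent pairs
contributes equal fractional weight to each (the validation data offered
no canonical tie-break, so none is invented). Full-haplotype homozygosity
can never exceed anchor-locus homozygosity — haplotype identity implies
anchor identity — and the tests assert this ordering on every simulated
cohort, mirroring the direction of the published 27.5% (DRB1) versus
21.3% (haplotype) figures.

## What the synthetic-data generator emulates — and what it does not

The packaged fixture transcribes the published eight-haplotype panel
(A–H over seven loci, including the three DQA1-null haplotypes, the
DQB1\*07:01/07:02 exon-2 ambiguity group, and the three-DQB haplotype G).
The real exon-2 alignments are published only as images, so the fixture
pairs the real allele names with **synthetic stand-in sequences**,
generated deterministically: within-locus alleles a handful of
substitutions apart, between-locus divergence an order of magnitude
larger (so the three DQB clusters are phylogenetically separable), all
coding regions in frame and stop-free, and the DRB1\*13:01 deletion
placed in the 5′ flank of the full amplicon so that the full-exon assay
shows a length conflict while the truncated assay does not.

`sample_population()` draws haplotype pairs by random union
(Hardy–Weinberg) — the source study states no population-genetic model
for the flock, so inbreeding and cohort structure are deliberately not
modelled. `simulate_assay()` is noise-free by design: the analysed inputs
are curated consensus sequences, so miscalls are represented only through
the per-assay dropout sets (cDNA expression failure) and the
novel-allele injection knob (`mutate_allele()`, exact substitution
counts). Passing tests therefore demonstrate the combinatorial
correctness of deconvolution and anchoring under the published assay
structure; they do not demonstrate robustness to base-calling error,
chimeric PCR products, or allele-specific amplification bias, none of
which enter the model.

Default study conditions used by the tests and the acceptance script:
cohorts of 300 individuals with all eight haplotypes at equal frequency
1/8 (every frequency ≥ 0.05, comparable to the 118-animal screen plus
94-animal validation panel of the source study). Under these conditions a
rare anchor allele still occasionally lacks homozygotes, which is exactly
what exercises the subtraction path.

## Codon models and numerical choices

The selection module is self-contained: GY94-style rate matrix over the
61 sense codons (single-nucleotide changes at relative rate
$\kappa^{\mathrm{ts}} \omega^{\mathrm{nonsyn}} \pi_j$), F3x4 equilibrium
frequencies, and Felsenstein pruning over site patterns with the hot loop
in compiled code. Site-class mixtures: M0 (one $\omega$), M1a
($\omega_0 < 1$, $\omega_1 = 1$), M2a (adds $\omega_2 > 1$), M7
(beta-distributed $\omega$, discretised into 10 equal-probability
categories by quantile midpoints — the common default, since no category
count is stated in the source), M8 (beta plus $\omega_s > 1$). Nested
pairs are compared with $2\Delta\ell$ against $\chi^2_2$, which is
conservative at the boundary; the test suite calibrates the realised
type-I error on 200 null simulations and requires it in [0.01, 0.09].

Fitting uses bounded quasi-Newton (`nlminb`) with
$\omega_0 \in (10^{-4}, 0.999)$, $\omega_2 \in (1, 50)$,
$\kappa \in (0.1, 20)$, convergence tolerance $10^{-8}$ on the
log-likelihood, and three starting points by default (warm starts from
the nested null count toward that total in the paired workflow
`positive_selection_test()`). Branch lengths follow the fixed-input-tree
workflow: an M0 pre-fit estimates a single branch-scale factor
(converting a nucleotide NJ tree to substitutions/codon) which the site
models then hold fixed; joint scale estimation remains available via
`optimize_scale = TRUE`. Reversible-matrix eigensystems are memoised
across optimiser evaluations (the normalisation only rescales
eigenvalues), and transition matrices are cached per unique branch
length.

Site classification is **naive** empirical Bayes (posterior
$\propto w_c \times$ site likelihood at the MLEs): the Bayes empirical
Bayes prior-integration grid adds substantial machinery with no stated
settings, and NEB's known anti-conservatism with poorly estimated
parameters is accepted as a documented caveat. The FEL-style scan fixes
$\kappa$ and branch scale from M0, maximises each site's likelihood over
separate synonymous ($\alpha$) and nonsynonymous ($\beta$) rates in units
where $\alpha = \beta = 1$ is one expected substitution/codon, tests
$\beta = \alpha$ with a df-1 LRT, and flags a site only when $p < 0.05$
*and* $\hat\beta > \hat\alpha$. The episodic-selection (MEME) method is
out of scope. Pairwise dN/dS follows Nei–Gojobori 1986: per-codon site
counts averaged between sequences (changes to stop codons counted
nonsynonymous), multi-step codon differences averaged over stop-free
minimal paths, Jukes–Cantor correction of both proportions, and an
undefined ratio reported as such when $d_S = 0$.

The published per-locus positively-selected-site counts (12/14/13) are
**not** reproduced here: they depend on the external curated allele
database and unpublished allele sets. The acceptance surface is instead
simulation recovery: $\hat\omega_2 > 1$ in ≥ 90% of replicates generated
with a positive class, LRT power ≥ 80% under strong selection, NEB
finding ≥ 50% of truly selected sites with ≤ 5% false labels at 16
sequences and strong divergence. Calibration simulations use 8 sequences
× 80 codons on a fixed topology with 0.4 substitutions/codon per branch,
and recovery simulations 12–16 sequences × 90–100 codons — alignment
sizes on the order of the exon-2 allele sets the method targets.

## Phylogenetic locus assignment

K80 distances are computed with pairwise deletion so exon-2-only
fragments remain comparable with full-length alleles; saturated pairs are
an error naming the pair. Neighbour joining delegates to `ape::nj`, with
negative branch lengths clamped to zero and the deficit moved to the
sister edge. `assign_locus()` resamples alignment columns, rebuilds the
tree per replicate, and lets the query vote for a locus when it falls
inside the smallest bipartition side containing all of that locus's
references; majority fraction is the support, below 0.5 the query stays
unassigned, and non-monophyletic reference sets trigger a flagged
nearest-mean-distance fallback. The original study used Bayesian
inference (MrBayes, K80 + gamma) for this figure; distance-based NJ with
a nonparametric bootstrap is substituted as a desk-scale method that is
sufficient for cluster membership, with gamma rate heterogeneity omitted
because no shape parameter is reported. Queries lacking the region where
the signal is strongest (3′ UTR) are flagged low-confidence; the
primer-set-based designation used for such alleles in the source is a
provenance note, not an algorithmic rule.

## Coordinates and nomenclature

All sequence positions are 1-based and inclusive. Exon-2 coordinates are
alignment-relative; the genomic numbering offsets of the source data
(exon 2 beginning at base 83 for DQA and base 110 for DQB, counted from
the translation start) are metadata to be applied by the caller, never
silently. Novel alleles follow the temporary-nomenclature priority of
`register_novel()`: full-length transcripts are flagged for official
submission; fragments matching an archive entry are named
`locus*accession`; remaining fragments are named `locus-haplotype`. The
fixture keeps the source's printed temporary names as literal strings.

## A worked run

```{r demo, eval = FALSE}
cfg <- pipeline_config(n = 300, seed = 1,
                       stages = c("simulate", "genotype", "haplotype",
                                  "validate", "phylo"))
report <- run_pipeline(cfg)
report
as.data.frame(report$inferred$panel)
```

## Known limitations

* Synthetic stand-in sequences preserve the combinatorial structure of
  the published panel, not its actual sequence content; distances,
  dN/dS values and tree shapes computed from the fixture are properties
  of the stand-ins.
* Heterozygote subtraction can be blocked when every available partner
  shares an anchor with a second, uncharacterised haplotype; such anchors
  are reported unresolved rather than guessed.
* No statistical (EM/likelihood) phasing: the method is deliberately the
  combinatorial anchoring procedure it reproduces, and inherits its need
  for homozygotes or clean subtraction partners.
* NEB instead of BEB; NJ + bootstrap instead of Bayesian tree inference;
  no MEME. Each substitution is noted where it applies.
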