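---
title: "Methods: the famscreen family-based rare-variant screen"
author: "famscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the famscreen family-based rare-variant screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscreen)
```

# Scope and model

`famscreen` implements a forward genetic screen for multiplex families
with systemic lupus erythematosus: given pedigrees, per-sample exome
variant calls and variant/gene annotation tables, it returns the genes
whose surviving variants segregate with disease under autosomal dominant
(AD), autosomal recessive (AR: homozygous or compound heterozygous) or
X-linked (XL) inheritance. The package deliberately begins *after*
alignment and variant calling: its inputs are a PED pedigree, a VCF with
`GT`, `DP` and `QUAL`, and TSV tables carrying per-variant population
frequencies (one column per ethnic subpopulation), CADD scores and
consequence classes, and per-gene GDI and MSC values. Consequence
prediction, GDI computation and negative-selection metrics are consumed
as published values, never recomputed.

The screen is a deterministic composition of per-variant filters followed
by per-family genotype pattern matching. Because every filter is a pure
predicate on an annotated variant, the composition is an intersection:
order-invariant and idempotent, which the test suite asserts directly.

# Filters and their boundaries

**Call quality.** A site survives iff its Phred-scaled quality is
strictly greater than 20, and a sample's genotype is used iff its depth
is strictly greater than 2 reads (both boundaries are exclusive because
the quality rule *removes* calls at "≤ 20" and "≤ 2x"). The depth rule is
applied per sample: a failing sample has its genotype masked to
`missing` rather than the whole site being dropped, because a single
shallow sample should not delete information about the rest of the
family. Whether the original depth filter was per-sample or per-site is
not specified by the screen's description; per-sample masking is this
package's choice, and it makes the filter total and idempotent. A
missing depth under a called genotype is masked the same way.

**Consequence.** Kept classes: missense, nonsense, frameshift, in-frame
indel, essential splice. Synonymous, other, and unknown classes are
dropped.

**Frequency.** Variants with global public MAF above 0.01 or in-house
cohort frequency above 0.01 are excluded outright (common polymorphisms
cannot explain a rare severe familial disease). The surviving variants
must then satisfy the model ceiling in *every* ethnic subpopulation —
implemented as max over all `maf_*` columns present — strictly below
10⁻⁴ (AD), 10⁻² (AR) or 10⁻⁴ (XL). A missing frequency counts as 0: an
allele absent from the databases is unobserved, i.e. rare, not unknown.
The in-house exclusion is a configurable threshold (default 0.01)
because in the original screen it was only qualitative ("too frequent to
explain the disease").

**Gene damage index.** Genes with GDI strictly above 13.84 — the
recommended cutoff, the 95% CI upper boundary of the GDI distribution,
designed to remove 5% of genes — are excluded. 13.84 itself is retained,
since exclusion requires being *above* the boundary. A gene absent from
the score table passes with a warning: an annotation gap must not
silently delete a candidate gene.

**Deleteriousness.** A variant is kept iff CADD/MSC is strictly greater
than 1. The MSC here is the lower bound of the two-sided Student-t
confidence interval (default confidence 0.99) of the mean CADD score of
the gene's known disease-causing mutations. The original MSC estimator
is defined in its own publication and not restated in the screen's
description; the t-interval form was chosen because it is deterministic,
closed-form and directly testable (it is translation-equivariant and
monotone in the confidence level, both asserted as properties). With a
single disease score the score itself is used; with none, a caller-
supplied fallback. A non-positive MSC leaves the ratio undefined and the
variant is kept with a warning; a missing CADD drops the variant as
unscored.

# Compound-heterozygote phasing

For each gene with at least two surviving variants, all unordered pairs
for which some affected individual is heterozygous at both sites are
enumerated. Phase is classified per affected carrier from the possible
parental origins of each allele: a parent is a possible origin if it is
ungenotyped at the site or carries the allele, and a homozygous-alternate
parent is a *forced* origin (the child must have received one copy). The
pair is `trans` when every consistent origin assignment puts the alleles
on opposite parental haplotypes, `cis` when both can only derive from the
same parent, and `ambiguous` when both configurations remain possible —
typically because a parent is ungenotyped and no contradiction exists.
Ambiguous pairs are retained and flagged, mirroring the way a candidate
with an ungenotyped parent must stay in play; cis pairs are rejected as
AR candidates because the second haplotype is intact.

This classification is scoped to the child–parent trio for the pair of
sites. Haplotype information that siblings could contribute (e.g. a
sibling whose genotype pins down which of an ungenotyped parent's
haplotypes carries an allele) is deliberately not propagated; the
acceptance suite verifies the trio-scope semantics against an
independent brute-force enumeration of parental haplotype contents and
transmissions on 1,000 random Mendelian-consistent families. Mendelian-
inconsistent input (an allele neither parent could have transmitted)
cannot be phased and is classified `ambiguous` rather than discarded.

**Segregation.** Missing genotypes never veto a pattern — only available
family members were ever genotyped. Under complete penetrance (the
default) no unaffected member may carry a full causal genotype: both
alleles of a comp-het pair, a homozygous AR genotype, any carrier
genotype under AD, or a hemizygous XL genotype in a male. Carrying a
single comp-het allele is always consistent, and X-linked heterozygous
females are allowed to be unaffected under every penetrance setting.
Under incomplete penetrance unaffected carriers are tolerated and the
report row is labelled `incomplete_only`. Reports are sorted
lexicographically by family, model and gene for deterministic output.

# Ancestry assignment

The reference panel PCA uses Patterson scaling — dosages centred by twice
the panel allele frequency and scaled by `sqrt(2p(1-p))` — which is the
standard for genotype PCA; the original screen does not state its
scaling. Monomorphic variants are dropped (their scale is zero), missing
dosages are mean-imputed, and requesting more components than the panel's
numerical rank is an error. Study samples are projected onto panel-only
axes rather than included in the fit, so case genotypes cannot induce
their own axes. Assignment is a majority vote among the k = 10 Euclidean
nearest panel neighbours on the 10 first PCs; the neighbour count is this
package's choice (the screen says only "closest neighbours"), with ties
broken by smaller summed distance and then lexicographic label so the
result is deterministic. Distances on PCs are invariant to the sign
indeterminacy of singular vectors, which the tests assert by flipping.

# Assay quantification

The Ab Score is `log2(NFI × SNR + 1)`: zero at zero signal, strictly
increasing in the product. Each sample's NFI column is first divided by
that sample's mean internal IgG-control intensity; whether the original
normalization divides or regresses on the controls is unstated, and
division is this package's convention (it makes the score invariant to
per-sample staining intensity, which the tests check). Heatmap
clustering follows the stated parameters: hierarchical with one minus
Pearson correlation and complete linkage (a constant row, whose
correlation is undefined, is placed at distance 1 from everything to
keep the metric total), and k-means with Euclidean distance, two
clusters and up to 10,000 iterations under a caller-fixed seed. Group
comparisons use the Wilcoxon matched-pairs signed-rank test with the
standard zero-drop convention, exact for up to 25 non-zero pairs and the
normal approximation above; because exact p-values are discrete and
floor at 2/2ⁿ, the antigen ranking breaks p-value ties by the magnitude
of the mean shift. The TIRF actin clearance ratio is
`mean(F3,F4,F5)/mean(F1,F2)` per linescan, averaged over the two
perpendicular scans; a zero edge mean returns `NA` with a warning rather
than an infinite ratio.

# What the generator emulates — and what it does not

`simulateCohort()` produces nuclear multiplex families (two founders,
2–4 children): founder haplotypes are Hardy–Weinberg draws from the
family's subpopulation MAF, children receive one whole per-gene
haplotype from each parent (no intragenic recombination, so comp-het
phase is exactly defined), and affection status follows the planted
genotype under complete penetrance. Planted causal variants satisfy
every filter by construction — family-private alleles with subpopulation
MAFs below the model ceiling, missense consequence, CADD between 1.5 and
2.5 times the gene's MSC, gene GDI at or below 13.84 — so recovery
failures can only come from the screen itself or from deliberately
injected missingness. Cis plants put both alleles on one haplotype of
one parent and mark the carrier sibship as affected (a phenocopy
scenario): the only correct screen behaviour is rejection. Truth labels
are written as a sidecar table, never into the VCF, so the screen cannot
read them. Background variants get log-uniform MAFs (10⁻⁴–0.2) with
gamma-perturbed subpopulation spread (Dirichlet-style, concentration 50)
and uniform CADD on 0–30, so each filter has genuine work to do; a small
fraction of background sites receive failing quality (2%) and failing
depth cells (1%) to exercise the call-quality filter.

The generator does not model linkage disequilibrium, recombination maps,
sequencing error, population admixture within a family, de novo
mutation, or consanguinity loops; pedigrees are single nuclear families.
A passing recovery test therefore shows the screen's logic is correct
under clean Mendelian transmission, not that it is robust to genotyping
error or pedigree misspecification in real cohorts.
`simulateReferencePanel()` uses the Balding–Nichols model (per-population
Beta frequencies around shared ancestral frequencies at a configured
F_ST), the standard structure simulator, with independent variants —
adequate for testing ancestry assignment, not for LD-aware methods.

# Problem sizes and numerical choices

The test and acceptance runs use sizes chosen to exercise every code
path while staying comfortably interactive: 200 simulated families (150
trans, 50 cis plants) for recovery; 1,000 random families of up to 6
members and 4 variants for the phasing-oracle equivalence; a
3-population, 50-per-population, 500-variant panel at F_ST 0.1 for
ancestry (at that separation assignment should be exact, and the test
requires 100%); 2,000 genes for the GDI percentile check, where a cutoff
at the empirical 95th percentile must exclude 5% of genes to within
1/n. Multi-allelic VCF sites are decomposed into biallelic records
because every downstream filter is per-allele; allele counts are
conserved by construction and checked. Coordinates are 1-based VCF
positions; the genome build is metadata only, and no liftover is
attempted.

# Known limitations

Phasing is trio-scoped (no sibling haplotype propagation, no
multi-generation inference beyond parental genotypes); X-linked
compound heterozygotes are not considered (hemizygous males have one X);
the AD screen reports any segregating variant per gene rather than
ranking within genes; and the in-house frequency exclusion is a plain
threshold, not a model of cohort-specific artefacts. The MSC t-interval
can be negative for small, dispersed disease-score sets, in which case
the CADD/MSC ratio test is conservative in the keep direction — such
variants are kept with a warning, consistent with the principle that
annotation pathologies must not silently remove candidates.
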