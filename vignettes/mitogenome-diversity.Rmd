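---
title: "Recovering mitogenomes and maternal diversity from multi-sample VCFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering mitogenomes and maternal diversity from multi-sample VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodiv)
```

## The problem

Large whole-genome sequencing panels of livestock carry, as a by-product,
deep short-read coverage of the mitochondrial genome. Turning those
multi-sample mitochondrial VCFs into maternal-diversity results is not a
matter of running a consensus caller: the calls are diploid-style on a
haploid genome, many genotypes are *heteroplasmic* (two alleles observed in
one animal, either from genuinely mixed mitochondrial populations or from
nuclear copies of mitochondrial DNA — NUMTs — misaligned onto the
mitogenome), semen-derived samples carry few mitochondria and therefore
exaggerated NUMT interference, and the classic mtDNA toolchain (haplogroup
callers, diversity estimators) expects clean haploid FASTA in a specific
reference coordinate system.

`mitodiv` implements that whole path as composable, tested functions:

1. **QC filtering** of a multi-sample mitochondrial VCF at site level
   (QUAL, MQ, minor allele count, depth cap), followed by INDEL/missing
   removal, an animal-level mean-depth filter, and a tissue-aware
   heteroplasmy cap for the semen group.
2. **Consensus building**: depth-aware haploid base calling per genotype,
   variant-position sequences, and full-length N-filled FASTA.
3. **Reference liftover** of haplogroup-defining variants between two
   mitochondrial assemblies differing by indels and substitutions.
4. **Haplogroup assignment** against a defining-variant catalogue, with
   missing- and private-variant reporting, region-restricted (D-loop-only)
   mode, and discovery of shared private variants marking putative
   subgroups.
5. **Diversity and structure**: pairwise-difference matrices, nucleotide
   and haplotype diversity, hierarchical haplotype clustering, one-level
   AMOVA, and a haploid GRM with PCA.
6. **Imputation evaluation**: a masking cross-validation harness with a
   built-in nearest-haplotype imputer and an ingestion path for external
   GT:DS:GP output.
7. **Synthetic data**: a generator that emulates the statistical structure
   of a real cattle cohort so every stage is testable without restricted
   data.

## The synthetic cohort generator

Real cohorts of this kind sit behind managed-access agreements, so the
package ships a generator (`sim_config()`, `simulate_haplogroup_definitions()`,
`simulate_population()`, `simulate_vcf()`) whose defaults describe the
conditions the pipeline is designed for:

* a 16,340 bp linear 1-based mitochondrial reference (the mitogenome is
  circular, but variant tables and haplogroup catalogues treat positions
  linearly, so the generator and the pipeline do too);
* haplogroup-structured haplotypes: disjoint defining-variant sets drawn
  without replacement, one founder per haplogroup, each animal a founder
  plus a Poisson number of private substitutions. Private mutations avoid
  defining positions — a private variant is by definition not in the
  defining catalogue — which also makes truth-label recovery on noiseless
  cohorts a deterministic check rather than a probabilistic one;
* per-genotype read depth drawn from a normal with mean 12.34 (the
  per-animal coverage scale of the motivating cohort) truncated at one
  read;
* heteroplasmy emitted as two-allele genotypes whose major-allele read
  fraction is Beta-distributed per tissue class. The semen class is both
  more frequently heteroplasmic (default rate 0.05 per site vs 0.005
  somatic) and more balanced (expected contaminating-read fraction 0.45 vs
  0.25), mimicking NUMT interference in low-copy-number samples. The true
  shape of the empirical allelic-ratio distribution is not published, so
  the Beta is a modelling choice with a configurable concentration, not a
  calibrated fit;
* sporadic missing genotypes (default 0.01 per genotype), spiked INDEL
  records (default rate 0.001 per reference position), and a configurable
  fraction of sites with QUAL or MQ below 30 so the filters have work to
  do;
* substitutions pick a uniform random non-current base. Real mitochondrial
  variation is transition-dominated; nothing downstream depends on the
  transition:transversion ratio, so the generator does not model it.

All randomness flows from one master seed (`seed`), with the three
generation stages drawing from documented offsets (`seed`, `seed + 1`,
`seed + 2`), so a configuration reproduces its VCF byte for byte. What
passing tests on these cohorts shows is that the *algorithms* are correct
under the stated statistical structure; they do not certify behaviour on
real data with alignment artefacts, reference bias, or non-independent
missingness, none of which the generator emulates.

## QC filtering

`filter_sites()` applies, in order: QUAL ≥ 30, MQ ≥ 30, a depth cap, and a
minor-allele-count rule (all thresholds live in `filter_thresholds()`).
Two points needed decisions the conventional recipe leaves open:

* **Depth cap.** "Mean + 3 SD" is computed over per-site mean depths
  across animals, because the filter removes *sites*; a pooled-read
  version would conflate animal and site effects. With a single site the
  SD is undefined and the cap is vacuous.
* **Minor allele count (AC2).** Alleles are counted across all non-missing
  genotypes, each allele of a heteroplasmic call once and a homoplasmic
  call twice. At multi-allelic sites every alternate allele must reach the
  minimum count on its own; failing ALTs are pruned, genotypes referencing
  them become missing (and thus feed the missing-genotype filter), and the
  site survives only if its remaining least-frequent allele still reaches
  the count. This is the conservative reading.

`drop_indels_and_missing()` then removes INDEL records and any site with a
missing genotype, establishing the contract the consensus builder relies
on (zero missing, SNPs only). `filter_animals_by_depth()` removes animals
with mean depth below 10 (boundary retained). Finally
`filter_semen_heteroplasmy()` caps heteroplasmic sites per animal at 150 —
but only in the **semen group**: males sampled from semen or from unknown
tissue. Females, and males with a known non-semen tissue, are never removed
by this rule, however heteroplasmic they are, because their heteroplasmy is
not attributable to the low-copy-number NUMT mechanism. The canonical order
(site filters → INDEL/missing → animal depth → semen cap) is fixed in
`qc_pipeline()` and recorded in its report, since the removal counts depend
on it.

## Consensus rules

`call_consensus_base()` converts one diploid-style genotype to one base:

* homoplasmic genotypes map directly to their allele;
* heteroplasmic genotypes take the allele with the higher read depth;
* a REF/ALT depth tie takes **ALT**, deliberately avoiding reference bias;
* an ALT/ALT depth tie is not covered by that rationale; the package takes
  the higher allele index (extending the "never prefer the lower-numbered
  allele" direction of the ALT rule) and warns, so the case is visible in
  logs rather than silently resolved.

`expand_to_full_sequences()` writes each animal's bases at its 1-based
variant positions into a reference-length string of Ns (default
16,340 bp), the input format traditional haplogroup callers require.
IUPAC ambiguity codes are deliberately not used for heteroplasmy: the
whole point of the depth rule is to commit to one base.

## Reference liftover

`liftover_map()` describes two assemblies that differ by a short list of
deletions (bases present in the target, absent from the source; stored in
target coordinates) plus single-base substitutions. The packaged default
(`default_liftover_map()`) maps the 16,338 bp bovine reference (BRS,
V00654) onto the 16,340 bp ARS-UCD1.2 mitochondrial contig: deletions at
target positions 222 and 589 and twelve substitutions.

`lift_position()` maps a source position `p` to the unique fixpoint
`t = p + #{deletions ≤ t}`. With the default map this is +0 through source
221, +1 for 222–587 and +2 from 588 onward, which reproduces every
published coordinate pair for this reference change (363→364, 2536→2538,
8188→8190, 9682→9684, 12165→12167, 13310→13312, 15635→15637, and
16338→16340). The fixpoint form is used rather than a verbal
"+1 up to X, +2 after X" rule because it is the unique convention under
which the inverse map is total off the deletion sites and
`lift_position_inverse(lift_position(p)) == p` holds for *every* source
position; the inverse returns `NA` exactly at the deleted target
coordinates. `lift_variant_set()` lifts a defining-variant catalogue and
moves any variant whose allele now equals the target reference base into a
dropped list — those variants are simply no longer variant on the new
reference — with lifted and dropped partitioning the input.

## Haplogroup assignment

`assign_haplogroup()` scores a query against each group by the **match
fraction** matched/(matched + mismatched) over non-missing defining sites.
The fraction, rather than the raw match count, keeps small
(sub)group definitions competitive with large ones; published haplogroup
callers do not document their internal scoring, so this is the package's
own, stated choice. N positions count as missing and can only move sites
out of the denominator — masking never manufactures evidence. Exact ties
are reported as a tie list plus the deepest common name prefix (a T1/T3
tie reports "T"), mirroring how unresolved calls are usually summarised;
a query with no positive evidence for any group (e.g. the bare reference)
is "unassignable". Private variants are query bases differing from the
reference at positions that define *no* group (a variant at another
group's defining position is "known", not private); missing variants are
the assigned group's defining sites that are N in the query.

`restrict_to_region()` implements D-loop-only mode. The bovine control
region spans the sequence origin, so the default `dloop_region()` is the
join of a head interval and a tail interval; its exact boundaries are a
configurable default, not a biological claim. Restriction can only remove
evidence, which is why region-restricted calls show more ties and
unassignables whenever the discriminating sites lie outside the region —
the package's tests construct exactly that situation.

`find_shared_private_variants()` groups each haplogroup's private variants
by their exact carrier set and reports every variant set carried by at
least `min_group_size` animals — by construction carried by nobody else in
the haplogroup. This is the signature by which an uncatalogued subgroup
(a block of animals sharing two private mutations, say) is detected.

## Diversity, AMOVA, GRM

`pairwise_difference_matrix()` counts mismatches with pairwise deletion of
N positions. Downstream: `nucleotide_diversity()` (k = mean pairwise
differences, π = k/L with L the number of sites considered),
`haplotype_classes()` (exact-equality classes and singletons), and
`haplotype_diversity()` (Hd = n(1 − Σp²)/(n − 1), with the Nei 1987
eq. 8.12 large-sample variance for its SD — the conventional estimator
when none is named).

`hierarchical_clusters()` wraps average-linkage `hclust` cut at a height.
At cut height 0 on N-free sequences the clusters coincide exactly with the
exact-match haplotype classes, and the linkage choice is provably
irrelevant; both facts are unit-tested rather than assumed.

`amova()` is the one-level Excoffier–Smouse–Quattro decomposition. The
pairwise nucleotide-difference count is used directly as the squared
distance (under a binary per-site encoding the count *is* the squared
Euclidean distance). A negative among-group component — possible under the
moment estimator when groups are no more different than random draws — is
reported as-is with a warning rather than truncated at zero, so that
permutation nulls built on shuffled labels stay centred. The permutation
test shuffles labels and reports the proportion of permuted Φ~ST~ values
reaching the observed one.

`haploid_grm()` encodes each polymorphic site as one 0/1 indicator per
non-reference allele (a multi-allelic site contributes several indicators;
`collapse = TRUE` gives the single ref/non-ref alternative), standardises
by the sample frequency, z = (x − p)/√(p(1 − p)), and averages the
cross-products over indicators. Monomorphic indicators are excluded. With
no stated reference the most frequent allele per site serves as reference;
the choice affects individual indicators but not the spanned space.
`grm_pca()` is a plain eigendecomposition with coordinates scaled by
√eigenvalue.

## Imputation cross-validation

`make_mask()` splits the cohort into a study group (default 20% of
animals) and a reference panel, masking a fraction (default 10%) of sites
per study animal. The masked site draws are independent per animal — the
alternative, one shared masked-site set, would confound site difficulty
with replicate noise; per-animal draws also match how sporadic missingness
actually arises.

`naive_impute()` is intentionally simple: rank panel haplotypes by Hamming
distance on the unmasked sites, copy the nearest haplotype's allele as a
phased homoplasmic genotype, and convert the k = 5 nearest haplotypes'
inverse-distance weights into a dose (DS) and genotype probabilities (GP).
It exists to exercise the evaluation machinery end to end, not to compete
with a production imputer; `read_imputed_vcf()` ingests external
GT:DS:GP output (Beagle-style) into the same scoring path.

`resolve_imputed_base()` turns an imputed genotype into a haploid base:
homoplasmic genotypes give their own base; REF/ALT heteroplasmy follows
the dose (DS < 1 → REF, DS ≥ 1 → ALT; doses in (1,2) fall to ALT by
monotonicity, since the stated rule covers only "< 1" and "= 1"); ALT/ALT
heteroplasmy with DS = 2 and symmetric probability mass is set to N
(no evidence to prefer either allele), otherwise the allele with the
larger probability mass summed over the GP entries containing it wins.

`concordance()` scores masked cells by unordered allele-pair agreement and
reports a confusion matrix keyed by the original genotype class, so the
characteristic failure mode — heteroplasmic classes imputed far worse than
homoplasmic ones — is visible per class, not averaged away.
`run_replicates()` repeats the whole cycle (replicate r seeds its mask
with `seed + r`) and aggregates means and SDs; `haplogroup_agreement()`
closes the loop by re-assigning haplogroups from the imputed sequences and
comparing with the original calls, tie lists compared as sets.

## Problem sizes and numerical choices

The test suite and examples run on cohorts of 200 animals with four
haplogroups of 25 defining variants (the scale at which every property the
package asserts is already decidable) and 50-replicate imputation runs;
the estimator identities (AMOVA, GRM, diversity) are checked against
independent brute-force implementations at tolerance 1e-9 on small random
fixtures. Ties in the nearest-haplotype imputer break toward the lowest
panel index; ties in haplogroup scoring are reported, never broken
silently. Degenerate inputs (empty tables, single sequences, monomorphic
GRMs, empty region intervals) raise errors rather than returning
placeholder values.

## Known limitations

* The QC thresholds are the conventional recipe; nothing re-estimates
  QUAL/MQ from reads, and NUMT contamination is addressed statistically
  (depth, heteroplasmy caps), not by alignment.
* The consensus commits to one base per site; genuinely mixed
  mitochondrial populations are flattened by design.
* The liftover handles the short-indel-plus-substitution case typical of
  mitochondrial reference revisions, not genome-wide chain files.
* The built-in imputer is a nearest-haplotype copier; its accuracy numbers
  characterise the evaluation harness, not the state of the art.
* AMOVA is one-level (among/within one grouping); hierarchical designs
  (breed within country) are out of scope.
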