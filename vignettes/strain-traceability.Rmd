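---
title: "Tracing strains by private SNPs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing strains by private SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptracer)
```

# The problem and the model

Inter-delta PCR fingerprints resolve *Saccharomyces cerevisiae* strains by
the layout of delta elements in their genomes. Closely related strains share
layouts, so their fingerprints coincide and the assay saturates. The
SNP-marker strategy replaces (or complements) it: whole-genome variant calls
over a collection are mined for **private SNPs** — biallelic substitutions
whose alternate allele occurs in exactly one strain — and each marker is
turned into an **allele-specific (ARMS) PCR assay** whose product appears
only when the template carries the variant allele. A multiplex of such
assays converts a gel lane into a strain identifier.

`snptracer` implements every step in silico. This vignette records the
operational definitions, parameter choices and numerical decisions; it
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

# Private-SNP calling

A locus qualifies iff:

1. both alleles are single nucleotides (InDels are excluded: they are less
   stringent markers for an assay whose specificity lives in one 3′ base);
2. the alternate allele is carried — heterozygous or homozygous, both
   qualify, since the assay detects allele *presence* — by exactly one
   strain;
3. **no strain has a missing genotype** at the locus. A missing call cannot
   certify absence of the allele, and a traceability marker is only as good
   as that certificate. This is deliberately stricter than requiring
   absence among observed calls;
4. every strain is covered at ≥ `min_depth` (default 50×): the same
   certificate argument, at the read level.

Raising `min_depth` can only remove reported SNPs (a property test asserts
this monotonicity), and the caller is checked against a brute-force oracle
on random toy matrices.

Heterozygous calls in *non-owner* strains at a candidate locus disqualify it
under rule 2 (a het non-owner carries the allele). Whether the original
workflow tolerated such calls is not documented anywhere we could follow;
the strict rule is the safe reading for a marker that must never
cross-amplify.

# Marker triage: operational criteria

The published selection criteria are qualitative ("avoid polymorphic,
repetitive, hard-to-amplify regions"). The package fixes them
operationally (all thresholds in `marker_config()`):

| check | window | default rule |
|---|---|---|
| polymorphic flank | pos ± (`max_primer_len` + 5) = ±33 bp | any other collection variant flags |
| repeats | same window | homopolymer > 6 nt or dinucleotide repeat > 4 units flags |
| soft-masking | same window | any masked base flags |
| GC content | pos ± 100 bp | outside 30–65 % flags |
| 3′-anchor uniqueness | 15-mer ending at the SNP | > 1 occurrence in the reference (both strands) flags |

The footprint window covers every base a primer ending on the SNP could
touch, plus slack for the mate's 3′ end. The 15-mer count is a cheap exact
surrogate for "difficult to amplify / non-specific": it bounds the
specificity of the primer's business end. Passing candidates are ranked per
strain by greedy chromosome dispersion (next pick on an unused chromosome
ranks higher, ties by chromosome then position), because markers for one
strain on different chromosomes fail independently — the ranking is fully
deterministic, so reruns reproduce.

# Melting temperatures

Unified nearest-neighbor thermodynamics (the SantaLucia 1998 parameter set)
with duplex initiation terms, non-self-complementary pairing
(`Tm = ΔH / (ΔS + R ln(Ct/4))`, `Ct` = 0.5 µM primer), and an entropic salt
correction `0.368 (n−1) ln[Na⁺_eq]`.

**Monovalent-equivalent salt.** The reaction buffer contains MgCl₂, and
divalents dominate duplex stability at PCR-typical concentrations. We use
`[Na⁺_eq] = mono + 120·√(Mg − dNTP)` (defaults 50 mM, 2.0 mM, 0.8 mM →
181 mM equivalent). This is a deliberate, documented extension of the plain
50 mM monovalent model: without it, a 62 ± 2 °C design window is
unreachable within 18–28 nt for most flanks at yeast-like GC (≈ 0.40), i.e.
the design contract and the stated Tm model contradict each other. Setting
`mg_mM = 0` restores the literal monovalent model. The Tm target of 62 °C
(tolerance ± 2 °C, panel spread ≤ 3 °C) anchors the annealing end point of
the touch-down program, 61.5 °C.

Tm is computed for the primer *as synthesized* against its perfect
complement; the engineered −2 mismatch is not penalized. That is the
conventional design quantity, and mismatch-NN corrections would suggest a
precision the rest of the model does not have.

# ARMS assay design

For each SNP the allele-specific footprint ends on the SNP; the wild-type
and variant primers differ only at the terminal base (the allele) and share
length and footprint — length is selected on the shared reference context,
minimizing |Tm − target|, and design *fails* (reported, not patched) if no
length of 18–28 nt lands in the window.

**The −2 destabilizer.** Position −2 from the 3′ end is replaced so it
mismatches the annealing strand on *every* haplotype. The substitution
table (configurable) maps annealing-strand base → primer base A→A, C→C,
T→T (identity clashes) and G→A (A·G): strong non-Watson-Crick pairs in the
ARMS tradition. The terminal allele base then carries the discrimination:
on the matched template the primer has exactly one internal mismatch (the
engineered one); on the mismatched template it has a 3′ terminal mismatch
as well, and extension fails.

**Size separation.** The conventional mates are placed (footprint pinned at
the product boundary, length again chosen by Tm) so that both products lie
in 150–800 bp and |wild-type − variant| ≥ 200 bp, making the allele call a
band-size call. 800 bp and the 25 bp gel resolution are conservative
readings of the published product-size table (maximum 689 bp, smallest
within-strain gap 227 bp). All four footprints must occur exactly once in
the reference (both strands) and overlap no known collection variant except
the target SNP.

`design_assays()` staggers the minimum variant-product size by 40 bp per
assay so multiplexed assays land on distinct, gel-separable sizes —
criterion (d) made mechanical.

**Panels.** Only the variant-specific pairs enter the multiplex (2–12
primers = 1–6 assays). Compatibility checks: Tm spread ≤ 3 °C;
within-strain expected bands ≥ 25 bp apart; no 3′-end-to-3′-end
complementarity run ≥ 5 nt between any two primers. The dimer rule is
end-on-end (the extensible dimer); a "3′ k-mer complementary to anywhere on
the other primer" rule was measured to reject essentially every random
12-primer panel and would void the 2–12-primer contract.

**Touch-down program.** `touchdown_protocol()` is pure arithmetic:
annealing temperatures `start, start−step, …` down to the last value
≥ `end` (so a step that does not divide the range stops *before*
overshooting), then the standard phase at `end`. Defaults reproduce the
optimized program: 9 touch-down cycles 69.5 → 61.5 °C plus 25 standard
cycles, 34 total, 98 °C/2 min activation, 72 °C/5 min final extension.

# In-silico PCR

A primer binds a site iff its 3′-terminal base matches the template exactly
and it has at most `internal_mismatch_max` internal mismatches (default 1 —
precisely the budget the engineered −2 mismatch consumes on the intended
template; the non-target allele adds a terminal mismatch and is rejected
outright). Inter-delta primers get a budget of 2, modelling diverged delta
elements. Every convergent forward/reverse site pair on one chromosome
within `max_amplicon` (3000 bp, the agarose-visible window) yields an
amplicon.

This model has no cycle-count or efficiency dependence: the 45-cycle
inter-delta protocol variant and band-intensity differences are wet-lab
sensitivity matters, deliberately out of scope.

**Gel rendering.** Bands are what a gel resolves, not molecules: sizes
closer than `gel_resolution` (25 bp) merge by single linkage into one band
at their mean. Merged bands are ≥ 25 bp apart by construction, so rendering
is idempotent. Fingerprint classes are connected components of the
pairwise band-by-band match graph (tolerance < 25 bp) — an equivalence-safe
generalization of exact matching; on planted data matching is exact anyway.

**Colony assignment** is exact signature matching: empty or foreign
patterns are `unassigned`; a pattern equal to the merged union of two or
more signatures is `ambiguous` (a mixed template is reported, never
guessed). Frequency tallies divide by *all* colonies and round
half-away-from-zero (14/26 → 54 %).

# The synthetic world

`collection_spec(seed = …)` defaults describe a 28-strain collection with
the structure of the motivating panel: one 6-member cluster (C1), four
2-member clusters (C2–C5), 14 singletons (U1–U14) — 19 delta layouts, hence
19 expected fingerprints of which 5 are multi-strain.

* Reference: 10 chromosomes × 60 kb, i.i.d. at GC 0.40 (yeast-like). A
  scaled-down stand-in for the 12 Mb genome; `chrom_count`/`chrom_len` are
  free parameters.
* Delta layouts: one convergent delta-12/delta-21 site pair per layout,
  amplicon sizes 180 + 34k bp — every layout's band differs from every
  other's by more than the gel resolution. Layout membership is encoded by
  SNPs: a strain lacking a layout carries an inactivating SNP at each of
  that layout's 3′-anchor bases. This keeps the truth set strictly
  biallelic-SNP and makes the truth round-trip (reference + truth records →
  strain genome) exact, at the cost of not modelling genuine delta
  insertions/deletions.
* Cluster backbones: 25 shared SNPs per multi-member cluster (every third
  heterozygous); singletons rely on layout + private differences.
* Private SNPs: 2–4 per strain (alternating hom/het), planted in blocks
  ≥ 3 kb apart — farther than `max_amplicon`, so panel assays cannot
  cross-talk — with positions vetted at planting time for clean flanks and
  Tm-window designability (the generator *guarantees* designable markers;
  that is its stated role, not a tuned outcome).
* Depth: constant 60× (clears the 50× filter); a range mode
  (`depth = list(model = "range", …)`) exercises filter rejection.
* Colonies are pure strains — a colony grows from one cell; mixtures exist
  only before plating.
* Strain genomes are single haplotypes carrying every allele the strain
  possesses (het loci apply the alternate allele). That is exactly the
  allele-presence semantics AS-PCR reads; it does *not* model the
  wild-type-pair signal on heterozygous templates, ploidy, or any
  population-level heterogeneity.

What a green test therefore establishes: the pipeline's logic —
private-SNP identification, design constraints, binding/discrimination
rules, panel compatibility, assignment — is exact on a world with planted
truth. What it does not establish: performance on real reads (alignment
and calling artifacts, repeats at genuine delta elements, depth
heterogeneity, primer chemistry beyond the NN model).

# Phylogeny

Distances are counts of unshared variants under allele-presence semantics
(het = hom_alt = "carries"; loci missing in either strain are skipped per
pair); a strict-genotype mode is available. Neighbor joining is the classic
Saitou–Nei agglomeration, re-implemented: Q-criterion, standard
branch-length formulas, reduction `d(u,k) = (d(i,k)+d(j,k)−d(i,j))/2`. Ties
in Q break to the smallest index pair; negative branch lengths clamp to 0;
n = 2 returns a single edge split d/2 + d/2 (NJ is undefined below three
taxa; the symmetric completion is the natural one). The implementation is
exact on additive matrices and is cross-checked against an independent NJ
in the test suite. Trees serialize as Newick with labels restricted to
`[A-Za-z0-9_.-]` — anything else errors, which buys deterministic
round-trips.

# Known limitations

* No secondary-structure/hairpin thermodynamics; the dimer screen is a 3′
  complementarity rule, not a free-energy model.
* No amplification-efficiency or band-intensity modelling; gels are size
  multisets.
* The Tm model's Mg correction is an equivalence rule, not full
  divalent thermodynamics.
* Synthetic delta layouts are presence/absence of planted sites, not
  transposon biology.
* Variant calling itself (alignment, recalibration, VQSR) is upstream and
  out of scope: the package consumes a finished multi-sample VCF.
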