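# snptracer

Strain traceability for microbial collections via private SNPs and
allele-specific PCR — an end-to-end *in silico* toolkit.

## The problem

Wineries (and any industry running defined microbial starters) must verify
that the strain in a product is the strain on the label. The workhorse assay
for *Saccharomyces cerevisiae*, inter-delta PCR fingerprinting, amplifies
between the delta elements (Ty-retrotransposon LTRs) scattered through the
genome: strains with different delta layouts give different gel band
patterns. Its weakness is resolution — closely related strains share delta
layouts and therefore produce *identical* fingerprints.

`snptracer` implements the SNP-marker alternative: given whole-genome
variant calls for a collection, find **private SNPs** (a biallelic
single-nucleotide variant whose non-reference allele occurs in exactly one
strain), design **allele-specific (ARMS) PCR assays** for them, multiplex
the assays, and read strain identity from gel band sizes. The package
simulates the whole workflow, so a panel can be validated before any
oligonucleotide is ordered.

## The method in brief

- **Private-SNP calling** — a locus is a marker candidate iff both alleles
  are single nucleotides (InDels excluded), every strain is genotyped and
  covered at ≥ 50×, and the alternate allele (het or hom) is carried by one
  strain only.
- **Marker triage** — candidates in polymorphic, repetitive, soft-masked or
  GC-extreme flanks, or whose 3′-anchor 15-mer is non-unique in the
  reference, are flagged; survivors are ranked to spread a strain's markers
  across chromosomes.
- **ARMS design** — per SNP, a wild-type–specific and a variant-specific
  primer share one footprint ending on the SNP (3′-terminal base = the
  allele); both carry an engineered destabilizing mismatch at position −2
  from the 3′ end. Conventional mates are placed so
  |wild-type product − variant product| ≥ 200 bp, with nearest-neighbor
  melting temperatures in a 62 ± 2 °C window.
- **Multiplexing** — 1–6 assays (2–12 primers) per reaction, validated for
  Tm spread ≤ 3 °C, within-strain band separation ≥ 25 bp and absence of
  3′-end primer-dimers, cycled with a touch-down program
  (69.5 → 61.5 °C at −1 °C/cycle, 9 + 25 = 34 cycles).
- **Simulation** — a primer binds iff its 3′-terminal base matches the
  template exactly (≤ 1 internal mismatch tolerated, which accommodates the
  engineered −2 mismatch); amplicons are rendered into gel band patterns,
  colonies are assigned by signature matching, frequencies tallied.
- **Phylogeny** — pairwise counts of unshared variants (allele-presence
  XOR) feed a neighbor-joining tree (own Saitou–Nei implementation, exact
  on additive matrices).
- **Synthetic collections** — a seeded generator plants cluster-shared SNP
  backbones, shared delta layouts and per-strain private SNPs on a toy
  reference, with truth sets, so everything above is testable offline.

## Worked example

A 28-strain collection (one 6-strain cluster, four 2-strain clusters, 14
singletons — the structure of a real oenological panel), fingerprinted,
mined for markers, and genotyped:

```r
library(snptracer)

spec  <- collection_spec(seed = 42L)       # the 28-strain default world
truth <- generate_collection(spec)

snps <- call_private_snps(truth$matrix, min_depth = 50L)
nrow(snps)                                 # 81 private SNPs across 28 strains

# inter-delta fingerprinting cannot separate cluster members:
pats    <- lapply(truth$genomes, interdelta_fingerprint)
classes <- cluster_fingerprints(pats)
length(classes)                            # 19 patterns
sum(lengths(classes) >= 2)                 # 5 multi-strain clusters

# design a 6-assay (12-primer) panel for the 4 cluster-1 strains:
cands <- apply_marker_criteria(snps, truth$reference, truth$matrix)
pick  <- function(s, n) head(cands[cands$strain == s & cands$pass, ], n)
sel   <- rbind(pick("C1.A", 2), pick("C1.B", 2), pick("C1.C", 1), pick("C1.D", 1))
panel <- build_multiplex_panel(design_assays(truth$reference, sel,
                                             matrix = truth$matrix))
panel
#> <multiplex_panel> 6 assay(s), 12 primers, 4 strain signature(s)
#>   C1.A: 150, 190 bp
#>   C1.B: 230, 270 bp
#>   C1.C: 310 bp
#>   C1.D: 350 bp

# genotype colonies from a 1:1:1:1 mixture of the four strains:
four     <- truth$genomes[c("C1.A", "C1.B", "C1.C", "C1.D")]
colonies <- sample_colonies(four, rep(0.25, 4), 12, seed = 7L)
report   <- genotype_colonies(colonies$genomes, panel)
head(report, 3)
#>      colony   bands call
#> 1 colony_01 150/190 C1.A
#> 2 colony_02     310 C1.C
#> 3 colony_03 230/270 C1.B
mean(report$call == colonies$labels$strain)   # 1  (all 12 correct)
tally_frequencies(report$call)$per_strain
#>   strain n percent
#> 1   C1.B 6      50
#> 2   C1.A 3      25
#> 3   C1.C 3      25
```

Each lane's band sizes *are* the strain call: the four strains share one
inter-delta fingerprint (one class), yet every colony is identified
unambiguously by the SNP panel. The thermal program ships with the panel
(`panel$protocol`): 98 °C 2 min; 9 touch-down cycles 69.5 → 61.5 °C; 25
standard cycles at 61.5 °C; 72 °C 5 min — 34 cycles total.

## Layout

- `R/` — genomes/VCF/Newick I/O, variant selection, phylogeny, thermo,
  assay design, in-silico PCR, synthetic data.
- `tests/testthat/` — unit + property suites, oracles in
  `helper-oracles.R`, acceptance criteria in `test-acceptance.R`.
- `vignettes/strain-traceability.Rmd` — model, parameters, numerical
  choices, limitations.
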