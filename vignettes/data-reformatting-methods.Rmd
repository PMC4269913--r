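---
title: "Methods: validated pedigree/genotype reformatting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validated pedigree/genotype reformatting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedforge)
```

## The problem

A genetic study of a human disease rarely ends with one analysis
program.  Linkage, family-based association, population-structure, and
quality-control tools each demand their own input dialect — and each
conversion done by hand or ad-hoc script is an opportunity for silent
data corruption.  pedforge is a validated reformatting engine: it reads
a matched set of pedigree, phenotype, genotype, and map information,
passes it through explicit error-checking and reordering stages, and
writes analysis-ready file sets, with every stage covered by tests
against independent oracles.

The pipeline has four fixed stages — input, error checking, reordering,
output — that all operate on one in-memory object, the dataset: a
pedigree graph, an ordered locus list, a genetic map, a genotype
matrix, a trait table, and a provenance trail.

## The packed genotype store

Storing two 8-byte label pointers per genotype, as naive
implementations do, costs 16 bytes per person-marker.  For biallelic
markers pedforge instead stores one 2-bit code per genotype
(0 missing, 1 homozygous allele 1, 2 heterozygous, 3 homozygous
allele 2), four genotypes per byte, marker-major:

```{r}
pack_codes(c(1L, 2L, 0L, 3L))   # one byte: first code in the low bits
```

Two further choices cut memory and appear throughout the file writers:

* **Untyped individuals are not stored.**  An individual with no
  genotype at all remains a full member of the pedigree graph and of
  every pedigree-bearing output file, but owns no row in the genotype
  store.
* **Half-typed genotypes are demoted to missing** (with a count kept
  on the store).  A single 2-bit code cannot represent "one allele
  known", and downstream formats disagree about how to write it; a
  logged demotion is the least surprising behaviour.

The bit-level layout — first genotype in the least-significant bits,
final partial byte zero-padded — is this package's own convention,
chosen to coincide with the dominant binary genotype file format so
that the binary writer is a plain memory copy.  Loci with more than two
alleles switch the store into a general mode holding an
allele-index-pair table; the two modes decode identically on biallelic
data (a tested invariant).  Phase is never stored: codes are
unordered-pair codes.

## Error checking

**Structural validation** returns findings, never raises: missing
referenced parents, one-parent individuals, fathers not male / mothers
not female (when sex is known), ancestry cycles, duplicate ids as
errors; unknown sex and untyped pedigrees as warnings.  Error-severity
structure findings block the batch pipeline unless an override flag is
set.

**Mendelian checking** is per nuclear family and marker.  A
family-marker is flagged only if *no* completion of missing parental
genotypes permits all typed children under biparental transmission;
completions are enumerated exhaustively over the alleles observed in
the family plus one extra allele (sufficient, because an unobserved
allele's identity never matters to a typed child).  Checking is
deliberately *not* a full-pedigree genotype-elimination: findings stay
attributable to one nuclear family, and the search stays small enough
to verify against brute force.  The test suite compares the checker
with an independent enumeration oracle on all 64 trio configurations
(4 codes for each of father, mother, child) and demands exact
agreement.

Resolution policies: `report_only`, `zero_child` (blank the offending
children), and the default `zero_family_marker` (blank the whole
nuclear family at that marker) — conservative, blames nobody, and
provably a fixed point: re-checking after resolution finds nothing.

**Allele frequencies** are counting estimates over founders by default;
counting all individuals would overweight large sibships.  A locus with
no countable allele falls back to uniform frequencies with a warning.

**Hardy-Weinberg** uses the Pearson chi-square on observed genotype
counts against expected proportions p², 2pq, q² at the sample allele
frequency, 1 df, no continuity correction (an exact test is out of
scope).  Monomorphic markers report chi2 = 0, p = 1 with an info
finding.  Founders-only counting is again the default.  X-linked
markers are excluded from scans by default; male X heterozygotes are
error findings and are blanked before frequency or HWE computation so
they cannot bias either.

## Reordering transforms

* `recode_alleles()` numbers alleles by descending founder frequency
  (ties broken lexicographically), making allele 1 the major allele —
  the LINKAGE-era convention; the operation is idempotent and exports
  an audit table.
* `apply_omit()` blanks (individual, marker) pairs from an omit file;
  a wildcard blanks the whole row, and a fully blanked individual
  leaves the typed set.
* `subset_loci()` selects by chromosome, name list, or inclusive bp
  range (positions are points, so both ends are inclusive); output
  order is always map order.
* `split_by_chromosome()` partitions loci; pedigree and traits are
  duplicated into each piece.
* `to_nuclear_families()` makes each nuclear family its own pedigree
  `<origPed>_F<k>`.  Connector individuals are duplicated into every
  family they belong to *keeping their individual id*, so cross-family
  identity stays traceable (the pedigree id carries the
  disambiguation); parents of duplicated parents are dropped, so the
  parents become founders of the child family.

## Output formats

Nine targets: LINKAGE pre- and post-makeped, PLINK text and binary,
Merlin, SOLAR, Eigenstrat, Structure, FBAT, plus the package's own
annotated bundle.  All writers emit Unix line endings and space
delimiters (comma for the SOLAR pedigree/phenotype files), fixed so
byte-level determinism can be tested.  Format-specific choices:

* The LINKAGE datafile derives inter-marker recombination fractions
  from adjacent sex-averaged map positions through the inverse Haldane
  function θ = (1 − e^(−2d))/2 (d in Morgans); markers 10 cM apart get
  θ ≈ 0.0906.  Classic datafiles cannot carry marker names, so names
  and chromosome labels ride on `#` comments that classic parsers
  ignore — this is what makes a LINKAGE round trip lossless on loci.
* The binary genotype writer emits magic bytes `6C 1B`, SNP-major mode
  byte `01`, then `ceiling(N/4)` bytes per marker with sample 1 in the
  least-significant bits.  Column 5 of the marker table carries the
  code-2 (minor-by-recode) allele and column 6 the major allele; the
  target ecosystem decodes either order correctly from that table, so
  a deterministic documented choice beats guessing.
* SOLAR founders get empty parent fields, LINKAGE-family founders get
  `0` — each format's own dominant convention wins.
* The post-makeped proband is the first-listed member of each
  pedigree's first founder couple: deterministic and reproducible.

Every writer is tested for conservation (individual, marker, and
missing-genotype counts) by an *independent* per-format parsing oracle
written against the format notes above, not against the writer code;
formats with readers are additionally round-trip tested.

## The batch front end

The interactive menus of classic reformatting tools are replaced by a
batch file of `key = value` pairs (plus flag twins on the `pedforge`
command-line wrapper; flags override the file).  The key vocabulary is
this package's own documented dialect.  Stage order is fixed: read,
structure validation, X check, Mendelian check/resolution, frequency
estimation, omission, subsetting, trait selection, recoding, optional
per-chromosome split, write.  Frequencies deliberately follow Mendelian
resolution so zeroed genotypes cannot bias the counts.  Any blocking
error aborts with nonzero status and removes partial outputs, keeping
pipelines idempotent; identical inputs and seed give byte-identical
output trees.

## The simulator

Test data come from gene dropping: founders draw genotypes allele-wise
at the stated frequencies (hence in Hardy-Weinberg proportions), and
each child receives one haplotype per parent built by walking the
marker list with a crossover probability per interval given by the
Haldane function.  Haldane (no interference) was chosen over Kosambi
for its closed-form inverse, which the LINKAGE datafile writer shares.
Defaults — trio / sibship / three-generation structures, 5 cM marker
spacing, biallelic loci — mirror a small microsatellite/SNP panel
study.  All randomness flows from one seed; per-stage seeds are derived
by fixed offsets.

`inject_defects()` plants Mendelian errors by re-drawing a child
genotype to a configuration the family-consistency oracle itself marks
impossible, skipping families where none exists (e.g. both parents
heterozygous) — so detection recall is a sharp 100% test, not a
statistical one.  Family-markers carrying a plant are shielded from the
subsequent missingness pass, which would otherwise erase the evidence.
The returned truth tables are authoritative.

What the simulator does *not* emulate — genotyping error patterns that
are Mendelian-consistent, linkage disequilibrium between founder
haplotypes, population structure, mutation, trait models — bounds what
green tests mean: they certify the mechanics of storage, checking, and
conversion, not robustness to every failure mode of real data.

## Numerical and sizing choices

Fixture sizes in the test suite (up to ~40 three-generation families,
10 markers; one 1,000 x 10,000 storage-width check) keep the whole
suite under a minute while leaving every statistical check adequately
powered: HWE calibration uses 2,000 simulated markers at n = 200,
p = 0.4, where the nominal 0.05 rejection rate is expected within
±0.01; frequency recovery uses 200 founders over 20 seeds against a
3-standard-error band.  Frequency sums are validated to 1e-6.
Recombination fractions read from a datafile are capped just below 0.5
before inversion (θ = 0.5 has no finite map distance).  Chromosome
labels are compared after stripping a `chr` prefix.  A LINKAGE map is
reconstructed with bp equal to the marker index, since LINKAGE files
carry no physical positions — round-trip identity is defined over
pedigree, loci, and genotypes, not the map.

## Known limitations

Phased and polyploid genotypes, CNV/dosage data, BCF input, pedigree
loop-breaking (loops are detected, not broken), exact HWE tests,
likelihood-based error detection, and relationship inference are out
of scope.  Multi-allelic VCF records are dropped by default (or kept in
general mode); they are never split into biallelic records.
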