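# pedforge

Validated reformatting of pedigree and genotype data for genetic
analysis programs.

A family-based or case/control genetic study rarely uses one analysis
program: linkage, family-based association, population structure, and
quality control each have their own — and each has its own strict,
often under-documented input format.  pedforge converts a matched set
of pedigree, phenotype, genotype, and genetic/physical map information
between those formats through an explicit, tested pipeline of four
stages: **input** (LINKAGE, annotated pedigree/names/map bundles,
PLINK text and binary, VCF), **error checking** (structural pedigree
validation, Mendelian-inconsistency detection and resolution,
allele-frequency estimation, Hardy-Weinberg testing),
**reordering** (allele recoding, genotype omission, locus subsetting,
chromosome splitting, trait selection, nuclear-family decomposition),
and **output** (LINKAGE pre/post-makeped, PLINK text and binary,
Merlin, SOLAR, Eigenstrat, Structure, FBAT, annotated).

At its core sit three ideas:

* a **2-bit packed genotype matrix**: biallelic genotypes are stored
  as one of four codes (missing, hom A1, het, hom A2), four per byte,
  marker-major, over typed individuals only — genome-scale data fit in
  memory, and completely untyped individuals cost nothing while
  remaining full pedigree members;
* **Mendelian checking by exhaustive enumeration**: a nuclear
  family × marker is flagged only when *no* completion of missing
  parental genotypes permits all typed children under biparental
  transmission — small enough to verify against brute force, which the
  test suite does on all 64 trio configurations;
* the **Pearson 1-df chi-square for Hardy-Weinberg equilibrium** on
  founder genotype counts against expected proportions
  (p², 2pq, q²) at the sample allele frequency
  p̂ = (2·n_hom1 + n_het)/2n;

plus a **gene-dropping simulator** (founders drawn in Hardy-Weinberg
proportions, haplotypes transmitted with Haldane recombination
θ = (1 − e^(−2d))/2) that generates test data with known truth and can
plant guaranteed-detectable defects.

## Worked example

Simulate three 10-person three-generation families, plant a Mendelian
error, detect and resolve it, test Hardy-Weinberg, and write a Merlin
file set:

```r
library(pedforge)

tab <- simulate_pedigree(3, "three_generation", seed = 11)
ds  <- gene_drop(tab, freqs = c(0.3, 0.5, 0.7), seed = 12)
ds
#> <ped_dataset> 30 individuals (30 typed) in 3 pedigree(s), 3 markers, 0 trait(s)
#>   genotype storage: two_bit mode

inj <- inject_defects(ds, mendel_error_rate = 0.05, seed = 13)
check_mendelian(inj$dataset)
#>   pedigree father mother marker                reason
#> 1       F2     I3     I5     M1 parents_exclude_child
```

One family-marker is flagged: in pedigree F2 the genotypes of the
couple I3 × I5 exclude a child's genotype at marker M1 under any
transmission.  The default resolution blanks that family at that
marker; re-checking then finds nothing.

```r
ds2 <- resolve_mendelian(inj$dataset, check_mendelian(inj$dataset))
rec <- recode_alleles(ds2)$dataset
hwe_scan(rec)
#>   marker n_hom1 n_het n_hom2     p_hat      chi2 df   p_value monomorphic
#> 1     M1      3     6      2 0.5454545 0.1100000  1 0.7401441       FALSE
#> 2     M2      4     5      3 0.5416667 0.3104308  1 0.5774159       FALSE
#> 3     M3      5     5      2 0.6250000 0.1481481  1 0.7003114       FALSE
```

No marker departs from Hardy-Weinberg among the 12 founders (11–12
typed after resolution), as expected for gene-dropped data.  Finally:

```r
write_dataset(rec, "merlin", "out/", "study")
#> study.ped  study.dat  study.map
```

The same pipeline runs non-interactively from a batch file of
`key = value` pairs:

```
input.format  = plink_text
input.ped     = study.ped
input.map     = study.map
output.target = merlin
output.dir    = out
mendel.policy = zero_family_marker
seed          = 7
```

```sh
pedforge convert --batch run.batch          # exec/pedforge, a thin wrapper
```

or from R via `run_batch(parse_batch_file("run.batch"))`.  Identical
config and seed give byte-identical output trees; any blocking error
aborts with nonzero status and removes partial outputs.

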