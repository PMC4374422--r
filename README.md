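# polyArray

SNP array design and genotype-cluster analysis for allo-polyploid crops.

## The problem

In an allo-octoploid such as cultivated strawberry (genome model
AABBCCDD), short reads from all four subgenomes align onto one diploid
reference, so every reference coordinate superimposes up to eight
homoeologous copies. Two consequences dominate array design there:

1. **Most apparent variants are not markers.** A variant that is fixed
   between subgenomes — a *homoeologous sequence variant* (HSV) — is
   present in every panel member and never segregates. Discovery
   pipelines must separate segregating marker variants (present in some
   accessions, absent in others) from HSVs.
2. **Cluster compression.** On a two-channel array, the non-segregating
   subgenomes add constant signal, shrinking the separation between
   genotype clusters. With per-allele intensities `a` and background `b`,
   a cluster centre is

   ```
   A = nA * a + b,   B = nB * a + b
   contrast = log2(A/B),   size = (log2 A + log2 B) / 2
   ```

   so an octoploid AB marker with six fixed B alleles sits at
   `log2(200/800) = -2` instead of a diploid's 0, and its three clusters
   crowd together.

polyArray implements the design methodology built around these two
facts: discovery pipelines for di-allelic SNPs, multi-allelic SNPs
(mSNPs), 3–6 bp indels, and three classes of ploidy-reducing
**haploSNPs** — marker SNPs coupled to a nearby destabilising HSV (a SNP
within 6 bp, a 4–6 bp indel within 14 bp, or a 3–6 bp insertion
containing the marker) so that the probe hybridises to a single
subgenome; probe tiling and probeset accounting with flank, 16-mer and
score screens; a genotype-cluster model with the six array quality
classes (PHR, NMH, OTV, MHR, CRBT, Other), the **HomRO** statistic
(displacement from zero contrast of the homozygous cluster nearest it;
`HomRO = min(contrast_AA, -contrast_BB)`, diploid-like when ≥ 0.3),
and off-target-variant (null allele, ∅) recalling; plus
pedigree-concordance and read-count binomial validation. A fully seeded
synthetic allo-octoploid panel generator (reference FASTA, gene-model
GFF3, per-accession VCFs, read depths, two-channel intensities,
pedigrees, and a ground-truth table) makes every stage testable with no
external data.

## Worked example

```r
library(polyArray)

cfg   <- simConfig(seed = 7, ref_length = 60000L, n_chromosomes = 1L)
panel <- generatePanel(cfg)
tab   <- makePanelTable(panel)
tab
#> PanelVariantTable: 175 distinct variants over 168 sites; 20 files, 19 accessions
#>   subpanels: GDP=20, HD16=10, HD20=8

res <- discoverAll(tab, pipelineConfig(), reference = panel@reference,
                   gene_models = panel@genes,
                   diploid_records = panel@diploid_vcf)
vapply(res, nrow, 1L)
#>      diallelic_snp               msnp              indel    haplosnp_snpsnp
#>                 12                  4                  4                  5
#>  haplosnp_indelsnp   snp_in_insertion diploid_parent_snp        codon_based
#>                  3                  3                  4                623
#>           combined
#>                658
```

Every planted, constraint-satisfying marker in the truth table
(`panel@truth`) is recovered, and none of the 129 planted fixed HSVs is
emitted as a di-allelic candidate: the presence/absence filter (present
in ≥ 2, absent in ≥ 2 subpanel members) removes them, which is the core
of marker-vs-HSV discrimination.

Cluster geometry at two effective ploidies, with the default model
(all constants 100) and 5% multiplicative noise:

```r
g <- matrix(rep(c("AA", "AB", "BB"), each = 50), 1, dimnames = list("m1", NULL))
for (p in c(2L, 8L)) {
  d  <- generateIntensities(g, p, noise_sd = 0.05, seed = 1)
  cl <- callGenotypes(d$contrast, d$size)
  print(homro(cl$centers[c("AA", "BB")]))
}
#> HomRO =  1.595 -> diploid_like     (2x locus)
#> HomRO = -1.210 -> polyploid_like   (8x B-fixed locus)
```

Sequence-derived genotypes from read counts (one-sided binomial test at
the boundary null minor-allele frequency 1/8, ≥ 20 reads):

```r
binomialGenotype(c(20, 30), c(0, 0))
#>    genotype    p_value major
#> 1       het 0.06920876   ref
#> 2 hom_major 0.01820713   ref
```

Probe accounting for a tiling plan — e.g. an mSNP plan with 1,414
both-strand and 347 single-strand sites uses
`accountDesign(tilingPlan("msnp", n_single = 347, n_both = 1414))`:
12,700 distinct probes (4 per tiled strand) interrogated by 19,050
probesets (6 pairwise di-allelic sets per tiled strand).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/polyarray.R`
(`polyarray.R simulate --config cfg.yaml --out DIR`, then `discover`,
`design`, `classify`, `validate`).

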