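# plasmacall

Replicate-aware low-frequency variant calling for amplicon panels on
cell-free DNA (cfDNA), with the digital-PCR and analytical-validation
statistics such assays are qualified with — plus a synthetic-data stack
that emulates the reference-standard dilution and spiked-plasma
experiments used to validate them.

## Who this is for

Developers and validators of amplicon-based circulating tumor DNA (ctDNA)
assays who need a desk-scale, fully inspectable implementation of the
statistical machinery: position-specific background error models fitted
from controls, maximum-likelihood integration of evidence across technical
replicates, thresholds calibrated to a per-base specificity budget,
copy-number inference from normalized depth, SNP contamination checks,
droplet-dPCR Poisson quantification with dual-binomial limits of
detection, and exact binomial validation statistics.

## The model in brief

At each panel position and substitution, control libraries define a
beta-binomial null with mean error rate $\mu$ and overdispersion $\rho$
(method of moments over pseudocounted per-library fractions). A candidate
variant at shared allele fraction $f$ across replicates has per-replicate
alt counts modeled at rate $f + (1-f)\mu$; the call statistic is the
likelihood ratio $\mathrm{LR} = 2\{\ell(\hat f) - \ell(0)\}$ with $\hat f$
the joint MLE, and the threshold on LR is calibrated by simulation from the
fitted background so the expected false calls stay within a per-base
budget (default $3\times 10^{-6}$, i.e. 99.9997% per-base specificity).
For dPCR, the limit of detection combines two binomials at
$\alpha=\beta=0.05$: the critical droplet count is the 95th percentile of
the false-positive binomial, and the detectable occupancy is the smallest
$p$ whose 5th percentile reaches it, giving
$\mathrm{LOD} = n \cdot(-\ln(1-p))$ copies per reaction
($-\ln 0.05 \approx 3.0$ when the false-positive rate is zero). The methods
vignette (`vignettes/plasmacall-methods.Rmd`) derives and motivates every
piece.

## Worked example

Simulate a validation run on a 1 kb toy panel: fit a background from 12
control samples, calibrate the threshold, spike three variants at 0.65%
expected allele fraction into 8,000 amplifiable copies split over 8
replicates, and call:

```r
library(plasmacall)

panel <- toyPanel(nAmplicons = 10, insertLen = 100, seed = 42)
panel
#> PanelDesign: 10 amplicons over 2 genes, footprint 1000 bases
#>   amplicon lengths (primers+insert): 140-140 bp

rates <- syntheticErrorRates(panel, seed = 12)
controls <- do.call(rbind, lapply(1:12, function(i)
  snvCounts(simulateCounts(NULL, panel, rates,
                           sampleName = paste0("C", i), seed = 200 + i))))
background <- fitBackground(AlleleCountTensor(controls))
background
#> BackgroundModel: 3000 SNV entries (0 low-confidence), 0 indel entries
#>   mean error rate: median 2.23e-04, max 1.06e-03

thresholds <- calibrateThreshold(background, budget = 3e-6, nSim = 50,
                                 seed = 77)
round(thresholds$snv, 2)
#> [1] 23.93

truth <- diluteTruth(syntheticTruthSet(panel, 3, stockAf = 0.013, seed = 5),
                     0.5)                       # 1.3% stock -> 0.65% expected
pool  <- sampleMolecules(truth, 8000, seed = 6)  # binomial molecule sampling
split <- splitReplicates(pool, 8, seed = 7)      # multinomial replicate split
tensor <- simulateCounts(split, panel, errorRates = background@snv,
                         sampleName = "PT1", seed = 8)
calls <- callVariants(tensor, background, thresholds, panel)
calls[, c("chrom", "pos", "ref", "alt", "af_mle", "af_pooled", "lr", "status")]
#>   chrom  pos ref alt  af_mle af_pooled   lr status
#> 1  chrT 1229   G   A 0.00715   0.00757  654 called
#> 2  chrT 1907   T   C 0.00585   0.00607  911 called
#> 3  chrT 2275   G   T 0.00725   0.00746 1236 called
```

All three spiked variants are recovered; the maximum-likelihood allele
fractions (0.59–0.73%) track each variant's realized molecule fraction
around the 0.65% expectation, and the LR values sit orders of magnitude
above the calibrated threshold of 23.93. `writeCallsVcf(calls, panel,
"calls.vcf")` emits the calls as VCF 4.3.

The dPCR side, for an assay with a measured per-droplet false-positive
rate of $10^{-4}$ over 15,000 droplets and wild-type occupancy 0.5:

```r
computeLod(fprLambda = 1e-4, nDroplets = 15000, wtLambda = 0.5)
#> dPCR limit of detection (alpha = 0.05, beta = 0.05)
#>   false-positive rate/droplet: 0.0001 over 15000 droplets
#>   critical level: 4 positive droplets
#>   LOD: 9.15 mutant copies/reaction (0.1219% AF at wt lambda 0.5)
```

meaning a reaction is called positive above 4 mutant droplets, and 9.15
mutant copies per reaction are detectable with 95% probability at a 5%
false-positive rate. Exact validation intervals come from
`clopperPearson()`: detecting 238 of 240 variants gives 99.17%
(90% CI 97.40–99.85%).

A thin command-line wrapper over these functions lives at
`inst/scripts/plasmacall.R` (subcommands `call`, `dpcr-lod`, `validate`).

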