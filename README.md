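# vennfallacy

Differential expression studies with a two-group, treatment-vs-control
design often report "group-specific" genes: genes significant in one
group's comparison but not the other's, usually displayed as the
non-overlapping fields of a Venn diagram, and then fed into gene set
enrichment. That procedure is statistically invalid — the difference
between significant and non-significant is not itself significant — and,
worse, it produces enrichment results that *look* biologically relevant:
because false negatives are far more common than false positives, the
"specific" lists are dominated by genes that in truth respond to treatment
in **both** groups, so enrichment finds exactly the pathways of the shared
treatment response.

`vennfallacy` packages this demonstration as reusable, tested machinery
for bioinformaticians and methods teachers:

* a **negative binomial GLM engine** for the 2×2 group × condition design:
  median-of-ratios size factors, Cox–Reid-adjusted per-gene dispersion
  MLE, and Wald tests for the model
  `log2 mu_gj = log2(s_j m_g) + x_j' beta_g` with contrasts
  `trt_in_G1` (treatment effect in group 1), `trt_in_G2`, and
  `interaction` (their difference — the correct test for group-specific
  response);
* **gene set statistics**: hypergeometric overrepresentation (ORA) with
  the standard in-universe size filter, the rank-based CERNO test
  (statistic `-2 * sum_i log(r_i / N)`, chi-squared with `2|S|` df), and
  the signed disco concordance score
  `lfc_A * lfc_B * (|log10 p_A| + |log10 p_B|)`;
* **power arithmetic** for the two-sided two-sample t-test from the
  noncentral t distribution, quantifying the false-negative rate that
  drives the artifact;
* a **synthetic cohort simulator** with known ground truth (NB counts,
  dispersion trend `a0 + a1/mu`, log-normal size factors, shared
  treatment effects, configurable true interaction) plus gene set
  catalogs that concentrate the truly responsive genes; and
* a **replication harness** that runs the incorrect and the correct
  analysis side by side over replicates and over a grid of LFC thresholds
  and sample sizes.

## Worked example

Simulate a cohort with a purely *shared* treatment response (zero true
interaction), run both analyses, and watch the artifact appear:

```r
library(vennfallacy)

params <- simParams(nGenes = 2000, seed = 42)   # 20 samples per cell
truth  <- simulateTruth(params)                 # 10% of genes truly DE,
sets   <- makeGeneSets(truth, seed = 42)        #   identically in G1 and G2
se     <- simulateCounts(truth, params, seed = 43)

res <- runDiffExp(se, degCriteria(fdrThreshold = 0.05, lfcThreshold = 1))
res
#> DEResults: 2000 genes ( 0 filtered ), 80 samples
#>   contrasts: trt_in_G1, trt_in_G2, interaction
#>   trt_in_G1    66 DEGs (fdr < 0.05, |lfc| > 1)
#>   trt_in_G2    63 DEGs (fdr < 0.05, |lfc| > 1)
#>   interaction  1 DEGs (fdr < 0.05, |lfc| > 1)

universe <- testedGenes(res)
vp <- vennPartition(callDEGs(res, "trt_in_G1"),
                    callDEGs(res, "trt_in_G2"), universe)
vp$counts
#>  only_A  only_B    both neither
#>      12       9      54    1925
```

Twelve genes look "specific to G1" and nine "specific to G2" — yet the
truth contains no group difference at all. Almost all of them are false
negatives of the other comparison:

```r
specific <- union(vp$only_A, vp$only_B)
mean(specific %in% truth$gene_id[truth$isDE])
#> [1] 0.952381
```

Enrichment on the "G1-specific" list returns significant,
plausible-looking terms — all of them response-labelled sets, i.e. the
biology of the *shared* response:

```r
ora <- runORA(vp$only_A, universe, filterGeneSets(sets, universe))
head(ora[, c("set_name", "label", "overlap", "expected", "p_value", "fdr")], 4)
#>      set_name    label overlap expected      p_value         fdr
#> 1 response_09 response       4    0.198 2.775409e-05 0.001764201
#> 2 response_05 response       4    0.210 3.528403e-05 0.001764201
#> 3 response_16 response       3    0.144 3.114682e-04 0.010382275
#> 4 response_13 response       3    0.258 1.780217e-03 0.038079511
```

The statistically correct analyses stay silent:

```r
sum(deTable(res, "interaction")$fdr < 0.05, na.rm = TRUE)
#> [1] 2        # ~nominal false positives; median over replicates is 0
sum(runCERNO(rankGenesByP(res, "interaction"),
             filterGeneSets(sets, universe))$fdr < 0.05)
#> [1] 0
```

The false-negative mechanism is plain power arithmetic — even a large
effect (Cohen's d = 0.8) needs 26 samples per group for 80% power, and
80% power still means a 20% false negative rate:

```r
requiredN(d = 0.8)$n_integer
#> [1] 26
fnrFromPower(0.8)
#> [1] 0.2
```

`runReplicate()` and `runGrid()` repeat this comparison over replicates
and over a threshold × sample-size grid; `exportLfcScatter()` produces
the paired-LFC table (with disco scores) recommended as the honest
alternative to the Venn diagram. A thin command-line wrapper with
subcommands `simulate`, `diffexp`, `enrich`, `power` and `study` is
installed at `inst/scripts/vennfallacy.R`.

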