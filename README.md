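# fracscore

Chromatin compaction scoring from sedimentation fractionation sequencing.

Sedimentation-velocity centrifugation of lightly crosslinked, sonicated
chromatin separates 300–500 bp fragments by their degree of local
compaction: open chromatin stays in the top sucrose-gradient fraction
(Fr-1), compact chromatin sediments to the bottom (Fr-5). Sequencing the
DNA of each fraction yields five genome-wide coverage tracks, and the
per-base **Fr-5/Fr-1 score**

```
score(p) = log2( (d5(p) + eps) / (d1(p) + eps) ),   eps = 0.001
```

on wigsum-normalized, recovery-scaled depths summarizes the local
compaction state: strongly negative scores mark locally open chromatin
(active TSSs), scores near zero mark compact chromatin. `fracscore` is
for epigenomics analysts working with such fractionation data — or
evaluating the method itself — and implements the complete downstream
analysis:

* per-fraction coverage, wigsum normalization, score construction, and
  five-class compaction binning with the share of the genome above a
  threshold (default −3.5);
* strand-aware TSS/TES windows (−250 bp to 0, exclusive of the start
  base), repeat-overlap exclusion, window statistics (mean score, rcpm);
* metagene fractional-proportion profiles over gene bodies with fixed
  2 kb flanks;
* nucleosome-free-region depth (max − min MNase occupancy in the TSS
  window) and TSS occupancy curves by expression class;
* gene-level association of the score with expression
  (Low / Mid / High on log10(TPM+1) with the standard thresholds),
  RNAP binding, and TAD structure (per-TAD mean/SD, boundary openness
  at −2.5);
* a seeded synthetic simulator — toy genome, genes, planted compaction
  landscape, binomial sedimentation law, MNase/RNAP tracks, repeats,
  TADs — so the whole pipeline is testable against known ground truth
  with no external data.

## Worked example

The standard demonstration study — one 1 Mb chromosome, 200 genes, a
compaction landscape at baseline 0.8 with Gaussian TSS valleys of planted
depth uniform in [0.2, 0.8], one million fragments — runs in under half a
minute:

```r
library(fracscore)
res <- runPipeline(demoConfig(seed = 101))

cat(sprintf("recovery  r = %+.3f\n", res$fitRecovery$r))
cat(sprintf("TSS~TPM   r = %+.3f   TES~TPM r = %+.3f\n",
            res$fitTssExpression$r, res$fitTesExpression$r))
round(res$classification$percentages, 2)
```

prints

```
recovery  r = +0.981
TSS~TPM   r = -0.733   TES~TPM r = +0.021
      <-4.5 [-4.5,-3.5) [-3.5,-2.5) [-2.5,-1.5)      >=-1.5
       6.87        1.65        2.18        2.72       86.57
```

Reading these numbers: the TSS-window mean score recovers the planted
compaction with Pearson r = 0.98 (the score works as a compaction
readout); expression anti-correlates with TSS compaction (r = −0.73) but
not with TES compaction (+0.02), the planted inverse coupling; and 91.5%
of the toy genome scores above −3.5 — the genome is mostly compact, with
openness confined to valleys at active TSSs. Per-gene values live in
`res$association` (score, TPM, class, rcpm qualification, NFR depth,
RNAP level), and the run directory holds per-fraction BEDs, the score
bedGraph, TSV tables and a JSON manifest; identical config + seed gives
byte-identical files.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package="fracscore"))')" \
    --seed 101 --outdir my_run
```

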