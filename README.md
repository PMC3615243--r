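# tlecad

Computer-aided diagnosis and lateralization of temporal lobe epilepsy
(TLE) from interictal FDG-PET region-of-interest metabolism.

## What it is for

Distinguishing epileptic from non-epileptic seizures (NES), and left
from right TLE, is hard: EEG spikes are rare events, and visual reading
of interictal FDG-PET (iPET) takes years of subspecialty experience.
`tlecad` implements an automated pipeline that operates on the 47
whole-brain-normalized ROI metabolism values of a NeuroQ-style feature
table — not on images — and classifies each patient as LTLE, RTLE, or
NES.  It is aimed at methods researchers in quantitative neuroimaging
who want a complete, reproducible reference implementation of this class
of CAD tool, including its statistical guardrails.

The pipeline, applied inside every cross-validation fold:

* **mRMR feature ranking** on histogram-quantized features: greedy
  selection maximizing the mutual information I(f; c) with the
  diagnosis minus the mean mutual information with already-selected
  features (MID score, in bits), with F features kept and Q quantal
  levels, both set a priori.
* **Cost-sensitive multilayer perceptron** (learning rate 0.3, momentum
  0.2, 500 epochs, inputs range-normalized to [−1, 1]) with instance
  weights chosen to optimize balanced accuracy =
  (sensitivity + specificity)/2; the three-class problem is decomposed
  into three 1-against-1 models combined by majority vote.
* **Cyclical leave-one-out cross-validation** (CL1OCV): every patient is
  held out once, and feature ranking, normalization, costs and training
  are all recomputed without the held-out patient.
* **(F, Q) selection by random field theory**: the balanced-accuracy map
  over an (F, Q) grid is standardized against the naive classifier
  (largest class share), its smoothness estimated from the map, and an
  operating point chosen from the region exceeding the RFT-corrected
  95% threshold.
* **Likelihood-ratio fusion**: for binary tasks, the automated call is
  combined with manual iPET/sMRI reads; every outcome pattern gets
  LR = P(pattern | epilepsy) / P(pattern | NES) with an exact-binomial
  chance median and 95% interval.

A synthetic-cohort generator reproduces the reference study population
(class sizes 32/39/34, covariate distributions, manual-read positivity
rates, lateralized temporal hypometabolism with distributed secondary
effects), so the whole pipeline is testable without patient data.  See
`vignettes/methods.Rmd` for the model details and design decisions.

## Worked example

```r
library(tlecad)

# a 105-patient synthetic cohort at the reference study conditions
cohort <- generate_cohort(default_table1_spec(seed = 7))

# leave-one-out evaluation of the LTLE-vs-NES classifier at F = 6, Q = 4
res <- cl1ocv(cohort, task = "ltle", mrmr = mrmr_config(F = 6, Q = 4),
              hyper = mlp_hyper(hidden_layout = 4), seed = 11)
compute_metrics(res)
#> n = 71  accuracy 0.704 (0.584-0.807)
#>  sensitivity 0.667 (0.498-0.809)  specificity 0.750 (0.566-0.885)  balanced 0.708  OR 6.00
naive_baseline(res$truth)
#> 0.549 (the 39/71 majority share -- the chance bar the classifier must clear)

# illustrative full-cohort feature ranking (fold rankings are recomputed
# per fold and may differ)
mrmr_rank(assemble_features(cohort), config = mrmr_config(6, 4))
#>   rank          feature relevance_bits mrmr_score_bits
#> 1    1  L sl temporal C          0.228         0.22788
#> 2    2  L pm temporal C          0.203         0.06917
#> 3    3 R ilp temporal C          0.121         0.07053
#> 4    4 L ila temporal C          0.156         0.04077
#> 5    5 R ila temporal C          0.125         0.03444
#> 6    6         Midbrain          0.117         0.00663

# chance likelihood ratio when 35 of 71 patients (39 LTLE, 32 NES) share
# an outcome: k ~ Binomial(35, 39/71), LR = k/(35 - k)
chance_lr_interval(n_pos = 39, n_neg = 32, m = 35)$median |> signif(2)
#> 1.2
```

The accuracy 0.704 (95% exact CI 0.584–0.807) beats the 0.549 naive
baseline; the top-ranked ROIs are the left temporal regions where the
generator plants hypometabolism, with contralateral temporal and
midbrain regions carrying secondary, non-redundant signal.

A command-line front end wraps the same functions
(`inst/cli/tlecad.R`; subcommands `simulate`, `rank`, `train-eval`,
`fq-search`, `fuse`, `report`):

```sh
Rscript inst/cli/tlecad.R simulate --seed 4 --out out/
Rscript inst/cli/tlecad.R train-eval --input out/synthetic_cohort.csv \
    --task ltle --f 6 --q 4 --seed 11 --out out/run1
```

## File formats

* **Feature table** (CSV, or TSV by extension): header row; columns
  `id`, `diagnosis` (`NES`/`LTLE`/`RTLE`), one column per atlas ROI,
  optional `age` (years), `sex` (`female`/`male`), `duration` (years),
  `frequency` (events/month), `ipet`, `smri` (`negative`,
  `left_abnormal`, `right_abnormal`, `bilateral_abnormal`; empty =
  report unavailable).  `write_cohort()`/`load_cohort()` round-trip all
  values exactly.
* **Atlas**: one ROI name per line, `#` comments ignored
  (`inst/extdata/atlas_default.txt` is the default 47-region list).
* **Run configuration** (YAML, schema version 1): see `?run_config`.

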