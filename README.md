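# pcmckit

Post-conflict matched-control (PC/MC) analysis of consolation and
reconciliation in bonobos, as a tested, reusable R pipeline.

Ethologists studying conflict resolution record, for every agonistic
conflict, a 10-minute focal follow of the victim (the post-conflict
period, PC) and a matched control (MC): a follow of the same victim on a
conflict-free occasion one or two days later at the same time of day, with
both former opponents within 10 m. Comparing when affiliative contact
arrives in the PC versus the MC separates genuine post-conflict responses
from baseline sociality. This package implements that method end to end
for a semi-free bonobo colony in two groups (36 study subjects plus 6
dependent infants), and pairs it with an agent-based synthetic-colony
generator so every stage is verifiable even though the original raw
observations are not deposited.

## The method in brief

Each retained PC/MC pair is labeled from its first-contact latencies
(censored at the 600 s follow end): **attracted** when the contact came
earlier in the PC or only in the PC, **dispersed** symmetrically for the
MC, **neutral** otherwise. For *consolation* the qualifying contacts are
those initiated by an uninvolved bystander toward the victim; for
*reconciliation*, contacts between the former opponents. Tendency scores
use

    TCT = 100 * (attracted - dispersed) / total pairs

per focal victim (TCT for bystander contacts, CCT for opponent contacts)
or per victim-bystander dyad. Downstream analyses:

* Wilcoxon signed-rank tests (tie-corrected Z, exact small-sample p) on
  per-focal attracted vs dispersed proportions;
* Kaplan-Meier / log-rank (Mantel-Cox) comparison of the censored PC and
  MC latency distributions;
* self-scratching (bouts/min) and self-grooming (s/min) as stress
  proxies, contrasted across PC outcome categories at the
  Bonferroni-corrected threshold 0.05/3 = 0.016;
* binomial-logit mixed models of consolation occurrence over one row per
  (conflict x eligible bystander) with random intercepts for victim,
  aggressor, bystander, group and conflict, selected by exhaustive (or
  stepwise, beyond 10 candidates) AIC search and compared to the null
  model by likelihood-ratio test;
* Gaussian mixed models of dyadic TCT / consolation index with
  simulation-based significance.

The generator's defaults are the study conditions (conflict rate 356
conflicts / 453 h, the printed victim/aggressor class shares and intensity
distribution, scratch rates 0.37 / 0.43 / 0.19 bouts/min); see the methods
vignette (`vignettes/pcmc-methods.Rmd`) for the model, its calibration and
its limits.

## Worked example

A full campaign-scale run (301 + 152 observation hours, a few minutes on
one CPU):

```r
library(pcmckit)
report <- run_all(seed = 1)   # simulate -> validate -> label -> stats -> models
print(report)
```

which prints (seed 1):

```
<pcmc_report>
  385 conflicts, 376 PC/MC pairs, 35 focal victims
  consolation: attracted 60.2% vs dispersed 26.9% (Z = 3.91, p = 9.15e-05); mean TCT = 33.32
  reconciliation: attracted 25.7% vs dispersed 4.5%; mean CCT = 21.21
  latency log-rank: consolation chisq = 69.2, reconciliation chisq = 53.0
  scratch rates (bouts/min): MC = 0.37, PC_both = 0.19, PC_consolation = 0.20, PC_no_affiliation = 0.39, PC_reconciliation = 0.35
```

Reading the numbers: attracted pairs far outnumber dispersed pairs and the
per-focal Wilcoxon rejects the no-consolation null (Z = 3.91, p < 0.001);
bystander contact arrives much earlier in PCs than in matched controls
(log-rank chi-square 69.2 on 1 df); and victims who received consolation
scratch at roughly half the baseline rate (0.20 vs 0.37 bouts/min), while
PCs without affiliation stay at baseline — the stress-alleviation
signature. `report$determinants$occurrence` holds the AIC-selected
occurrence GLMM; with the default generator it retains proximity,
bystander age/rearing, victim-bystander affiliation and kinship, feeding
context, reconciliation and redirection, with signs matching the simulated
hazards.

The same stages can be run as scripts, each writing its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R       # campaign-scale synthetic colony
Rscript analysis/02_validate.R       # schema + matched-control protocol checks
Rscript analysis/03_label_pcmc.R     # attracted/dispersed/neutral labels, TCT/CCT
Rscript analysis/04_social_metrics.R # affiliation indices, opportunity table
Rscript analysis/05_stats.R          # Wilcoxon, log-rank, stress proxies
Rscript analysis/06_models.R         # GLMM selection, reduced runs, dyadic LMM
```

Set `PCMC_SEED` to change the campaign seed.

## Data layout

Datasets live in four diff-friendly CSVs (`roster.csv`, `conflicts.csv`,
`follows.csv`, `scans.csv`); nested event lists are packed into string
columns (`;` between records, `|` within, `id:band` for bystanders), and
`load_dataset()` / `write_dataset()` round-trip exactly. The packaged
roster (`lola_roster()`) and the published campaign summary counts
(`published_counts()`) ship under `inst/extdata/`.

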