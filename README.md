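# clipribo

Integration of cell-type-specific **FMRP CLIP** (crosslinking and
immunoprecipitation) with **RiboTag** ribosome-association profiling, for
quantifying how neuronal activation changes RNA binding and translation.

CLIP tag density on a transcript largely tracks the transcript's
abundance, so `clipribo` quantifies binding *relative to similarly
abundant transcripts*: for each CLIP replicate it fits an ordinary
least-squares line of log2 CLIP TPM on the condition-mean log2 RiboTag
TPM and scores every transcript by its deviation from that line,

```
CLIP score = log2(CLIP TPM) − slope · log2(RiboTag TPM) + intercept
```

(the formula as printed in the source protocol; the ordinary residual
convention, which subtracts the intercept, is also available — the two
differ by a constant `2·intercept` per replicate). On top of the score the
package provides:

* **target tiers** — stringent (score > 2, per replicate or on the mean),
  high (> 1), low (> 0), non-target — and cross-condition classes
  (stringent in both conditions / control-only / opto-only / neither);
* **differential FMRP binding** between activated (Opto) and control
  conditions via a from-scratch empirical-Bayes moderated t;
* **differential ribosome association** via a simplified two-group
  negative-binomial Wald test (median-of-ratios size factors,
  method-of-moments dispersion) with Benjamini–Hochberg control, used for
  both IP-vs-Input enrichment (with a cell-type marker-panel check) and
  Opto-vs-Control;
* the **quadrant model** cross-classifying differential binding against
  differential ribosome association (e.g. FMRP-Down & RiboTag-up =
  candidate ribosome re-association);
* **tag annotation** of genome-mapped CLIP tags (CDS / 3'UTR / 5'UTR /
  noncoding exon / intron / intergenic, maximal overlap with explicit
  precedence) stratified by **biological complexity** (number of
  supporting replicates);
* a **synthetic-data generator** with known ground truth emulating the
  full experimental design (2 conditions × 4 CLIP + 3 RiboTag IP/Input
  replicates), so every stage is testable without external data.

See `vignettes/clip-ribotag-methods.Rmd` for the statistical details and
design decisions.

## Worked example

```r
library(clipribo)

ds  <- generate_dataset(generator_params(n_genes = 1000, seed = 1))
cfg <- pipeline_config(score_convention = "residual",
                       stringency_mode = "mean")
res <- run_pipeline(ds$clip_counts, ds$ribo_counts, ds$models, cfg)
print(res)
#> clipribo_run over 1000 representative transcripts
#>   Control stringent targets: 148
#>   Opto stringent targets: 109
#>   cross-condition classes:
#> stringent_both   control_only      opto_only        neither
#>             98             50             11            841
#>   quadrants:
#>        fmrp_down_ribo_up      fmrp_down_ribo_down fmrp_down_ribo_unchanged
#>                        4                        0                       57
#>          fmrp_up_ribo_up        fmrp_up_ribo_down   fmrp_up_ribo_unchanged
#>                        3                        1                       47
#>   fmrp_unchanged_ribo_up fmrp_unchanged_ribo_down                unchanged
#>                       32                       25                      830
```

The generator planted a +3 binding offset on 10% of genes in both
conditions, a −2 activation shift on 5% (FMRP-Down) and +2 on 1%
(FMRP-Up); the recovered tier counts above (148 control-stringent of 150
planted, 98/50/11 cross-condition classes) reflect that truth. Each
per-replicate abundance fit is available:

```r
res$fits$Control[["1"]]
#> regression_fit [Control rep 1]: slope 0.9867, intercept -0.3482 (n=999)
```

and the differential-binding table ranks transcripts by moderated-t
p-value (`effect` is the Opto−Control CLIP-score difference; the
generator's shifted genes surface at the top):

```r
head(res$clip_diff$table[, c("id", "effect", "p", "padj", "direction")], 3)
#>          id    effect            p         padj direction
#> 1 g00073.t1  3.037892 2.987594e-13 2.984607e-10        up
#> 2 g00919.t1 -2.712221 1.002959e-11 4.028825e-09      down
#> 3 g00167.t1 -2.704355 1.209858e-11 4.028825e-09      down
```

`run_pipeline(..., outdir = "out")` writes every stage table as TSV plus a
JSON quadrant summary and a run manifest; outputs are byte-identical
across reruns at a fixed seed. A thin command-line wrapper with
`simulate` / `all` / `annotate` subcommands is installed at
`inst/scripts/clipribo`.

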