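# toxitext

Dose-stratified keyword mining for social-media toxicosurveillance in R.

Recreational use of dextromethorphan (DXM), an over-the-counter cough
suppressant with dissociative effects at high doses, is hard to monitor
through surveys or poison-centre data. Comments on drug-related videos
discuss both doses and effects, and clinical toxicology describes four dose
*plateaus* (100–250, 250–400, 450–800, >800 mg), each with characteristic
signs and symptoms. `toxitext` implements the full text-mining pipeline
that tests whether those clinical descriptions can be recovered from such
comments — built for epidemiologists and clinical-informatics researchers
who want a reproducible, offline-testable version of this kind of
syndromic-surveillance analysis.

The pipeline:

1. **Corpus IO** — JSON-lines comment corpora; each comment carries a
   16-digit Uniform(0,1) sampling key so any key range `[lo, hi)` draws the
   same random subset every time, even as the corpus grows.
2. **Preprocessing** — non-ASCII removal, punctuation deletion (so
   "drunk-high" fuses to "drunkhigh", as in real pipelines of this kind),
   case folding, stopword removal (English/French/Spanish + internet
   slang/elision lists), digit stripping after dose extraction.
3. **Dosing** — dose-mention extraction (`375mg`, `1.5g`, `600
   milligrams`), conversion to mg, binning into half-open plateau ranges
   `[100,250)`, `[250,450)`, `[450,800)`, `[800,∞)`.
4. **Keyword statistics** — each plateau's pooled text is one document;
   terms are scored with length-normalised tf-idf,
   `tfidf(t,p) = (c(t,p)/Σc(·,p)) · ln(N/n_t)`, and keywords must strictly
   exceed the greatest of the per-plateau 75th-percentile thresholds of the
   nonzero-score distributions.
5. **Semantics** — a bundled 50-node WordNet-style taxonomy with synsets;
   path similarity `1 − L(a,b)/diameter`; a Yes/Maybe/No
   medical-relatedness rubric from hypernym hops to medical seed nodes.
6. **Comparison** — the medically-related keyword table is scored per
   plateau against a clinical symptom lexicon (per-keyword best-match
   similarity) and compared with a size-matched unenriched control corpus
   by two-tailed Mann–Whitney tests, per plateau and pooled.
7. **Synthetic data** — a generator with known ground truth (negative-
   binomial lengths modal at 15–20 words, dose mixture peaking at 375 mg,
   plateau-confined symptom slang at 5× background rate, slang/non-ASCII/
   punctuation-fusion noise) replaces the original corpus so everything
   runs and validates offline.

## Worked example

The numbered drivers under `analysis/` run the whole study; each writes
its tables and figures under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess_dose.R
Rscript analysis/03_keywords.R
Rscript analysis/04_compare.R
```

Stage 1 generates the corpora:

```
generated 2000 treatment comments (697 with dose mentions, 34.9%)
injected 12 plateau-specific symptom words at 5x background rate
control corpus: 2000 comments, no symptom enrichment
```

Stage 2 confirms the corpus shape the analysis assumes — modal comment
length bin `[9, 18)` words, and a modal dose bin `[200, 400)` mg containing
the 375 mg generator peak. Stage 3 extracts the keywords and checks them
against ground truth:

```
plateau pools: 134/323/145/95 comments; 1303 excluded (no in-range dose)
global tf-idf threshold: 0.000584 (75th percentile, max over plateaus)
keywords per plateau: 6/8/7/11
medically related keywords (Yes category):
  plateau 1: buzzed, racing, jittery
  plateau 2: dizzy, trippin, wobbly
  plateau 3: numb, floating, slurred
  plateau 4: blackout, overdosed
ground-truth recovery: 92% of injected words in their true plateau, 0 in wrong plateaus
```

The injected symptom vocabulary surfaces in the right plateaus (11 of the
12 injected words here; "puking" fell just under the global threshold),
and no injected word leaks into a wrong plateau. Stage 4 runs the clinical
comparison:

```
pooled: median similarity 1.000 (drug corpus) vs 0.375 (control), U = 81.0,
        two-tailed p = 0.000151 (n = 9 vs 9)
```

The drug-corpus keywords sit essentially on top of the clinical symptom
lexicon (median path similarity 1.0) while size-matched control keywords do
not (0.375), and the pooled two-tailed Mann–Whitney test rejects equality
well below the 0.01 level.

Programmatic use mirrors the scripts:

```r
library(toxitext)
res <- run_synthetic_comparison(generator_config(seed = 1))
recovery_rate(res$treatment$keywords, res$truth)
res$comparison$pooled$p_value
```

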