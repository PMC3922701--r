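---
title: "Dose-stratified keyword mining: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-stratified keyword mining: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxitext)
```

## The surveillance problem

Dextromethorphan (DXM) is an over-the-counter antitussive whose metabolite
dextrorphan is an NMDA antagonist: at supratherapeutic doses it produces
dissociative effects, and its recreational use is hard to track through
surveys or poison-centre calls. Free-text comments on drug-related videos
discuss both the amounts ingested and the effects experienced, and clinical
toxicology describes four dose "plateaus", each with characteristic signs
and symptoms (roughly: mild stimulant effects at 100--250 mg;
ethanol/marijuana-like intoxication with occasional hallucinations at
250--400 mg; a ketamine-like dissociative, "out-of-body" state at 450--800
mg; and full dissociation, with death reported at the highest doses, above
800 mg).

`toxitext` implements the complete analysis from raw short-text comments to
that clinical comparison: reproducible keyed sampling of a comment corpus,
noise-tolerant preprocessing, dose-mention extraction, plateau binning,
plateau-level tf-idf keyword extraction, a taxonomy-based medical filter,
and a path-similarity comparison of the extracted vocabulary against the
clinical symptom lexicon, with an unenriched control corpus and a
Mann--Whitney test. Because no public comment corpus exists, a synthetic
generator with known ground truth replaces the original data; every stage
of the pipeline is exercised and validated offline.

## Corpus model and keyed sampling

A corpus is a table of `(id, text, key, source_tag)` stored as JSON-lines.
Each comment carries a Uniform(0,1) sampling key with 16 decimal digits,
assigned once and stored with the record. Any half-open key range
`[lo, hi)` then defines a reproducible random subset: `[0, f)` draws a
fraction-`f` sample, and disjoint ranges draw disjoint samples, stable as
the corpus grows. Keys are canonicalised through their 16-digit decimal
representation at assignment, so writing a corpus and reading it back
reproduces the keys bit-for-bit.

## Preprocessing

Normalisation applies, in order: removal of characters that cannot be
encoded in ASCII, deletion of non-alphanumeric ASCII characters,
case-folding, whitespace tokenization, stopword removal, and (only once
comments have been assigned to plateaus) removal of digits. Two points are
deliberate:

* **Punctuation is deleted, not blanked.** Deleting intra-word punctuation
  turns "don't" into "dont" and "drunk-high" into "drunkhigh" — the fused
  tokens characteristic of this kind of pipeline. The stopword list
  therefore includes elision variants (`dont`, `im`, ...) so that
  apostrophe loss does not let stopwords leak through. A `punct = "space"`
  switch is available for users who prefer cleaner token boundaries.
* **Digits survive until dose extraction.** Dose parsing needs `375mg`
  intact; digit stripping happens when tokens are pooled by plateau, so
  dose numerals never become plateau vocabulary.

Stopwords ship as plain-text English, French and Spanish lists plus a
custom list of elision variants and internet abbreviations (`lol`, `jk`,
`ftw`, ...). The custom list is this package's own curation; the previously
published custom list is no longer retrievable, so ours is documented but
not identical to it.

## Dose extraction and plateau binning

Dose mentions are number+unit patterns (`mg`, `milligram(s)`, `g`,
`gram(s)`, fused or spaced), converted exactly to milligrams. The printed
clinical ranges overlap at 250 mg and leave a 400--450 mg gap, so the
implemented bins are half-open and contiguous: `[100, 250)`, `[250, 450)`,
`[450, 800)`, `[800, Inf)`, with the gap absorbed into plateau 2 and the
bounds configurable. Doses under 100 mg (therapeutic) are excluded, as are
doses above 5000 mg (default, configurable), which we treat as hyperbole.
Comments mentioning several in-range doses are assigned by their first
mention (options: `first`, `max`, `drop`); each pooled comment contributes
its tokens to exactly one plateau.

## tf-idf over plateau documents

Each plateau's pooled text is one document. For term $t$ in plateau $p$:

$$\mathrm{tfidf}(t, p) = \frac{c(t, p)}{\sum_{t'} c(t', p)} \cdot
  \ln\frac{N}{n_t}$$

with $c$ the term count, $N$ the number of non-empty plateau documents
(four in any standard run) and $n_t$ the number of documents containing
$t$. Term frequency is length-normalised so the largest pool gains no
advantage; a term present in every plateau has idf 0 and can never be a
keyword. The log base is configurable (natural by default); changing it
rescales all scores uniformly and cannot reorder keywords.

Per plateau, the keyword threshold is the 75th percentile of that plateau's
*nonzero* score distribution, and the greatest of the four thresholds is
applied globally. Three numerical choices here were genuinely open:

* **Percentile definition**: linear interpolation between order statistics
  (`stats::quantile` type 7), with nearest-rank available as an option.
* **Strict exceedance**: keywords must score strictly above the threshold;
  ties at the threshold are excluded.
* **Nonzero-only ECDF**: structural zeros (terms absent from a plateau or
  present everywhere) are excluded from the percentile computation; in
  sparse vocabularies including them would collapse the 75th percentile to
  zero and make every positive-scoring term a keyword.

## Taxonomy, path similarity and the medical filter

Semantic relatedness uses a rooted hypernym/hyponym taxonomy. The package
bundles a 50-node mini-taxonomy with a drug branch (analgesics such as
meperidine and methadone, diuretics such as furosemide, dissociatives,
stimulants, depressants), a clinical-condition branch (gastrointestinal,
neurological, cardiovascular and psychiatric symptom groups plus injuries)
and an everyday-object branch, together with a synset table mapping surface
words — including slang such as "puking", "trippin", "wobbly" — onto
concept nodes. Both files are synthetic fixtures in WordNet's style, not
extracts of WordNet, so all tests run offline; an edge-list adapter lets
real deployments substitute a full lexical database, in which case the
exact diameter is replaced by a documented approximation (hierarchy depth
times two) because exact all-pairs shortest paths over a full WordNet are
impractical.

The default similarity between concepts $a$ and $b$ is the complement of
the shortest-path/diameter ratio,

$$\mathrm{sim}(a, b) = 1 - \frac{L(a, b)}{\mathrm{diameter}},$$

which is 1 exactly at identity and 0 for diameter-separated pairs. The
toolkit-style reciprocal form $1/(1+L)$ is available behind a `measure`
switch; the complement form is the package default because it is the
definition the analysis is built around. Polysemous words take the maximum
similarity over sense pairs, the standard convention. Word-set comparisons
score each keyword by its best match (max) over the reference terms.

The Yes/Maybe/No medical-relatedness rubric walks each word's hypernym
chain toward the root: a medical seed node (the symptom, injury or drug
subtree heads) reached in fewer than $k$ hops gives **Yes**, at exactly
$k$ hops **Maybe**, otherwise **No**, with $k = 3$ by default. A manual
override file is consulted first, replacing interactive curation; words
with no taxonomy node are logged and classified No.

## The control comparison

The published comparison sets the medically-related keyword table of the
drug corpus against words from an equivalently sized sample of popular
videos. We reproduce that construction: the treatment side is the
Yes-filtered keyword table, the control side the raw keywords of an
unenriched corpus; both are scored per plateau against the clinical symptom
lexicon, size-matched by down-sampling the larger side (after taxonomy
lookup, so unmappable fused tokens cost no sample), and compared with a
two-tailed Mann--Whitney test. The per-keyword best-match similarity is the
sample unit — the only reading under which a rank test is well-formed.
Because the published significance level is a single figure, the pooled
test (all plateaus concatenated) is reported alongside per-plateau tests
with Holm adjustment.

The Mann--Whitney implementation uses the exact null distribution of $U$
when there are no ties and the smaller sample has at most 8 observations
(two-tailed $p = 2\min(P(U \le u), P(U \ge u))$, capped at 1), and a
tie-corrected normal approximation with continuity correction otherwise.
The test suite checks it against full enumeration of all group labellings
for every small sample size, and against the standard library
implementation.

## The synthetic generator

The generator emulates, with known ground truth, the features the analysis
depends on:

* **Lengths**: negative-binomial (size 12, mean 16, shifted by a 3-word
  minimum), putting the modal comment length in the 15--20 word band with a
  heavy right tail — Poisson lengths would be too concentrated.
* **Doses**: 35% of comments mention a dose, drawn from a plateau mixture
  (weights 0.20/0.45/0.22/0.13) with per-plateau triangular distributions
  peaking at 150/375/600/900 mg, so the overall mode is 375 mg and the
  support spans 100--1500 mg. Mentions are rendered in the formats the
  extractor must parse (`375mg`, `375 mg`, `1.5g`, `600 milligrams`) and
  every rendered string re-parses to its true milligram value.
* **Symptom enrichment**: each plateau has three slang symptom words
  (e.g. "puking", "blackout", "overdosed" for plateau 4) injected only into
  that plateau's dosed comments at `multiplier` (default 5) times the
  median background-word frequency, and nowhere else. Zero background rate
  is deliberate: it makes the confinement of enrichment — and hence the
  wrong-plateau error of the pipeline — measurable exactly, and a
  multiplier of 0 removes a word entirely.
* **Noise**: slang insertion drawn from the custom stopword list (with
  apostrophes restored half the time, so normalisation is exercised),
  occasional non-ASCII tokens, hyphen-fused word pairs, capitalisation and
  trailing punctuation.
* **Background vocabulary**: a Zipf-weighted common head plus a sparse tail
  of rare words. The tail is what makes the threshold machinery realistic:
  rare words land in one or two plateau pools by chance and populate the
  nonzero tf-idf distribution that sets the 75th-percentile threshold. Tail
  words are mapped into the taxonomy's object branch by the synset table,
  as they would be in a full lexical database, so control keywords obtain
  (low) similarity scores rather than vanishing at lookup.

The control generator shares the length, noise and dose models but injects
no symptom vocabulary.

What the generator does **not** model: grammar and word order, discourse
across comment threads, sarcasm and hyperbole beyond the implausible-dose
cutoff, misspellings other than punctuation fusion, and the unknown
relationship between commenters and the wider population. Passing tests
therefore demonstrate that the pipeline recovers the statistical structure
it assumes — not that real comment corpora have that structure.

## Problem sizes and validation

The test suite and the acceptance script use 2000-comment corpora over ten
generator seeds for the end-to-end checks — large enough that each plateau
pool holds roughly a thousand or more tokens and recovery statistics
stabilise, small enough to keep the whole suite fast on a single CPU.
Smaller corpora (400--1500 comments) back the distributional and
conservation checks, and the tf-idf, path-similarity and Mann--Whitney
cores are validated against independent brute-force oracles (direct
per-term recomputation, Floyd--Warshall shortest paths, exhaustive
labelling enumeration) on toy fixtures. The end-to-end checks assert the
two designed properties of the study conditions: the pipeline recovers at
least 90% of injected symptom words in their true plateau (median over
seeds, with zero wrong-plateau placements), and the pooled enriched-vs-
control Mann--Whitney p-value falls below 0.01 in the majority of seeds.

## Known limitations

* Plateau assignment trusts the first in-range dose mention; nothing
  verifies ingestion, dose accuracy or tone — inherent to the data source.
* The bundled taxonomy is small; similarity values on it are coarser than
  WordNet's and its diameter (8) caps the resolution of the similarity
  scale at increments of 1/8.
* Statistical specificity is not semantic relevance: a term can be a
  legitimate plateau keyword while being medically irrelevant, and the
  Yes/Maybe/No filter only approximates the manual curation it replaces.
* Unit support covers mg and g; volume-based dosing ("half a bottle")
  is product-dependent and deliberately unparsed.
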