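---
title: "Discovering venom-gland-specific transcripts and toxin candidates"
author: "arachnotox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering venom-gland-specific transcripts and toxin candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arachnotox)
```

## The problem

Venomous spiders concentrate their toxin repertoire in a single tissue.
Comparing RNA-seq expression of the venom gland against non-venom
tissues (here: silk gland and cephalothorax with the venom gland
removed) isolates the transcripts that the gland is specialised to
express, and those are the natural search space for toxins: latrotoxins
(very large ankyrin-repeat neurotoxins), small disulfide-rich
inhibitor-cystine-knot (ICK/knottin) peptides, latrodectins, CRISPs and
venom enzymes. `arachnotox` implements that discovery path as a tested
pipeline over five kinds of input: transcript sequences (FASTA),
per-tissue expected read counts with effective lengths (an RSEM-style
table), a best-hit homology annotation table, signal-peptide calls, and
venom shotgun-proteomics peptide identifications. A seeded synthetic
generator with planted ground truth makes every stage testable without
sequencing data.

## The model, stage by stage

### Best protein per transcript

Open reading frames are enumerated stop-to-stop in all six frames,
discarding ORFs under 90 nt (the conventional 30-residue floor). Codons
containing `N` translate to `X` and never terminate an ORF, so
ambiguous bases cannot fragment a real coding region. The best protein
is the longest ORF in the frame of the transcript's best homology hit
(longest overall when there is no hit), except that a
methionine-initiated ORF wins when (i) its parent ORF is bounded by
literal stop codons on both sides — the signature of a potentially
full-length coding sequence, a sequence end does not qualify — and
(ii) the M-started sequence reaches at least 75% of the longest
predicted ORF. The override is considered across all frames, since a
stop-bounded full-length ORF is better evidence than a longer unbounded
fragment wherever it lies. Ties break by frame order
(+1, +2, +3, −1, −2, −3) then position; reverse-frame coordinates are
reported on the forward strand, 0-based half-open.

### Redundancy collapse

Assembled transcript sets retain distinct nucleotide sequences encoding
identical proteins. Proteins *identical over their entire region of
overlap* — implemented strictly as exact substring containment, which
is deterministic where an alignment-based 95/95 rule is not — are
linked into single-linkage clusters; the longest member represents each
cluster, the first-encountered member among co-longest ties. The
operation is idempotent.

### Venom-gland-specific transcripts (VSTs)

Counts are normalised to expected counts per million within each
tissue, $\mathrm{eCPM}_{ti} = 10^6 c_{ti} / \sum_j c_{tj}$, and to
FPKM, $c_{ti} / (\ell_i^{kb} \cdot \sum_j c_{tj}/10^6)$, for comparing
abundance among transcripts. Two rules define the VST set:

* **exclusive** — venom eCPM > 1 with *zero* eCPM in both other
  tissues;
* **ratio** — among the remaining transcripts with any venom
  expression, both ratios (venom/silk and venom/cephalothorax eCPM)
  fall in the upper 2.5% of their distributions, and venom eCPM ≥ 1.

The 2.5% cutoff is a nearest-rank quantile (the value at ascending
position $\lceil 0.975\,n\rceil$), attained by `>=`, because "top
2.5%" is a rank statement. A zero denominator yields an infinite ratio
that ranks above all finite values: a transcript absent from one
comparison tissue is more specific, not less. The reference
distribution is the remaining transcripts (venom eCPM > 0, not
exclusive); both choices are recorded in the run metadata because
plausible alternatives exist (e.g. including transcripts below one
venom eCPM). The realized fold cutoffs per comparison tissue are
reported alongside the classification — they are the run's analogue of
a "306-fold over silk, 32-fold over cephalothorax" statement.

### Toxin screens

Homology descriptions are mapped to toxin categories by an ordered,
editable keyword rule set (first match wins, so `latrotoxin`
outranks a generic `toxin` rule) under a 1e-5 e-value cutoff;
transcripts with no qualifying hit are `no_hit`, annotated transcripts
matching no rule are `other`. Independently of homology, small
cysteine-rich proteins (< 200 residues, ≥ 6 cysteines — the minimum
for the three disulfides of an ICK fold — N-terminal methionine
required by default) are flagged as candidate novel knottins. For each
candidate the cysteine framework is computed on the mature region
(after the annotated signal cleavage) and a transparent spacing rule
marks ICK candidates: a near-adjacent cysteine pair (spacing ≤ 1)
among cysteines 3–6 and first two inter-cysteine spacings ≤ 16.
Machine-learned toxin classifiers and knottin connectivity predictors
are deliberately out of scope; the spacing rule is fully configurable
and inspectable, trading fidelity for reproducibility.

### Family clustering sweep

Putative gene families are single-linkage clusters over pairwise local
alignments: an edge requires both percent identity over the aligned
columns and coverage of *both* sequences to reach the cell's
thresholds, swept over a 30–95% grid (step 5). Scoring is fixed and
logged — BLOSUM62, gap existence 11, extension 1 (a length-$k$ gap
costs $11+k$) — with a deterministic traceback (diagonal over
vertical over horizontal; gaps close eagerly; end cell at the smallest
indices among maxima). Because co-optimal alignments differ between
orderings of the pair, the pair is canonicalised (lexicographically
smaller sequence first) so similarity is symmetric. Pairs with no
positive-scoring alignment contribute no edge at any threshold, and
cluster growth is provably monotone under threshold relaxation.

### GO overrepresentation with length-bias correction

Long transcripts are more likely to clear count-based thresholds, so a
naive hypergeometric test over-calls categories rich in long genes.
The correction fits a probability-weighting function — the proportion
of VST membership per length bin (20 quantile bins), regularised by
isotonic regression in the direction of the observed
length–membership correlation and rescaled to sum to the VST count —
and replaces the analytic null with explicit weighted resampling:
draws of $|VST|$ background transcripts without replacement with
probability proportional to the weights
(Efraimidis–Spirakis exponential keys), giving
$p = (1 + \#\{count \ge observed\})/(1 + N)$. With uniform weights
this converges to the hypergeometric tail, which the tests verify.
Benjamini–Hochberg step-up control flags terms at FDR 0.05. The
background is the expressed set (venom eCPM > 1). Isotonic binning
was chosen over a monotone spline for having no tuning beyond the bin
count; the resampling route was chosen over a Wallenius approximation
because it is directly checkable against closed forms.

### Proteome-confirmed secretome

Venom peptide identifications are mapped onto the predicted proteins
at every occurrence, treating isoleucine and leucine as
interchangeable (they are isobaric in mass spectra; the flag is
switchable). Peptides below 0.95 probability are discarded; a protein
is venom-confirmed when its protein probability exceeds 0.95 and at
least two unique peptides (distinct sequences after I/L
canonicalisation) map to it. Peptides shared across proteins count for
every match — no razor/parsimony logic — with coverage the
percentage of residues under the union of placement intervals.
Confirmed proteins are cross-tabulated by VST membership and predicted
signal peptide: the proteome-confirmed secretome report.

## The synthetic world

`generate_bundle()` emulates the three-tissue study design at desk
scale. Defaults: 2,000 broadly expressed transcripts, 100
silk-specific, and 12 venom-specific families of 4–8 paralogs, half
short secreted ICK-like proteins (exactly 8 mature cysteines behind a
hydrophobic signal) and half long latrotoxin-like proteins (a
family-specific 33-residue ankyrin-like unit in tandem array,
~460–720 aa — real latrotoxins are ~1200–1400 aa; the length is
scaled down for alignment cost, not structure). Venom families are
500-fold enriched in venom tissue; 55% are planted as strictly
exclusive (zero expression elsewhere), matching the roughly
55/45 exclusive/ratio split such studies observe. Counts are negative
binomial (dispersion 0.05, the low end of bulk RNA-seq from one
library per tissue) scaled to 5M/1.5M/5M expected counts — one tenth
of the venom/silk/cephalothorax read depths the design emulates.
Paralogs diverge from a family ancestor by 10% substitutions that
never touch cysteines or the initial M, so planted families sit near
80% within-family identity and every paralog still passes the
cysteine screens. Proteins are reverse-translated with uniform
synonymous codons; UTRs are uniform over multiples of 3 in 30–300 nt
so the coding sequence sits in frame +1, with a planted in-frame stop
at the end of the 5' UTR making the truth protein recoverable as a
stop-bounded M-start ORF. Tryptic peptides (cleave after K/R, not
before P, ≥ 7 residues) of the secreted proteins are detected with
probability 0.9 and spiked with shuffled decoys at low probability.

What the generator does **not** emulate: read-level error and
alignment ambiguity, positional coverage bias, isoform structure,
chimeric assembly, homology across family boundaries, or real
mass-spectra. A green test therefore establishes correctness of the
*rules* on a faithful miniature, not performance on real libraries.

One planted behaviour deserves emphasis: at the permissive (30, 30)
clustering cell, the ICK-like families merge into a superfamily
cluster. That is not a defect — short proteins sharing a hydrophobic
signal and eight anchored cysteines (BLOSUM62 scores C/C at +9)
sustain positive alignments over more than half their length, exactly
as real knottin superfamilies cluster at permissive thresholds. Exact
family recovery at (30, 30) is accordingly asserted for the long
latrotoxin-like families; for ICKs the tests assert that families are
never split and that the superfamily merge happens.

## Numerical choices and degenerate inputs

* Nearest-rank quantile with `>=` attainment; infinite ratios
  participate and can become the cutoff when the reference set is
  mostly zero-denominator.
* Fewer than 40 transcripts in the ratio reference distribution
  triggers an instability warning rather than an error.
* An all-zero tissue is an error naming the tissue; non-positive
  effective lengths are errors.
* `N`-containing codons translate to `X`, never to stop.
* Alignment tie-breaks and pair canonicalisation as above; the plain-R
  test oracle implements the same stated conventions independently.
* The resampling p-value uses the add-one form, so $p \in (0, 1]$ and
  a planted term can never report zero.
* Peptides are kept at probability `>= 0.95` while proteins require
  `> 0.95` ("in excess of"), implemented literally.

## Limitations

Assembly, read mapping, abundance estimation, signal-peptide
prediction and spectrum identification are upstream inputs, not
reimplemented. GO annotations are taken as given (no ancestor-term
propagation). The keyword rule set ships as an editable YAML default,
not a claim about any particular annotation vocabulary. With one
library per tissue the specificity classification has no
within-tissue variance estimate — the generator supports `n_reps > 1`
for power exploration, but the classifier itself expects one column
per tissue.
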