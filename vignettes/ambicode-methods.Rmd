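---
title: "Methods: inferring ambiguous genetic codes and context-dependent termination"
author: "ambicode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring ambiguous genetic codes and context-dependent termination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Some ciliates translate all 64 codons as amino acids while still
terminating translation at UAA/UAG/UGA: the same triplet is read as sense
deep inside a coding sequence and as stop near the transcript end. This
package implements the computational machinery for studying that regime
on transcript-level data:

1. **Genetic-code inference** from profile-alignment evidence. Six-frame
   translations (dedicated stops recorded as `"X"`) are searched with
   protein-family profiles; every aligned pair of (consensus amino acid
   *j*, underlying codon *i*) surviving two filters contributes a count
   m[i, j] to a 64 x 20 matrix. The codon's translation is called as the
   amino acid with the maximal per-codon share.
2. **Poly(A)-anchored transcript-end analysis**: tail detection, primary
   stop calls in the 60-nt terminal window, 3' UTR length distributions
   (lengths exclude the stop codon and the tail), positional codon counts
   walking in-frame codons backward from the poly(A) site, and a
   proximal-vs-distal depletion contrast for candidate stop codons.
3. **Ribosome-profiling evidence**: footprint filtering (25-32 nt, at
   most one mismatch), per-length frame distributions, 3'-end
   metaprofiles around anchor codons, classification of the termination
   signature (terminating footprints end 11-12 nt past the stop codon's
   last base), and per-transcript readthrough estimation (footprints
   extending at least 13 nt past the primary stop).
4. **Evolutionary utilities**: pairwise dN/dS by Nei-Gojobori (1986)
   pathway counting under arbitrary code tables, stop-codon usage
   summaries, and fourfold-degenerate-site composition with the
   UAA-usage-versus-A-content regression.
5. A **synthetic-data generator** producing transcriptomes, alignment
   record streams and footprints with full ground truth, so that every
   stage is testable without any external download.

# Conventions

* Coordinates are 1-based and closed throughout, following the
  Bioconductor containers the package is built on (`DNAStringSet`,
  `GRanges`, `IRanges`). `polya_site` is the 1-based position of the
  first tail adenosine.
* Codons are keyed as DNA (`TGA`, not `UGA`) internally; reports print
  RNA-style codons.
* The dedicated stop marker `"*"` is distinct from `"X"`; recording
  stops as `"X"` is an explicit translation mode, not a property of the
  code table.
* A `GeneticCodeTable` carries an `ambiguousSet`: codons translated as
  sense that can nevertheless act as stops near transcript ends. The
  stop set used by transcript-end analyses is the union of dedicated
  stops and the ambiguous set.

# The inference matrix and its two normalisations

The printed scaling of the count matrix divides each entry by the sum of
counts **for each amino acid** (M = m[i,j] / sum_i m[i,j]); this is the
form a sequence-logo renderer expects and is what `exportLogoMatrix()`
writes. For *calling* codon translations, however, per-amino-acid scaling
distorts codons of abundant amino acids, so `predictCode()` works on
per-codon shares (each codon row divided by its total). Both
normalisations are computed by `normalizeMatrix()`; the dual output
reproduces the logo while keeping calls well-defined.

Calls require `min_support = 10` aligned pairs per codon and a winning
margin of `ambiguity_margin = 0.1` over the runner-up share. These two
thresholds are this package's choices (exposed in the configuration):
low-frequency entries in the matrix reflect the codon mutational space
and noise, so an unthresholded argmax would over-call rare codons. A
dedicated stop codon never occurs inside coding sequence, so it
surfaces as `UNASSIGNED`; labelling such codons *candidate stops* is the
transcript-end module's job, not the matrix's.

The filters follow the source method exactly: conditional e-value
strictly below `1e-10`, column conservation (modal-residue frequency of
the profile column) at least 50% inclusive, and no `N` in the matched
codon. Conservation is taken from the record stream as supplied: the
package cannot recompute it without the seed alignments behind each
profile, so a profile-search front-end must provide it (the simulator
writes it).

# Transcript ends

`detectPolyA()` reports the longest terminal adenosine run (tolerating
`max_mismatch` non-A bases, trimming any non-A prefix) of at least
`min_tail = 8` nt. For **assembled transcripts** the pipeline default is
`max_tail_mismatch = 0`: with AU-rich 3' UTRs, allowing one mismatch
lets the detector bridge a single genomic non-A base and absorb upstream
genomic adenosine runs into the tail, which we measured to shorten UTR
medians by 1-2 nt and distort the zero-length-UTR fraction on simulated
cohorts. Mismatch tolerance remains available (and is the function-level
default) for read-level tail evidence, where sequencing errors motivate
it.

The primary stop is the most 5' in-frame stop-set codon whose first base
lies within 60 nt of the poly(A) site. Transcript ends follow the
tail-completion convention: the final in-frame codon may borrow 0, 1 or
2 tail adenosines to complete its triplet. Consequently a UAA stop
abutting the tail is callable even though its adenosines are
indistinguishable from tail adenosines; its UTR length is 0. Two
explicit outcomes replace silent choices: a window containing no
stop-set codon yields *no call* (the transcript is a 3'-UTR-less or
unresolved candidate), and ties cannot arise because the scan is
strictly positional (most 5' wins).

Positional codon counts index codons by the 3-nt-resolved offset d of
the codon's first base upstream of the poly(A) site (d = -3 is the
final, possibly tail-completed codon). The depletion contrast compares a
codon's frequency between a proximal window (default -90 <= d < -42,
upstream of the approximately -39 nt boundary below which most
stop-set codons are true stops or UTR codons) and a distal
coding-sequence window, with a two-sided binomial test of the proximal
count against the distal frequency. Two caveats are deliberate:

* The contrast is run on **coding-restricted** counts (codons 5' of each
  transcript's primary stop). 3' UTRs carry in-frame stop-set codons
  roughly every five codons, so including them would contaminate the
  proximal window for any transcript whose UTR reaches past -42 nt; the
  depletion question is about coding sequence.
* The binomial form treats the distal rate as known and is mildly
  anticonservative at cohort scale; `test = "fisher"` gives the exact
  two-sample contrast. The default remains the binomial contrast, and
  `flagged` requires both p below `alpha` and a ratio below 1.

# Ribosome profiling

Footprint geometry, not occupancy modelling, carries the signal:
terminating footprints end 11 or 12 nt after the stop codon's last
base, and readthrough is defined as a footprint 3' end at least 13 nt
past it. Metaprofile offsets follow the display convention in which the
anchor codon occupies positions 1-3, so a terminating end sits at
offsets 14-15 of a stop-anchored profile; `classifyTermination()`
reports modal offsets relative to the stop's 3' nt (11/12) and the
fraction of profile ends they carry.

The per-transcript readthrough rate is
`n_downstream / (n_downstream + n_stop)`, where `n_stop` counts ends
bearing the termination signature (exactly 11/12 nt past the stop) and
`n_downstream` counts extensions of at least 13 nt. The denominator
anchored at the stop is one of several defensible choices (footprints
across the whole CDS, or fixed windows, are others); it is isolated
behind `estimateReadthrough()`, and a density-ratio alternative
(`method = "density"`, equal windows downstream and upstream of the
stop) is provided. Cohort summaries (mean, median, fraction zero) are
computed over covered transcripts only: terminating plus downstream
footprints strictly greater than `coverage_min = 20`.

One interaction deserves note: if a sense stop-set codon occurs a few
codons upstream of the true stop, `findPrimaryStop()` calls it primary
and every footprint at that transcript then looks like readthrough.
This inflates apparent cohort readthrough in proportion to the sense
usage of stop-set codons near ends — which is precisely the
counterselection pressure that depletes such codons there. Estimator
calibration should therefore be assessed against known stop positions
(as the package's tests do); on real data the inflation is part of the
biology being measured.

# NG86 dN/dS

Synonymy is always evaluated under the supplied `GeneticCodeTable`, so
genes containing reassigned codons (e.g. in-frame UGA = Trp) are
handled correctly. Site counts use, at each codon position, the
synonymous fraction among non-stop single-base alternatives, so that
every position contributes exactly one site (N + S = 3 x codons).
Differences average over all mutational pathways between two codons,
excluding pathways through stop codons; in the rare case that every
pathway is blocked, all pathways are used with stop-creating steps
counted as nonsynonymous. Proportions are Jukes-Cantor corrected; the
ratio is flagged undefined when dS is 0 or saturated. The intended use
here is regime classification (purifying selection, ratio well below 1),
not precise rate estimation — a maximum-likelihood codon model is the
right tool for the latter.

# The synthetic-data generator

`simConfig()` fixes the study conditions; its defaults are the
conditions under which the acceptance properties are evaluated.

| parameter | default | what it emulates |
|---|---|---|
| `code` | fully ambiguous (UAA/UAG=Q, UGA=W, all context-dependent) | the most demanding variant code |
| `n_transcripts` | 2000 | a poly(A)-tailed single-gene cohort |
| `n_families` | one per transcript | distinct single-copy genes |
| `family_length` | 160 codons | CDS long enough to span the distal window |
| `sense_usage` | 0.001 | rare ambiguous sense codons (order 0.1% of codons) |
| `utr_zero_prob`, `utr_nb_size`, `utr_nb_mu` | 0.1, 12, 24 | zero-inflated, median-22-nt AU-rich 3' UTRs |
| `utr_at` | 0.7 | AU-rich untranslated ends |
| `stop_probs` | UAA 0.70, UAG 0.15, UGA 0.15 | UAA-dominated stop usage of AT-rich genomes |
| `utr_stop_prob` | 0.2 per UTR codon | about five codons between successive downstream stops |
| `depletion_factor`, `depletion_window` | 0.3 over [-90, -42) | proximal decline of sense stop-set codons |
| `rpf$length_probs` | peaked at 30 nt over 25-32 | footprint lengths |
| `rpf$frame3_prob` | 0.8 | 3'-end frame bias of elongating footprints |
| `rpf$term_prob`, offsets | 0.9 at +11/+12, remainder +8..+10 | termination geometry with slight under-digestion |
| `rpf$readthrough` | 90% zero, exponential mean 0.15 otherwise | majority-zero per-transcript readthrough |

Design notes:

* One master seed drives every stage; each stage derives its own
  substream (fixed offsets), so stages can be re-run independently and
  identical configurations are byte-reproducible.
* **Poly(A) canonicalisation.** Terminal genomic adenosines are
  indistinguishable from the untemplated tail, so the recorded
  ground-truth `polya_site` is the start of the maximal terminal A run
  (the tail absorbs trailing UTR adenosines and up to two adenosines of
  a terminal UAA/UGA stop). Without this, "exact" tail-detection
  comparisons would be ill-posed.
* One family per transcript is the default because shared families place
  the same consensus columns at the same distance from every member's
  end, creating positional composition lumps that a real multi-gene
  cohort does not have and that break the depletion test's binomial
  null. Shared families remain available for studying the inference
  stage specifically.
* Footprint 3'-end imprecision is placed on the short side (+8..+10)
  only: noise at +13 and beyond would be readthrough by definition, and
  the generator keeps the two notions distinct so that estimator
  calibration is meaningful.
* The readthrough footprints terminate at the first downstream stop-set
  codon when one exists, mirroring the observation that extensions are
  short because downstream stops are close.

What the generator does **not** emulate: rRNA contamination, ligation
and nuclease sequence biases, assembly errors or chimeric transcripts,
isoform mixtures sharing a poly(A) site, codon-usage bias beyond the
reassigned codons (synonymous codons are drawn uniformly), and indel
sequencing errors. Passing tests therefore demonstrate correctness of
the estimators under the stated statistical structure, not robustness
to every artefact of real libraries; on real data, the upstream choices
(assembly, mapping, frame inference, profile search) dominate several
of these quantities, and codon-usage fractions in particular depend on
the database and cutoffs used for frame inference.

# Problem sizes used in the checks

The package's property checks run at the cohort sizes stated with each
condition: 2000-transcript cohorts (five seeds, five code variants) for
full code recovery with at least 25 filtered pairs per sense codon;
about 5000 terminating footprints for termination geometry; 520
transcripts at 40 stop-situated footprints each for readthrough
calibration across rates 0, 0.005, 0.02 and 0.10; a 2000-transcript
depleted cohort plus 100 null cohorts of 400 transcripts for the
depletion test; and the exhaustive 61 x 61 sense-codon grid for NG86.

# Known limitations

* The HMMER domain-table format carries no aligned codon/consensus
  pairs, so the record stream must be produced by a front-end that
  walks the profile alignments; the package defines the tabular record
  format and consumes it, but does not run the search.
* Reading frames come from annotation (or the simulator); frame
  inference from homology search is out of scope.
* `detectPolyA()` cannot distinguish templated from untemplated
  adenosines without a genome reference; calls on A-rich 3' ends are
  canonicalised rather than resolved.
* The depletion contrast assumes positional homogeneity of base
  composition; `baseFrequencyProfile()` provides the companion flatness
  check used to validate that assumption on any cohort.
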