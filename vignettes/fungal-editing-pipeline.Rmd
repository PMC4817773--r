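---
title: "Detecting fungal A-to-I mRNA editing: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fungal A-to-I mRNA editing: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungedit)
```

## The biological model

A-to-I editing deaminates adenosine to inosine in mRNA; reverse
transcription reads inosine as guanosine, so an edited position appears as
an A-to-G mismatch between RNA-seq reads and the genome, *on the
transcribed strand*. In sexual-stage fungal tissue (perithecia) this
happens at thousands of sites, predominantly in coding sequence, while
vegetative stages show no enrichment of A-to-G among RNA-DNA variants. The
package treats that stage contrast as a first-class property: the
simulator's truth table assigns every planted site to a condition, and a
condition without planted sites is the negative control in which the
substitution spectrum must be flat.

A special consequence class motivates a dedicated detector: genes whose
open reading frame contains premature UAG stops that editing converts to
UGG tryptophan. Automated annotation tends to hide such stops inside
spurious introns (the gene model "looks" clean but the intron is actually
coding). `detect_puk1_like()` reverses that process: it extends the
upstream reading frame through each annotated intron that contains an
intronic A-to-G call and emits a call when the edited A is codon position 2
of an in-frame UAG and the retained frame stays open.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the study conditions the package is built
around: two stages (`hyphae`, `perithecia`) with editing confined to
perithecia; per-site editing levels drawn uniformly from 3–100%; two
biological replicates; 150-bp paired-end reads from a dUTP-style
strand-specific protocol (read 2 carries the sense strand — the protocol is
configurable because library chemistry varies); uniform per-base error
(default 0.001, a Phred-30-grade substrate); 10% PCR duplicates emitted as
exact coordinate-and-sequence copies; homozygous genomic SNPs as
confounders; and PUK1-like pseudogenes whose tandem stop-codon sites form
one haplotype group edited at level 0.9 on shared molecules (mirroring the
observation that ~90% of covering transcripts carry both G's).

Real introns and the pseudogenes' fake introns both use canonical GT..AG
boundaries, so the detector cannot shortcut on splice motifs. Fake introns
are codon-aligned by construction; a frame-breaking intron is exactly what
the open-frame test must reject, and a dedicated test constructs one.

Deliberately not modeled: indels, splice-discovery reads, quality-score
distributions (flat Phred only), GC or positional coverage bias,
heterozygosity, and hyper-edited read clusters. Consequently, green tests
demonstrate the *logic* of the pipeline — strand handling, deduplication,
filter semantics, frame arithmetic, statistics — not robustness to every
artifact of real libraries. Quality-floor filters (base/mapping Phred 20)
are therefore configurable pass-throughs here rather than exercised
defenses.

Gene expression weights are planted so that a few genes (pseudogenes
first) are silent outside perithecia and a few are boosted within it. At
toy library sizes FPKM is strongly compositional — silencing a third of
the genes inflates everything else — so planted fold changes compress; the
expression tests compare ranks rather than absolute folds, and the
categorical rules are verified on constructed records.

## The filter cascade

`filter_config()` defaults: pooled coverage ≥ 10, pooled alternate reads
≥ 3, editing level ≥ 0.03 (the floor of levels observed in this system),
alternate support required in **every** replicate, exclusion of positions
with ≥ 5% alternate allele in the DNA pileup (genomic variants), and
strand purity ≥ 0.9 (fraction of alternate evidence on the transcribed
strand). All filters are pure per-site predicates: the surviving set is
the intersection, order is irrelevant, and removed sites carry their full
list of failed filters in an audit table. An optional per-site binomial
test against the configured error rate exists but is off by default — the
cascade is deliberately a set of hard filters, not hypothesis tests.
Replicates are pooled *after* the per-replicate presence check.
Multi-allelic positions keep the single most-supported alternate; the rest
are logged.

The equal-error-rate FDR estimator summarizes the outcome: with all
non-A-to-G calls presumed false and errors spread evenly over the 12
substitution types, `FDR = (N_non/11)/N_AG`, reported as a percentage with
two decimals. It is homogeneous of degree zero in the counts and undefined
at `N_AG = 0`.

## Annotation choices

* UTR proxies: 500 bp upstream of the start codon and downstream of the
  stop codon stand in for UTRs (genomes of these fungi mostly lack
  annotated UTRs). Feature precedence is CDS > intron > UTR proxy >
  intergenic, and overlapping transcripts resolve to the longest CDS.
* Editing-level bins are `<30%`, `30–60%`, `>60%`; both boundary values
  fall in the middle bin (the published bin labels leave the boundaries
  open; a choice had to be made and is documented here).
* The amino-acid scheme is a standard 4-class table (nonpolar / polar /
  acidic / basic) chosen to reproduce the named examples (K basic, E
  acidic, S polar, G nonpolar); it is plain data (`AA_CLASSES`) and
  swappable, so cross-class percentages on other schemes are one argument
  away.
* The standard genetic code is assumed.

## Context and structure statistics

Context windows are computed on the spliced transcript, not the genome, so
splicing is respected. The control is a uniform, seeded, without-
replacement sample of adenosines from the same cDNA set (default 30,000,
scaled down automatically in the demo when the toy transcriptome has fewer
A's). Significance per position-base cell uses a two-sample proportion
z-test by default — the tool historically used for two-sample logos cites
a t-test on indicator variables, which is asymptotically the same thing;
both are available. No multiple-testing correction is applied by default
(matching common two-sample-logo practice); a Bonferroni flag exists.

Folding uses ViennaRNA's `RNAfold` (37 °C, default parameters) when the
executable is on the PATH; otherwise a bundled base-pair-maximization
folder (pair energies GC −3, AU −2, GU −1 kcal/mol, minimum hairpin loop
3 nt, deterministic traceback) keeps the pipeline self-contained. The two
backends agree on designed test cases, and element classification is a
pure function of the dot-bracket string, so it is backend-independent by
construction: paired → stem; unpaired positions classify by the number of
helices emanating from the loop closed by the innermost enclosing pair
(0 → hairpin, 1 → internal/bulge — merged, since published element
diagrams do not separate them in text —, ≥2 → multibranch); unpaired and
unenclosed → exterior. "Hairpin MFE" is interpreted as the free energy of
the enclosing hairpin substructure — the maximal helix stacking on the
closing pair plus its loop, refolded in isolation — not of the whole 61-nt
window; absolute MFEs therefore depend on the backend and are never
asserted against published values. Windows truncated at transcript ends
keep the site and carry a flag.

## Numerical and degenerate-input conventions

* All serialized coordinates are 1-based inclusive (GFF3/SAM); transcript
  orientation is used for all editing-level and codon arithmetic.
* Duplicate collapsing keys on (contig, leftmost position, mate leftmost
  position, transcript orientation); two genuine fragments with identical
  coordinates also collapse — accepted and documented, since coordinate
  keys are all a real aligner-based workflow has.
* `haplotype_cooccurrence()` with no co-covering fragments returns `NA`
  fractions with a warning rather than inventing a value.
* Empty site sets produce header-only files; an empty edited set produces
  an empty enrichment table; a single-site edited set reports frequencies
  but never significance.
* Every stochastic step derives its stream from one master seed and a
  stage label, so whole runs are bit-reproducible per seed.

## Problem sizes

The test suite simulates genomes of 2–50 genes (roughly 10–150 kb) at
25–100× coverage with two replicates; the headline recovery experiment
plants 200 sites at 100× with 20 SNPs and completes in well under a
minute, and the full suite in about a minute on one core. These sizes were
chosen as the smallest at which binomial sampling error is comfortably
below the tested tolerances (3 standard errors at per-site depths near
200 pooled reads).

## Known limitations

* Recall near the 3% level floor is intrinsically coverage-limited: at
  100× pooled depth a site at level 0.05 occasionally pools below the
  floor. The recovery criterion is therefore stated at ≥ 99%, not 100%.
* The pseudogene open-frame test spans only the annotated intron; whole-
  model re-annotation from coverage is out of scope.
* FPKM-based fold changes are compositional; on small synthetic libraries
  the categorical rules are exact but absolute folds are not.
* The bundled folder maximizes weighted pairs; it is not a full
  nearest-neighbor model and its MFEs are comparable only within a run.
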