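---
title: "Read-level de-noising of 1D genomic coverage: methods and design"
author: "chromsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level de-noising of 1D genomic coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

## The problem

ChIP-seq, CUT&RUN, CUT&Tag and ATAC-seq experiments produce 1D coverage
tracks in which genuine biological signal (transcription-factor binding,
histone marks, open chromatin) is mixed with substantial technical noise.
The classical remedies — input-control or spike-in experiments, or analytic
background models fitted per assay — are costly, sometimes infeasible, and
assume a background distribution that new assay types may not follow.

chromsieve takes a different route: it decides, *read by read*, whether the
coverage a fragment sits in could have arisen by chance placement on its own
chromosome. Reads that could not are "pass" (signal); the rest are "fail"
(noise). The pass pile-up is then a de-noised track on which a SICER-style
island caller produces peaks. No control experiment and no parametric
background model is needed: the background is estimated empirically from the
data themselves.

## The enrichment test

Let a fragment of length $L$ sit on chromosome $c$ with observed statistic
$x$, the exact mean of the full pile-up over the fragment's own span, minus
the fragment's own contribution (see *Self-subtraction* below). The
empirical null is obtained by placing $N$ pseudo-reads of length $L$
uniformly at random on $c$ (start positions uniform on the valid range) and
recording the same exact interval mean at each placement, yielding sorted
null values $m_1 \le \dots \le m_N$. The p-value is the add-one empirical
estimator

$$ p = \frac{1 + \#\{i : m_i \ge x\}}{N + 1}, $$

which is a valid p-value under the placement null, never zero, with floor
$1/(N+1)$; ties count toward the null. All fragment p-values are then
adjusted genome-wide with the Benjamini–Hochberg step-up procedure, and a
fragment passes iff its q-value is at most the nominal FDR level.

Defaults are an FDR of 0.2 with $N = 5000$ pseudo-reads; a stringent
analysis uses 0.1 with the same $N$. A stringent FDR risks discarding real
signal, while too few pseudo-reads limit the attainable significance (the
p-value floor is $1/(N+1)$, and with $m$ fragments BH can only reject when
$p \lesssim \text{fdr} \cdot k/m$). In our calibration simulations the pass
fraction moves by well under one percentage point between $N = 2500$ and
$N = 5000$, so 5000 buys a comfortable margin at modest cost.

### Null sharing and binning

Sampling a separate null per read would cost $\text{reads} \times N$
interval queries. Instead, fragments are grouped by (chromosome,
fragment-length bin); each group shares one null of $N$ placements sampled
at the group's *median* fragment length. The default bin width is 50 bp,
narrow relative to the smoothness of interval-mean distributions in
fragment length, so the approximation error is far below sampling noise.
The observed statistic is still computed on each fragment's own exact span.

### Self-subtraction

A pseudo-read measures coverage at a random location; it does not add a
read there. An observed fragment, by contrast, contributes exactly +1 to
every base of its own span in the pile-up it is being tested against. If
the observed statistic kept that contribution, every fragment would sit one
coverage unit above its own null and the test would be anti-conservative
everywhere — in calibration simulations the realised false discovery
proportion roughly triples the nominal level. chromsieve therefore
subtracts 1 from each observed mean by default (`selfSubtract = TRUE`),
putting the statistic and its null on the same footing. The subtraction is
exact, not an approximation: a fragment's own mean contribution over its
own span is exactly 1. The flag can be disabled for sensitivity analyses.

### Randomness and reproducibility

One user seed governs the run. Each (chromosome, length-bin) group draws
its null from a substream seeded deterministically by (seed, chromosome
name, bin index), so results are independent of iteration order and of any
future parallelisation, and two runs with the same inputs and seed are
bit-identical. The sampler restores the caller's RNG state.

### Exclusion regions and degenerate input

Optionally, a BED of assembly gaps or blacklist regions can be supplied;
pseudo-reads overlapping it are redrawn (up to 1000 rounds, then a hard
error — at that point the exclusion set leaves no room and the run is
misconfigured). By default no exclusion is applied. A fragment longer than
its chromosome is a data error and aborts the run.

## Exact interval queries

The per-read statistic requires on the order of $10^5$–$10^9$ exact
interval means per dataset, so the query primitive matters. chromsieve
builds, per chromosome, a prefix-sum structure over the run-length encoded
coverage: run start positions, run values, and cumulative mass before each
run. An interval sum is two $O(\log \text{runs})$ lookups; the mean is the
sum over the width. Cumulative masses are stored as doubles, which hold
integers exactly to $2^{53}$, far beyond genome-scale coverage mass, so
integer-track means are exact rationals. Interval maxima scan the runs
overlapping the query. Both are verified in the test suite against
per-base brute force and against `IRanges` views on 10,000 random queries.

## The island caller

Peak calling on the pass pile-up follows the SICER window/gap/island
scheme with its canonical defaults: non-overlapping 200 bp windows, each
fragment assigned to the window containing its midpoint; a window with
count $k$ is *eligible* iff $P(X \ge k) < p_0 = 0.2$ under
$X \sim \text{Poisson}(\lambda_w)$; runs of eligible windows separated by
gaps of at most $g = 600$ bp merge into islands whose score is the sum of
member window scores $-\ln P(X \ge k)$. Each island receives a Poisson
tail p-value on its total count with the rate scaled to its length, and
islands are kept at an island-level FDR of 0.01.

Two design choices depart from a mechanical reading of the scheme, both
forced by calibration:

* **Background rate from the parent library.** $\lambda_w$ uses the size
  of the sequencing library the fragments came from, divided by the
  effective genome length. When the caller runs on the de-noised pass
  subset, the parent library is the full input: enrichment is a claim
  relative to the experiment's depth, and rating the pass subset against
  its own thinned density would reward the thinning itself — on
  calibration data it floods the output with small clusters of
  false-pass reads (precision 0.09 against planted truth). With the
  parent-library rate the same run achieves precision 1.0 at recall 1.0.
  For a raw library the default (`backgroundCount = length(fragments)`)
  reduces to the classical rate. The pipeline wiring
  (`runDenoise`, `runPeaks`) passes the original library size
  automatically.
* **Multiplicity over windows, not candidates.** Candidate islands are the
  extreme tail of one Poisson test per window genome-wide. Adjusting only
  across candidates would condition on significance already achieved, so
  the BH adjustment uses $n = \lceil \text{effective genome length} / w
  \rceil$ as the number of tests (`p.adjust(p, n = nWindows)`); ineligible
  windows count as tests with larger p-values. Under a homogeneous
  background this keeps the expected island count near zero.

The full SICER aggregate-score background recursion and summit calling are
out of scope; the window/gap/island structure, which defines the method's
behaviour, is preserved.

## The synthetic-data generator

`simulationSpec()` / `simulateFragments()` produce labelled data for
calibration: background fragments with start positions uniform over the
genome (chromosomes weighted by length) and signal fragments with start
positions uniform within planted regions (regions weighted by width),
fragment lengths from a truncated normal — default mean 200 bp, sd 30,
bounds 50–500 bp, matching typical ChIP/CUT&RUN fragmentation. Planted
regions are either given explicitly or auto-placed disjointly with a
minimum gap (default 5 kb) so that truth regions are unambiguous for
precision/recall. Signal placement is uniform within a region — a flat-top
peak, not a summit shape — which is the minimal model sufficient to
exercise the classifier.

What the generator does *not* emulate: GC and mappability bias, duplicated
reads, copy-number structure, summit-shaped enrichment, and the long-range
correlation structure of real chromatin noise. Passing calibration here
shows the statistics are implemented correctly and control what they claim
to control under the stated model; it does not certify performance on any
particular real dataset.

## Calibration conditions

The standard calibration mixture used by the test suite and the
reproduction script is one 10 Mb chromosome carrying 100,000 background
fragments plus 10,000 signal fragments in 25 planted 2 kb regions
(20-fold mean enrichment inside regions), classified with 5000
pseudo-reads, five independent seeds. On this mixture the realised false
discovery proportion among pass reads (by generator label) averages below
the nominal level at both 0.2 and 0.1, island calling on the pass reads
recovers the planted regions at precision and recall $\ge 0.9$, and
zero-signal runs pass essentially nothing and call no peaks. Problem sizes
were chosen so the whole calibration runs in a few minutes on one CPU
while keeping per-window counts and pass-set sizes in the regime where the
asymptotics of BH and the Poisson background are meaningful.

Note one subtlety of label-based FDP: a background-labelled fragment that
happens to fall inside a planted region genuinely sits in enriched
coverage, is correctly passed by the test, and still counts as a "false"
discovery against the labels. The label FDP is therefore a conservative
upper bound on the test's actual error rate.

## Numerical choices

* Empirical p-values are computed by binary search on the sorted null;
  ties count toward the null. Observed and null statistics flow through
  the identical prefix-sum code path, so equal intervals give bitwise
  equal doubles and tie handling is deterministic.
* Poisson tails use `ppois(k - 1, lambda, lower.tail = FALSE)` and are
  floored at the smallest positive normal double before taking logs or
  adjusting, since island counts in strong peaks underflow the tail to 0.
* Coordinates are handled as `GRanges` (1-based, closed) throughout, the
  native Bioconductor convention; conversion to and from the 0-based
  half-open BED/bedGraph convention happens only inside `rtracklayer` at
  the file boundary. One internal convention eliminates off-by-one drift.
* bedGraph output omits zero runs and merges adjacent equal-valued runs
  (the run-length representation does this by construction), so
  write-then-read is the identity on tracks.

## Known limitations

* The placement null is uniform within a chromosome; regional biases
  (mappability, GC, copy number) are not modelled and will inflate pass
  rates in systematically over-covered regions unless an exclusion BED is
  supplied.
* Null sharing assumes interval-mean distributions vary slowly with
  fragment length within a 50 bp bin; exotic length distributions may
  warrant a narrower bin.
* The island caller's simplified significance model (Poisson tail on the
  island count) is deliberately cruder than SICER's score-distribution
  recursion; it preserves ranking and location behaviour but island
  p-values should not be compared across datasets.
* Single-cell input is treated as bulk; barcodes are ignored.
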