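---
title: "Coverage mixtures, core reads and candidate organisms: the methods behind gdvprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage mixtures, core reads and candidate organisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the estimation choices and
the known limitations of `gdvprofile`, at the level of detail a user needs
to judge what the numbers mean and what the bundled validation does and does
not demonstrate.

## The measurement model

A whole-genome shotgun experiment samples reads approximately uniformly from
each community member's genome, so each organism has a well-defined
sequencing depth proportional to its cell abundance (apart from effects such
as extreme GC bias, which we do not model). When those reads are mapped to a
*reference* genome that shares only part of its sequence with the sampled
organism, the reference decomposes into two region classes: shared regions,
covered at the organism's depth, and unshared regions, covered not at all
(save for spurious hits). The **genome–dataset validity (GDV)** of the
reference is the fraction of it that the dataset provides evidence for; it
is a read-based measure of the genomic distance between the reference and
the organism. Unlike an average nucleotide identity, which only looks at
whatever aligns, the GDV is penalized by everything that does not: one
horizontally transferred gene at 99 % identity still yields a GDV near zero.

### Coverage mixture (depth ≥ 1×)

The per-position coverage depth $x$ on a reference is modelled as

$$f(x \mid \alpha, \lambda) \;=\; \alpha_1\, z(x) \;+\; \alpha_2\,
P(x \mid \lambda) \;+\; \alpha_3\, T_\lambda(x),$$

with mixing weights $\alpha_i \ge 0$, $\sum_i \alpha_i = 1$:

* $z$ — a point mass at $x = 0$: the *structural* zeros of unshared regions
  (a zero-inflated Poisson construction; Poisson zeros in shared regions are
  handled by the next component).
* $P(\cdot \mid \lambda)$ — Poisson; $\lambda$ is the local sequencing depth
  on shared regions, the quantity reported as `depth`.
* $T_\lambda$ — a heavy right tail absorbing repeat pileups and
  divergence-induced skew. We use the normalized Poisson survival mass
  $T_\lambda(x) = \Pr(\mathrm{Poisson}(\lambda) \ge x)/\lambda$ for
  $x \ge 1$ (and 0 at $x=0$). The normalizer is exact because
  $\sum_{x \ge 1} \Pr(X \ge x) = E[X] = \lambda$.

Then $\mathrm{GDV} = 1 - \alpha_1$.

**Fitting.** The mixture is fitted to the coverage-depth *histogram* (so the
cost is per distinct depth value, not per genome position) by EM.
Initialization: $\alpha = (z_0, (1-z_0)/2, (1-z_0)/2)$ with $z_0$ the
observed zero fraction, and $\lambda$ the mean of non-zero depths. The
E-step and the $\alpha$ update are standard; because $\lambda$ appears in
both the Poisson and the tail component, the $\lambda$ update maximizes the
expected complete-data log-likelihood of both components jointly by 1-D
numerical optimization (`optimize`). Each accepted step therefore cannot
decrease the observed log-likelihood, and the implementation asserts this
(the log-likelihood trace is exposed on the fit object and checked in the
tests). Convergence is declared at a relative log-likelihood change below
$10^{-8}$; the iteration cap is 5000. The cap is deliberately generous: the
zero-split between $\alpha_1$ and the Poisson zeros is a slow EM direction
(at 2× depth, meeting the tolerance takes on the order of $10^3$
iterations), while one iteration on a pooled histogram costs microseconds.

**Histogram truncation.** Depth bins above the 99.9th percentile of
non-zero-depth positions are pooled into the top retained bin. Extreme
pileups on repeats otherwise contribute a handful of enormous depth values
that distort the tail fit.

**Degenerate input.** An all-zero histogram ("no coverage evidence") is an
error at the fitting level; the profiling layer maps it — and any other fit
failure — to GDV 0 with a `fit_failed` flag and the naive depth, so one
broken reference cannot halt a run.

### Spacing mixture (depth < 1×)

Below 1× most positions have depth 0 or 1 and the coverage histogram
carries little information, but the *spacings* between consecutive read
start positions still do. Within shared regions, read starts are
approximately a Poisson process with per-base rate $r$, so spacings are
geometric with success probability $p = 1 - e^{-r}$; spacings that jump
across an unshared region are systematically longer. We fit a
three-component geometric mixture by EM (success-probability MLE
$p_k = N_k / \sum_d d\,\gamma_k(d)$; monotone by construction; same
tolerance and cap as above). Spacings are computed within each member
sequence after sorting starts, then pooled — never across a sequence
boundary. Duplicate starts are recorded as spacing 1, the smallest value
the geometric supports.

Two post-fit identification choices matter:

* **Anchoring the shared regime.** The within-shared-region regime is the
  component with the *largest weight*, not the largest success probability:
  within-region spacings always outnumber the one-per-gap jumps, whereas a
  small chance cluster of near-coincident read starts can produce a tight,
  low-weight component that would otherwise masquerade as the shared regime.
* **Pooling split components.** On single-regime data EM happily splits one
  geometric across two near-identical components; all components whose mean
  spacing is within a factor 5 of the anchor's mean are pooled with it
  before any quantity is derived. The factor separates regimes cleanly in
  practice because gap jumps are one to two orders of magnitude longer than
  within-region spacings.

From the pooled shared regime with effective success probability
$p_\mathrm{eff}$ and posterior spacing count $N_s$: the per-base start rate
is $r = -\log(1 - p_\mathrm{eff})$, the depth is $r \times$ mean aligned
read length, and the GDV is the expected total span of shared regions over
the genome length, $\mathrm{GDV} = \sum_d d\, \Gamma(d)\, n_d / L$ with
$\Gamma$ the pooled shared-regime responsibility. At least 10 spacings are
required; fewer is an error ("insufficient reads for low-coverage model").

### Dispatch

The switch between the two estimators uses the naive depth (total aligned
bases / genome length), the only depth available before fitting: ≥ 1× takes
the coverage mixture, < 1× the spacing mixture. In validation both paths
recover depth within ±30 % and GDV within ±0.1 of truth from 0.05× to 10×.

### Homogeneity check and quality bands

Each reference also gets a one-sample Kolmogorov–Smirnov test of read start
positions against the uniform distribution *within the covered intervals*
(concatenated into one coordinate system). Restricting to covered regions is
deliberate: a partially shared reference is uniformly covered only inside
its shared regions, and testing against uniformity over the whole genome
would flag every honest partial reference. Non-rejection ($p \ge 0.05$) is
read as "homogeneous"; a tiny p-value flags clumped placements such as
spurious hits on one conserved locus. We note the convention explicitly
because presence/absence of rejection is easy to state backwards: a
*large* p-value is the good outcome here.

GDV bands summarize interpretability: above 0.8 the reference almost always
identifies the organism ("high"); 0.2–0.8 is "informative" (a real but
incomplete match — genus/family-level information); below 0.2 "caution"
(distant relation or mapping noise).

## Core reads and clustering

A read that maps to several references tells us those references share the
region it came from. If the read's target references have clearly
*different* local depths, the region is shared between distinct sample
organisms; if all targets have near-identical depth, the simplest
explanation is that they are all partial descriptions of *one* organism. A
read is a **core read (CR)** when
$(\max D_r - \min D_r)/\mathrm{mean}(D_r) \le t$ over the depths $D_r$ of
its targets (default $t = 0.2$; single-target reads pass trivially; reads
touching an organism whose fit failed are excluded, since no depth exists to
compare). The criterion is scale-free: rescaling all depths leaves the CR
set unchanged, and raising $t$ only ever adds reads.

References are then greedily clustered into candidate organisms. Processing
order is total-mapped-reads descending with lexicographic tie-break, so
well-supported genomes seed clusters and the outcome is deterministic. Each
genome joins the existing cluster with the highest CR overlap
$|\mathrm{CR}_g \cap \mathrm{CR}_c| / |\mathrm{CR}_g|$ if that reaches 20 %;
otherwise the cluster with the highest shared-read fraction
$|R_g \cap R_c| / |R_g|$ if that reaches 60 % (shared reads are less
discriminative than shared CR, hence the stricter default); otherwise it
founds a new cluster. Ties go to the earliest-created cluster; genomes
without CR skip straight to the shared-read stage. Cluster CR and read sets
are unions over members. The denominators are the *genome's* sets in both
stages — the thresholds are "20 % of the genome's CR" and "60 % of the
genome's reads". A taxonomy-aware scan-order hint exists for large
collections but cannot change results, because every cluster is still
scanned and the best match taken.

Each candidate is named by the lowest common ancestor of its members in an
optional taxonomy table (absent taxonomy: "unclassified"), its depth is the
read-count-weighted mean of member depths (members describe one organism, so
their depths agree by construction of CR), and its relative abundance is its
depth share — depth already normalizes genome length out of read counts, so
this is a cell-count abundance. Read counts are reported alongside for
read-fraction interpretation.

**Filters.** Before any estimation: reads mapping to more than 50 distinct
*organisms* are discarded (conserved-region filter — we interpret the
threshold at the organism level after chromosome/plasmid grouping, since the
rationale concerns distinct organisms, not replicons of one assembly), then
organisms with fewer than 10 uniquely mapping reads are dropped, in a single
pass in that order. Uniqueness is recomputed after the first filter, not
iterated to a fixed point.

## The simulator, and what passing its tests shows

`simulate_community()` generates the ground truth every test measures
against: i.i.d.-uniform organism genomes; references derived by copying a
chosen fraction of an organism genome (the *true* GDV) in 10 contiguous
blocks with i.i.d. substitutions at a chosen divergence, the complement
replaced by fresh random sequence; reads at Poisson counts with uniform
starts and binomial error counts; and a SAM emitted by coordinate
bookkeeping — a read aligns to every reference whose shared blocks contain
at least 90 % of its footprint, with edit distance = planted substitutions
in the span + the read's own errors. Block gaps follow a broken-stick split
of the unshared remainder, so gap positions are unstructured, as homologous
segment boundaries between real genomes are; a regular layout would make the
unique regions of different references of one organism systematically
coincide or systematically miss each other.

Deliberate simplifications, and hence limits of what the validation shows:
alignments come from bookkeeping, not a mapper, so there are no spurious
cross-organism hits, no clipped or indel alignments, and no
mapping-quality ambiguity; errors are substitutions only; depth is exactly
homogeneous (no GC bias); organisms share no homology across cluster
boundaries, so the promiscuous-read filter is exercised by hand-built
fixtures rather than by the community simulations. Recovery results on this
generator demonstrate the *estimators* (mixture fitting, CR extraction,
clustering) under the stated sampling model; they do not certify behaviour
under mapper artifacts or biased library preparation.

Problem sizes used in the bundled validation were chosen to make the
statistics, not the software, the binding constraint: 1 Mb genomes for the
depth × shared-fraction recovery grid (so even the 0.05× cell has ~500
reads), 500 kb for the staggered community (so the weakest reference of the
0.5× organism retains well over the 10 unique reads the support filter
demands), and 100–200 kb for single-property tests.

## Other numerical conventions

* Coordinates are 0-based half-open internally; SAM input/output is 1-based.
* Edit distances come from the `NM` tag, falling back to extended-CIGAR
  mismatch/indel operations, else 0 with a warning.
* Secondary and supplementary alignments are retained: every placement of a
  multi-mapping read is evidence.
* All randomness in the simulator derives from the community seed;
  per-reference and per-organism streams are offset deterministically, so
  reports are byte-identical across runs.
* TSV reports format floating point numbers with six significant digits to
  keep byte-level determinism across platforms.

## Known limitations

Organisms at (near-)identical depth whose references are highly similar can
merge into one candidate — the CR criterion cannot separate them; this is
inherent to depth-based identification and would require dedicated strain
disambiguation downstream. Abundance estimates inherit reference-database
imbalance: taxa with many references attract more clusters. The geometric
path needs on the order of tens of mapped reads per reference; below that
the reference is reported with `fit_failed` and GDV 0 rather than a guess.
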