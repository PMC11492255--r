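---
title: "Detecting ZW sex-chromosome structure from sexed coverage, and comparing Hox cluster organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ZW sex-chromosome structure from sexed coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwscan)
```

## The coverage model

In a female-heterogametic (ZW) species, females carry one Z and one W while
males carry two Z copies. When whole-genome sequencing reads from one female
and one male are mapped to a female-derived assembly, per-region copy number
translates directly into expected read depth:

| region                    | female copies | male copies | expected log2 M:F |
|---------------------------|---------------|-------------|-------------------|
| autosome                  | 2             | 2           | 0                 |
| pseudoautosomal (PAR)     | 2             | 2           | 0                 |
| Z-specific                | 1             | 2           | +1                |
| hemizygous Z (W degraded) | 1             | 2           | +1                |
| W fragment                | 1             | 0           | -Inf (male 0)     |

The scan computes mean depth per sex in fixed windows (100 kb by default),
divides each sex's depths by that sex's **median autosomal** depth so the
two libraries are comparable regardless of sequencing yield, and forms

$$ r = \log_2\frac{m_{\mathrm{norm}} + c}{f_{\mathrm{norm}} + c} $$

with pseudocount $c = 0.05$ in normalized-depth units. The pseudocount
keeps windows with zero male depth finite (a fully W-derived window with
$f_{\mathrm{norm}} = 0.5$ gives $r = \log_2(0.05/0.55) \approx -3.46$,
far below any autosomal value) while perturbing near-equal windows by less
than 0.01. The median, rather than the mean, makes the normalization robust
to the sex-linked windows themselves. Normalization can be switched off
(`normalize = FALSE`) when the inputs are already depth-comparable.

## Window classification and segmentation

Windows are classified by rules applied in a fixed order, so classification
is a total, deterministic function:

1. `LOW_COVERAGE`: both normalized depths < 0.1 (unmappable or collapsed
   sequence; nothing can be said).
2. `FEMALE_SPECIFIC`: male depth absent (`m_norm < 0.1`) with clear female
   depth (`f_norm >= 0.25`) — the W signature. A single-copy W window sits
   near `f_norm = 0.5`; the 0.25 floor rejects noise-only windows.
3. `Z_SPECIFIC`: `r` within [0.7, 1.5], the band around the one-versus-two
   copy expectation of +1.
4. `PAR`: `|r| < 0.35`.
5. `UNDETERMINED`: everything else.

Only the two-fold criterion `|r| > 1` is dictated by the copy-number
arithmetic; the band edges (0.35, [0.7, 1.5]) and depth floors (0.1, 0.25)
are this package's operationalization of the qualitative region
descriptions, chosen to leave a guard zone between the PAR and Z-specific
bands at roughly three Poisson standard deviations of a 30x / 100 kb
window. All are `zw_thresholds()` keys.

The class track is then smoothed by a centered 5-window majority vote (ties
keep the original class; window 1 is the identity), and segmented into
maximal same-class runs. Runs shorter than `min_run = 3` windows are
absorbed into the longer flanking run — the left flank on ties, an
arbitrary but fixed choice that keeps segmentation reproducible. At 100 kb
windows this suppresses features below ~300 kb, well under the megabase
scale of the planted W fragments.

A chromosome is reported as sex-linked when more than 5 % of its windows
are sex-linked (`|r| > 1` or class FEMALE_SPECIFIC / Z_SPECIFIC); all
fractions are reported and no uniqueness is forced, so a genuinely
multi-sex-chromosome input would flag every qualifying chromosome.

## Contig calls and W extraction

Assemblies of young sex chromosomes often interleave W-derived contigs into
the Z scaffold; the AGP file records which contig occupies which span.
Each window is assigned to the contig containing its midpoint (never
double-counted at junctions), and a contig is called `W` when at least 80 %
of its classified windows are FEMALE_SPECIFIC, `Z` when at least 80 % are
PAR or Z_SPECIFIC, otherwise `AMBIGUOUS`. The 0.8 fraction is deliberately
stricter than a majority: W calls drive the physical removal of sequence
from the chromosome, so they should be high-confidence. Both the fraction
and the bin-midpoint rule are package decisions (the threshold is a config
key); the underlying two-fold rule is applied per window and aggregated per
contig, since per-contig averaging would blur short W fragments embedded in
Z sequence.

`extract_w()` removes W-verdict components from their object, merges gap
rows left adjacent by a removal into one (keeping the left gap's length —
removing a contig should not inflate the remaining gap), drops gaps
stranded at object edges, renumbers parts and recomputes coordinates.
Sequence length is conserved exactly between the revised object and the
extracted contig list.

## Candidate sex-determining genes

Expression evidence is reduced to a fold rule: with pseudocount 1 (count
units; 0.1 is suggested for depth-scale measures), the fold is
`(max + c) / (min + c)` and a gene is sex-biased when the fold **strictly**
exceeds 2 ("more than two-fold"). W candidates are FEMALE-biased genes
overlapping W contigs or FEMALE_SPECIFIC regions; Z candidates are
MALE-biased genes overlapping Z_SPECIFIC regions. Overlap is any shared
base; a boundary-straddling gene is assessed against every region it
touches. Any non-negative expression measure is accepted — raw counts, TPM
(`compute_tpm()` implements the standard length-normalized measure summing
to $10^6$), or per-gene coverage depth; the choice is the caller's and is
carried through unchanged.

## The synthetic genome

`sim_config()` defines the study conditions the package is tested under:

* one 75 Mb ZW-mixed chromosome: PAR1 `[0, 48.3)` Mb, a female-specific
  stratum `[48.3, 62.5)` Mb carrying five 2 Mb W fragments starting at the
  stratum boundary and separated by 1 Mb hemizygous-Z segments, a fully
  differentiated Z-specific stratum `[62.5, 70)` Mb, and PAR2 from 70 Mb to
  the end. The boundaries follow the coverage-plot layout the scan is
  designed to recover; W fragment sizes are not constrained by that layout,
  and 2 Mb (within a plausible 1–3 Mb range for young, partially degraded
  strata) keeps each fragment tens of windows long. The chromosome end at
  75 Mb simply leaves PAR2 a 5 Mb tail beyond the 70 Mb boundary.
* three autosomes (20, 15, 12 Mb — all above the 10 Mb chromosome-scaffold
  cutoff), one of which carries a ten-gene Hox cluster with configurable
  gaps (defaults: 11.7 Mb between *pb* and *Hox3*, 500 kb between *abd-A*
  and *Abd-B*, 100 kb elsewhere; *ftz* on the minus strand) plus 20 decoy
  homeobox genes whose products never mention a canonical class name.
* depth: per window and sex, the covered-base total is drawn
  `Poisson(30 x copy factor x width)` and divided by the width. Copy
  factors are 1 for diploid regions, 0.5 for single-copy-in-female
  regions, and exactly 0 for W fragments in the male.
* expression: Poisson counts with mean `100 x fold`; planted folds are 1
  (unbiased), 4 on seven Z-specific genes (the male-biased candidates), and
  male-fold 0 on W-fragment genes. Unbiased Z-specific genes are given
  equal means in both sexes, i.e. full dosage compensation, so only planted
  folds create bias.

Everything is seeded and byte-reproducible. The simulator emits a gapless
AGP (components abut), which keeps the component-tiling arithmetic exact;
gap-row handling in `extract_w()` is exercised separately with explicit
fixtures. What the simulator deliberately omits: GC and mappability
covariates, overdispersed (negative-binomial) counts, alignment artifacts,
repeat-driven depth spikes, and real gene structure. Passing tests
therefore demonstrate that the algorithms recover the structure the
coverage model implies — not that the thresholds are optimal for any
particular real dataset, where mappability filtering upstream (the depth
input is expected to come from uniquely-mapping, high-MAPQ alignments) and
threshold tuning may both matter.

## Hox organization comparison

`collect_hox()` reduces an annotation plus a class assignment (product-name
matching via `match_hox_classes()`, or an externally produced
homeodomain-hit table — running a domain scanner is out of scope, keeping
the stage deterministic and offline) to an ordered, stranded organization;
duplicate class assignments keep the first gene by position with a warning,
and a cluster split across chromosomes warns without failing.
`hox_subclusters()` cuts between consecutive genes when the intergenic
distance (`next start - previous end`; negative for overlapping genes,
which never cut) exceeds a threshold, 1 Mb by default — between the
~500 kb and multi-megabase gap scales seen in arthropod clusters, so the
two-subcluster reading emerges at the default while a 400 kb threshold
would also cut the smaller gap.

Orientation is expressed relative to each species' majority strand (ties
break to `+`), which makes the comparison invariant to which DNA strand a
genome assembly happens to report. `infer_inversions()` flags a class as an
inversion site between two clades only when its relative orientation is
uniform within each clade and differs between them; absent or
within-clade-mixed classes are inconclusive rather than forced either way.
`synteny_conserved()` requires identical present-class order and identical
relative orientations, ignoring absolute coordinates.

## Problem sizes and runtime

The default simulation is 122 Mb of genome in 1,220 windows of 100 kb with
~100 genes — large enough that every region is tens of windows and
Poisson means are estimated to well under 1 % error, small enough that a
full simulate–scan–extract–candidates cycle runs in well under a second.
The test suite re-runs that cycle a handful of times and completes in tens
of seconds.

## A worked run

```{r example}
cfg <- sim_config(seed = 101)
sim <- simulate_zw(cfg)
res <- scan_sex_regions(sim$bins, autosome_ids = paste0("chr", 2:4),
                        agp = sim$layout$agp)
res$chrom_report
subset(res$regions, chrom == "chr1")
table(res$contig_calls$verdict)

cand <- candidates_in_regions(sim$layout$genes, bias_flags(sim$expression),
                              res$regions, res$contig_calls)
table(cand$candidate_type)

org <- collect_hox(sim$layout$genes, match_hox_classes(sim$layout$genes),
                   species = "simulated")
attr(hox_subclusters(org), "partition")
```

## Known limitations

* Thresholds are calibrated for ~30x depth at 100 kb windows; much lower
  depth or much smaller windows widen the Poisson spread into the guard
  zones and will increase UNDETERMINED calls.
* Evolutionary-strata dating, heteromorphy assessment and any use of Hi-C
  contacts are out of scope; the segmentation labels coverage classes, not
  strata ages.
* The inversion report is orientation-only; it does not attempt to infer
  breakpoints or order rearrangements beyond the first-difference report of
  `synteny_conserved()`.
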