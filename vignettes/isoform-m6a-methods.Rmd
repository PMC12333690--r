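---
title: "Methods: isoform-level m6A and poly(A) analysis in isomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-level m6A and poly(A) analysis in isomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomod)
```

# Scope and data model

`isomod` analyses *summaries* of nanopore direct RNA sequencing, not raw
signal. Its inputs are the tables a typical DRS study produces upstream:
per-sample site tables (one row per tested DRACH position on a transcript,
with a read count, a modification probability and a modification rate),
xPore-style between-condition differential tables, nanopolish-style per-read
poly(A) tables, limma/DEXSeq-style DE and isoform-usage tables, and a
GENCODE-dialect GTF. Basecalling, alignment, quantification and the neural
site callers themselves are out of scope; their outputs are contracts this
package consumes.

Coordinates follow one internal convention, converted at the I/O seam:
genomic intervals are 0-based half-open (GTF's 1-based inclusive records are
converted on read and write), and transcript offsets are 0-based spliced
positions, matching the `transcript_position` column of m6anet-style tables.
On the minus strand, transcript offset 0 is the highest genomic coordinate of
the genomically last exon. The CDS span of a transcript includes the stop
codon (CDS plus `stop_codon` features are unioned on parsing), the GENCODE
convention.

Two boundary conventions matter downstream and are fixed here once. First,
*boundary distances*: splice junctions, the transcript start and the
transcript end are pooled as boundaries; the first base of an exon has
`dist_up = 0` and the last base has `dist_down = 1`, so
`dist_up + dist_down` always equals the enclosing segment length. Second,
*metagene positions*: each coding transcript is rescaled per transcript into
three unit segments (5'UTR to [0,1), CDS to [1,2), 3'UTR to [2,3)) by the
fractional offset within the region. Cross-transcript median-length
rescaling, which some metagene tools apply, is deliberately not used: the
fractional variant is the simplest reproducible choice and is recorded here
as the package's convention. Noncoding transcripts are flagged and excluded
from metagene profiles.

# Consensus site calling

A transcriptomic site is identified by `(transcript_id, tx_pos)`; genomic
deduplication happens only in genomic-level analyses (shared-site grouping,
database intersection), because that is the resolution the site tables carry.
A site is *detected in a sample* when its modification probability strictly
exceeds 0.9; it enters the high-confidence catalog when detected in at least
two samples; it is *detected in a region* when detected in at least one of
the region's samples. Rows failing the ingestion invariants — non-DRACH
5-mer, coverage below 21 reads (the "more than 20 reads" rule), values
outside [0,1] — are rejected with counts reported.

The per-region modification rate of a site is the unweighted mean of its
modified-read ratio over the region's *tested* samples, not only the
detecting ones: conditioning on detection would bias rates upward. Whether a
study pools reads or averages samples at this point is usually unstated; the
averaging choice is recorded here and is invariant to sample order.

The *modified read fraction* estimate composes, per isoform, the probability
that a read carries at least one modified site under within-isoform
independence, `1 − Π(1 − rate_s)`, weighted by the isoform's read support
(summed per-sample median site coverage). Per-read co-modification is not
observable in site-level summaries, so this is an explicit lower-bound
heuristic, labelled as such in its output.

# Specificity and expression netting

At the isoform level, a feature is *commonly modified* only if a single one
of its sites is detected in all regions — a union of different
region-specific sites does not qualify, though the union-based alternative is
emitted as a secondary column for transparency. A feature is *specific* when
all of its sites are detected in exactly one region. At the gene level the
site identity switches to genomic coordinates with detection unioned over the
member isoforms; only the isoform-level rule is fixed by the upstream
definition, so the gene-level reading is a documented package choice.

"Up-regulated in region R" is operationalised as significant (BH-adjusted
p < 0.05) with a positive effect in *both* pairwise contrasts of R against
the other regions. The conjunction is the stricter reading of "up-regulated
specifically"; a region-versus-rest contrast would be the alternative and is
not used. Specific features missing from the DE tables count as *not*
up-regulated — conservative toward calling region-specific modification —
and are flagged `NA` with a message.

# Hypermodification scoring

The modification load of an isoform in a region is the sum of its detected
sites' regional rates. Load is regressed (OLS, with intercept) on spliced
length and exon density, and the residual is the normalised score; residuals
are invariant to affine rescaling of the predictors, and zero-variance
predictors are dropped with a warning rather than fitted. "Exon density" is
isoform length divided by exon count — literally the mean exon length; the
name is kept because that is what the quantity is called in this literature,
and its negative association with site count is reported under that name.

Scoring is per region (separate regressions), because hypermodified sets are
defined per region; the union across regions defines the global set whose
multi-region consistency is summarised. Whether to pool regions into one
regression was genuinely open; per-region fits match the "top n per region"
selection rule and avoid region effects leaking into the residual. Selection
uses a deterministic tie-break (score, then load, then id) because residual
ties occur on synthetic data. The headline selection size in the literature
is 500 per region; on the synthetic catalog (~300 isoforms) the analysis
drivers scale this to the top decile, which the function exposes as `top_n`.

Unmodified isoforms require more than one tested DRACH site and probability
below 0.5 at *every* tested site in *every* sample — the strictest reading
of "below 0.5 at all detected sites", enforced across samples rather than
per region.

# Differential modification

Within genes, isoforms sharing a genomic site are compared pairwise per
region with the pooled two-proportion z test. The site tables do not carry
read counts of modified reads explicitly; they are reconstructed exactly as
`k = round(mod_ratio · n_reads)` per sample and summed over the region's
samples — the inverse of how the ratio is defined. Groups with more than two
isoforms are tested on all pairs, BH adjustment spans all tests of the run
(one family per test type, matching "FDR-adjusted" without per-gene
families), and an isoform is differentially modified if it participates in
at least one significant pair (FDR < 0.05 *and* |Δrate| > 0.15). Whether the
original analysis used pairwise or one-versus-rest comparisons at >2 isoforms
is unstated; pairwise granularity is consistent with reporting both site and
isoform counts.

The structural model regresses the pairwise rate difference on the change in
distance to the downstream boundary, the change in distance to the upstream
boundary, and a 3'UTR-versus-CDS indicator (+1 / −1 / 0). Degenerate columns
are dropped with a warning.

Between regions, xPore-style rows are kept when the 5-mer is DRACH, the rate
difference exceeds 0.3 in absolute value, the BH-adjusted p is below 0.05,
and the site is corroborated by the site tables at probability > 0.7 in more
than one sample. The difference is oriented as second minus first region with
the pair ordered alphabetically, recorded in the output. Note that genuinely
region-specific sites (modified in one region, absent elsewhere) pass these
filters — they *are* between-region differences — so the direction summary on
synthetic data mixes planted directional sites with specificity-driven ones.

Two-proportion z tests are two-sided throughout (the sidedness is not stated
in this literature; two-sided is assumed), use no continuity correction, and
define the degenerate pooled-proportion case (p̂ ∈ {0,1}) as z = 0, p = 1.

# Poly(A) analysis

Only PASS-tagged reads with positive tail length are analysed, and
mitochondrial isoforms (contig `chrM`/`MT`, or annotated on those contigs)
are excluded, as their systematically short tails distort comparisons.
Summaries are per (isoform, sample) with more than 5 reads; quantiles use
linear interpolation between order statistics (R type 7), the declared
convention. Global region comparisons run the Mann–Whitney U test on the
per-(isoform, sample) medians — not raw reads — so highly expressed isoforms
do not dominate. Differential poly(A) length, within genes and between
regions, requires more than 50 pooled reads per unit, BH FDR < 0.05 and an
absolute median difference above 20 nt; the thresholds are strict
inequalities as printed in the source conventions (">5" means ≥ 6, ">50"
means ≥ 51). The same 50-read threshold is applied to the between-region
variant, where the source is only implicit. Dynamic tails are ranked by IQR
over pooled regional reads with a deterministic tie-break.

The Mann–Whitney implementation enumerates the exact null distribution of U
over all group assignments when the pooled size is at most 10, and otherwise
uses the tie-corrected normal approximation with continuity correction —
the defaults of `wilcox.test()`, which is the reference implementation in
this field. Both branches are exposed for cross-validation and agree within
0.02 absolute p at n = 5 + 5 on continuous data.

# The synthetic generator: what it emulates, and what it does not

The generator defines the study conditions the whole test bench runs under.
Defaults, chosen once: 100 genes with 2–4 isoforms sharing exons, 6–10 exons
of 100–400 nt, three regions (PFC, CN, CB) with three samples each, one
tested DRACH site per 100 exonic nt (~5,000 site-isoform observations),
P(modified) = 0.45 with base rates Beta(4, 2) (median ≈ 0.69, near the
published median stoichiometry of 0.66), an exclusion zone of 100 nt around
splice junctions and transcript ends that multiplies rates by 0.3, additive
region shifts of +0.05 (CB) and −0.05 (CN) mirroring the published ordering,
read coverage 21 + NB(mean ≈ 39) per sample, and probabilities Beta(20, 1)
for modified versus Beta(1, 20) for unmodified sites. Isoforms additionally
draw alternative transcription-start and polyadenylation extensions for
their terminal exons (0/150 nt and 0/200/450 nt), so the same genomic site
sits at different boundary distances in different isoforms — the structural
variation that drives within-gene differential modification in real data.

Planted truths, recorded in full: region-specific isoforms (8% of isoforms,
drawn from those with at least two truly modified sites, since a specificity
claim supported by a single site is fragile under the Beta(20, 1) detection
model), unmodified isoforms (8%), hypermodified isoforms (2%, six extra
private sites at rate 0.9), within-gene DM sites (5% of shared sites, one
isoform raised by exactly 0.4), and between-region DM sites (5% of modified
entries, one region — CB with probability 0.75 — raised by 0.4). Poly(A)
medians are lognormal (median 80 nt, sdlog 0.45) coupled to isoform length
through a Gaussian copula calibrated so the true medians reach Spearman
0.55, with shifts of −16 nt (CN) and −3 nt (PFC) against CB, lognormal
per-read noise (sdlog 0.30), 10% non-PASS reads, mitochondrial decoys and
unmodified spike-in transcripts with 35-nt tails. The generator is
sequence-free: DRACH 5-mers are labels with a realistic composition
(GGACT most frequent), since no downstream stage needs nucleotide sequence.

What passing tests on this generator do *not* show about real data: the
emitted modification probability is independent of the site's stoichiometry,
whereas real callers detect low-stoichiometry sites less reliably — so the
synthetic catalog retains suppressed exclusion-zone sites that real data
would tend to miss, its median site rate (~0.27) is below the published
~0.66, its reproducibility fraction (~95% of sites in ≥3 samples of a
region) is above the published 45%, and its modified-read fraction is far
above the published lower bound of 27%. Coverage is also independent of
expression, sites are placed uniformly rather than enriched near stop
codons, and DE/DIU tables are drawn from the planted truth rather than
fitted models. These quantities are therefore reported as properties of the
synthetic conditions, not as reproductions of the published values; the
published worked-example percentages are instead reproduced exactly by
running the summarisers on fixtures that encode the printed marginal counts.

# Verification design and problem sizes

The test bench runs at desk scale, with sizes chosen so the full suite
completes in a few minutes: coordinate round-trips over 200 random models ×
50 positions; kernel oracles over 1,000 random 2×2 tables (z versus the
signed root of the uncorrected chi-square), brute-force BH step-up,
exact-versus-normal Mann–Whitney agreement, and closed-form hypergeometric
values; and end-to-end recovery over 20 seeds of the default conditions. On
those seeds the pipeline recovers ≥95% of planted region-specific isoforms,
places ≥95% of planted hypermodified isoforms in the top residual decile,
recovers the planted −16 nt CN shift in sign and significance, keeps the
within-gene DM false-positive rate within Monte-Carlo error of the FDR level
on null data (no plantings, flat 100-read coverage), and detects ≥90% of
planted |Δrate| = 0.4 sites at 100 reads. The exclusion-zone structural
property is checked on ~5,000 modified observations: Spearman correlation of
rate with downstream-boundary distance is positive at p < 0.01 with the
penalty enabled and vanishes (|rho| < 0.05) with it disabled. The published
correlation magnitude depends on the real data and is not a numeric target.

One statistical caveat surfaced during verification: BH adjustment is not
idempotent (re-adjusting adjusted values changes them), so the suite asserts
monotonicity, permutation equivariance and agreement with the brute-force
step-up instead.

# Known limitations

Site-level inputs cannot support per-read co-modification or pairing of m6A
status with tail length on the same molecule; the read-fraction estimate and
the m6A/poly(A) integration are correspondingly coarse. The expression
netting treats features absent from DE tables as not up-regulated, which
undercounts expression-driven specificity when DE coverage is incomplete.
Genomic deduplication assumes exact coordinate identity; sites differing by
alignment jitter are not merged. The generator's annotation is structurally
simple (no overlapping genes, no intron retention), and its DE tables are
idealised draws rather than model fits.
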