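---
title: "Comparing two genome assemblies: SVs, TE insertions, and chromatin compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two genome assemblies: SVs, TE insertions, and chromatin compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpair)
library(dplyr)
```

svpair compares two related genome assemblies — the motivating use case is a
pair of ecotypes of one plant species, each with a chromosome-scale assembly,
gene and repeat annotation, Hi-C libraries, and population resequencing data.
This vignette explains the models and procedures behind each step, the
parameters that matter, and what the synthetic data generator does and does
not emulate.

## Gap-signature SV calling from whole-genome alignment

Assembly-versus-assembly SV calling works on the coordinate table of a
whole-genome aligner (a `show-coords`-style table), not on raw sequence.
After **unique-anchor selection** — blocks with a reference span of at least
`anchor_min_len` (default 10 kb) that do not overlap another kept block by
more than half their own length, chosen greedily longest-first — consecutive
anchors on one `(reference chromosome, query chromosome, strand)` run define
a *gap pair*: the reference gap $R$, the strand-aware query gap $Q$, and the
discrepancy $d = Q - R$.

The sign pattern of $(R, Q)$ classifies the event:

| $R$ | $Q$ | $d > 0$ | $d < 0$ |
|-----|-----|---------|---------|
| $\ge 0$ | $\ge 0$ | insertion | deletion |
| $< 0$ | $\ge 0$ | repeat_expansion | repeat_expansion |
| $\ge 0$ | $< 0$ | repeat_contraction | repeat_contraction |
| $< 0$ | $< 0$ | tandem_expansion | tandem_contraction |

A negative gap means the two anchors *overlap* in that genome — the hallmark
of copy-number change in repeated sequence: overlap in one genome only marks
a dispersed-repeat event, overlap in both marks a tandem array. Calls are
emitted when $50 \le |d| \le 100\,000$ bp and neither raw gap exceeds the
upper bound; the 50 bp floor is the conventional minimum SV size, and the cap
prevents "calls" that span unrelated anchor pairs. Insertion/deletion calls
are presence/absence variants (PAVs); the other four classes are
repeat-mediated. The classifier is total on its domain and is checked in the
tests against an exhaustive, independently written case table.

Inversions surface as maximal runs of `-` strand anchors embedded in `+`
context; translocations as anchor runs that violate the mutual-best
chromosome pairing. A reciprocal translocation therefore appears as exactly
two call groups with swapped chromosome pairs.

```{r quick-example}
blocks <- tibble::tibble(
  ref_chrom = "chr1", ref_start = c(0L, 20000L), ref_end = c(20000L, 40000L),
  qry_chrom = "chr1", qry_start = c(0L, 22000L), qry_end = c(20000L, 42000L),
  strand = "+", pct_identity = 99, is_unique_anchor = NA)
call_svs(select_unique_anchors(blocks))
```

### Positional annotation

Each call is annotated against the gene models of the genome that carries the
affected sequence — the reference for deletions and contraction classes, the
query for insertions and expansions — with one mutually exclusive category by
priority: `transcript_ablation` (the call swallows an entire gene) > `exon` >
`splice_site` (the 2 bp at either end of an intron) > `intron` >
`upstream`/`downstream` (within 5 kb, strand-aware) > `intergenic`. The first
three are `high` impact, the rest `modifier`. The `moderate` and `low` tiers
of the usual effect ontologies require codon-level reasoning that interval
arithmetic cannot support, so this annotator never emits them. The 5 kb
near-gene window follows the convention that "upstream of a gene" in figure
legends names the window within which an SV is associated with the gene.

## TE insertion detection

TE insertions are found with deliberately asymmetric gap rules on a
reciprocal comparison: a candidate insertion is a query gap strictly greater
than 1000 bp facing a reference gap of at least zero and strictly below
100 bp (the small reference gap is the *insertion site*). A candidate becomes
a TE insertion when strictly more than 80 % of the inserted query sequence is
covered by TE annotation, with overlapping annotations merged so double
cover counts once. A gene is *TE-affected* when an insertion site falls in
the gene or within 500 bp of it; the distance is counted inclusively, so a
site exactly 500 bp away still qualifies. All three thresholds are applied
strictly as stated; the tests plant insertions straddling each boundary
(999/1001 bp, 99/101 bp, 0.79/0.81 cover, 500/501 bp) and require the
accepted set to equal the rule-satisfying subset exactly.

## A/B compartments from Hi-C

Compartments are called per chromosome from a binned contact matrix (100 kb
bins by default, the standard resolution for plant-genome compartment
analysis):

1. **Masking**: bins whose marginal is zero or below 5 % of the median
   marginal are dropped — these are unmappable or empty bins that would
   otherwise dominate the correlation structure.
2. **O/E normalization**: each entry is divided by the mean contact at its
   genomic distance, removing the universal distance decay.
3. **Correlation + PC1**: the Pearson correlation matrix of the O/E columns
   is computed and its leading eigenvector extracted by shifted power
   iteration (Gershgorin shift, so the algebraically largest eigenvalue
   dominates even for indefinite matrices; tolerance $10^{-12}$). The tests
   check the routine against a dense `eigen()` decomposition.
4. **Orientation and sign rule**: positive entries are compartment A (open
   chromatin), negative B. The eigenvector's global sign is mathematically
   arbitrary, so it is oriented by positive correlation with a per-bin track
   where high values mark open chromatin — gene density or GC content.
   Without a track the sign is chosen so that B covers at least half the
   bins, the heterochromatin-majority convention; this fallback fixes
   determinism, not biology, and a track should be supplied whenever one
   exists.

Region-level status (used for, e.g., the compartment membership of
PAV-containing regions) is the bp-majority of overlapped bins, with an exact
tie resolved by the bin containing the region midpoint and regions more than
half-covered by masked bins reported `NA`.

## Syntenic blocks and compartment switches

Gene-anchor pairs are chained per chromosome pair and orientation by a
longest-chain dynamic program requiring strict rank monotonicity in both
genomes and at most 25 skipped genes between consecutive anchors; chains are
extracted greedily (longest first, `+` preferred on ties), each pair used
once, and chains below 5 anchors discarded — the defaults of the standard
collinearity tools. Blocks on the mutual-best chromosome pairing are
`collinear` or `inverted` by orientation; blocks off it are `translocated`.

Compartment switches are measured by walking each block's query span in
bin-size steps, mapping step midpoints linearly (orientation-aware) to
reference coordinates, and attributing the step's bp to `conserved`,
`A_to_B`, `B_to_A`, or `NA`. The four classes partition the compared bp
exactly, switched bp are attributed to the query genome, and `NA` is reported
explicitly rather than folded into the denominator, so the three informative
percentages are conservative.

## Short-read call-set merging and concordance

Calls from multiple callers merge when they share type and chromosome and
both breakpoints lie within 1000 bp, by single-linkage clustering within
type; SURVIVOR's common defaults. A merged call takes coordinate medians,
per-sample support summed across members, and the worst filter status. Exact
duplicate records collapse to one observation first, which makes the merge
idempotent in the strict sense. Retention then requires summed support of at
least 3 reads, size of at least 50 bp, and a PASS filter.

A whole-genome-alignment deletion is *confirmed* by a short-read deletion
with reciprocal overlap of at least 0.5; an insertion by a short-read
insertion point within 500 bp. The matching rule is this package's choice —
published concordance statements rarely print one — and both knobs are in
`sv_config()`.

## The synthetic data generator

Every module is tested against planted truth, so the generator is first-class
code. An ancestral genome is drawn i.i.d. at a chosen GC content with
non-overlapping gene models (1–6 exons, echoing the ~4 exons per gene of
plant annotations) and TE copies from per-family consensus motifs with 1–5 %
divergence. Two edit scripts derive the genome pair; each operation is
recorded in a segment map so every planted event lifts into both derived
coordinate systems. Alignment blocks are constructed from the truth — split
at every breakpoint, with the anchor-overlap extensions that make repeat and
tandem events produce exactly the negative-gap signatures the classifier
expects, and the implied zero-jitter gap calls recorded alongside. Hi-C
matrices follow a plaid Poisson model: the expected count between bins $i
\ne j$ is $s_i s_j\, C\, (|i-j|+1)^{-\alpha} (1 + \delta\, c_i c_j)$ with
log-normal visibilities $s$, decay $\alpha = 1$, plaid strength $\delta =
0.4$, and near-diagonal scale $C = 500$ — a depth consistent with deeply
sequenced plant Hi-C at 100 kb bins. Genome 2's compartment truth has 45 % of
bins flipped in geometric runs, emulating the extensive compartment
divergence observed between real ecotypes. Short-read call sets emit every
liftable PAV once per pseudo-caller with Poisson per-sample support over 10
individuals, plus uniformly placed false calls.

What the generator does **not** emulate: alignment noise other than uniform
breakpoint jitter, micro-homology or nested/overlapping variants, repeat
families that confound anchor uniqueness, Hi-C ligation artifacts and
translocation-induced contact changes, and read-level errors. Passing the
planted-truth tests therefore demonstrates that the *computations* are
correct under their stated assumptions, not that the thresholds are optimal
for any particular real data set.

## Numerical and design choices

- All internal coordinates are 0-based half-open; files keep their native
  conventions (GFF3 and coords tables 1-based inclusive, BED half-open) and
  are converted only at the I/O boundary.
- Reverse-strand query intervals are stored ascending with a strand flag, so
  interval algebra never branches on orientation.
- Degenerate inputs: zero-length call intervals are treated as 1 bp points
  for overlap tests; constant correlation columns are masked with a warning;
  an all-masked matrix is an error rather than a silent empty profile.
- Greedy tie-breaks are deterministic everywhere (longest-first then
  positional order for anchors; `+` before `-` for chains; alphabetical
  worst filter status), which is what makes end-to-end byte determinism
  under a fixed seed possible.
- Problem sizes in the tests (two chromosomes of 0.3–1 Mb, ~100 planted
  events, 200-bin matrices, 20 stochastic replicates) were chosen as the
  smallest sizes at which every class of event occurs many times per run.

## Known limitations

Within-alignment indels are not extracted — only between-anchor signatures,
so the caller undercounts relative to tools that mine alignment internals.
Duplications are representable in the call model but no detector emits them.
The translocation detector reports maximal off-pairing runs, which merges
adjacent translocated segments separated by small collinear islands. Compartment
calling assumes a single dominant plaid axis per chromosome; chromosomes
whose first principal component tracks arm-level features rather than
compartments would need an orientation track and manual review, as with any
PC1-based caller.
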