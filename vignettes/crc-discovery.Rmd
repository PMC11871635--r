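---
title: "Mapping core regulatory circuitries from H3K27ac profiles"
author: "crcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping core regulatory circuitries from H3K27ac profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

In many cancers — acute myeloid leukemia prominently among them — a small
set of lineage transcription factors (TFs) is driven by super-enhancers
(SEs), binds its own enhancers and each other's, and thereby locks the cell
into its transcriptional state. Such a fully interconnected, autoregulated
TF set is a *core regulatory circuitry* (CRC). `crcscan` implements the
computational chain that proposes CRC candidates from a single sample's
H3K27ac profile:

1. **Super-enhancer calling.** MACS2-style peak calls are cleaned of
   promoter-proximal peaks, stitched into enhancer domains, quantified
   against the H3K27ac signal track and ranked; the hockey-stick cutoff
   separates SEs from typical enhancers.
2. **SE-to-TF assignment.** SEs are assigned to TF genes whose TSS lies
   inside or within a proximity window of the region.
3. **Motif scanning.** Each SE-associated TF's SE regions are extended
   500 bp on both sides and scanned with every TF's position weight matrix
   on both strands, with exact p-values.
4. **Circuit construction.** A TF is *autoregulated* when its own motif
   occurs **more than two** times in its extended SE regions. Every fully
   interconnected subset of autoregulated TFs is a candidate circuitry;
   candidates are scored by occurrence frequency and ranked.

Because a real patient-cohort input cannot be shipped, the package carries
a first-class synthetic-data generator (`plant_epigenome()`) that emits a
complete input set — genome FASTA, gene GTF, narrowPeak calls, bedGraph
signal, MEME motifs — with a known planted circuit, so that every stage is
testable against an exact ground truth.

## The super-enhancer model

Peaks whose midpoint falls within ±2.5 kb of any TSS are removed; surviving
peaks separated by gaps of at most 12.5 kb are stitched into one region
(both values are the ROSE conventions, exposed in `crc_params()`). A
region's signal is the sum over its constituent-peak footprints of the
bedGraph value per bp; when a control track is supplied its mass-rescaled
footprint sum is subtracted and floored at zero, and when no track is
available the summed narrowPeak `signalValue` is the fallback. Overlapping
input peaks are merged before gap logic so signal is never double-counted.
The ROSE refinement that un-stitches regions spanning several TSSs is
deliberately not implemented.

The cutoff follows the ROSE tangent construction, made operational as an
exhaustive search: with signals sorted ascending and reference slope
$m = (\max s - \min s)/n$, a line of slope $m$ is drawn through every point
$(x, s_x)$; the cutoff index minimises the number of points at or below
that line (the sliding diagonal is tangent to the ranked curve from below
at the inflection). Ties resolve to the largest index — the most
conservative cutoff — which also fixes the degenerate all-equal curve to
"no super-enhancers". Regions strictly above $y^* = s_{x^*}$ are SEs. The
criterion is scale-equivariant, so input normalisation does not change SE
membership.

Gene assignment uses a 50 kb TSS-to-boundary window (distance 0 for a TSS
inside the region); a supplied TF list restricts the assignable symbols,
and overlap-only assignment is available as `assign_window = 0`. Whether
the original analyses excluded promoter peaks or used windowed assignment
is not always reported; both behaviours are therefore switchable
(`tss_window = 0`, `assign_window = 0`).

## Motif scanning with exact p-values

Scanning reproduces FIMO's model. A PWM with pseudocount $c$ and background
$b$ scores a window $w_1..w_k$ as

$$\mathrm{score} = \sum_j \log_2 \frac{(p_j(w_j) + c\,b(w_j))/(1+c)}{b(w_j)}$$

in bits. The null distribution of the window score is computed exactly by
discretising each matrix cell onto a common integer grid (1000 bins across
the score range) and convolving position by position; a hit's p-value is
the tail of that distribution at the window's integer score, and windows
with $p \le 10^{-4}$ (FIMO's default) are reported on both strands.
Overlapping and double-strand hits all count individually — the most
literal reading of "number of binding motifs". N bases contribute zero
bits. The reverse-complement orientation reuses the same distribution
exactly because its integer matrix is a row/column permutation of the
forward one; for this to hold with a non-uniform background the background
is symmetrised over complementary bases, which is the appropriate null for
double-stranded scanning (`estimate_background()` returns a symmetrised
0-order composition). Discretisation error for real-valued threshold
queries is bounded by `width / (2 * scale)` bits; on the integer scale the
DP is exact, which the tests verify against full $4^w$ enumeration.

If several motifs share one TF symbol their hit counts sum; the package
ships and generates one motif per TF.

## Circuit construction and scoring

From the hit counts, TF $a$ regulates TF $b$ when $a$'s motif occurs at
least `edge_min` (default 1) times in $b$'s extended SE regions.
Autoregulation is the strict rule: self-count $> 2$ (configurable via
`self_threshold`). A circuitry is any set of autoregulated TFs in which
**every ordered pair** is an edge; *all* such subsets of size
$\ge$ `min_size` (default 2) are enumerated — the downward-closed universe,
found by clique search on the symmetrised graph and verified against
power-set filtering. This reading of "all possible circuitries" is the only
one under which the occurrence-frequency score discriminates among
candidates; occurrence counting over maximal circuitries only is available
as `maximal_only = TRUE` for sensitivity analysis.

Scoring: $\mathrm{occ}(t)$ is the number of enumerated circuitries
containing $t$, and a circuitry $C$ scores
$\sum_{t \in C} \mathrm{occ}(t)\,/\,|C|$. Ranking is by score descending,
then size descending, then alphabetical member order — the tie-breaks are
this package's convention, chosen for reproducibility. Note a structural
property of the score: TFs that appear in many circuitries push up every
circuitry containing them, so small subsets of a hub can tie with or exceed
larger candidates; in a symmetric clique all subsets tie and the size
tie-break puts the full clique first. The top *maximal* circuitry
(`top_circuitry(scored, maximal_only = TRUE)`) is the natural CRC
candidate when subsets tie in this way.

## What the synthetic generator emulates

`synthetic_config()` defaults describe the validation conditions used by
the tests, the analysis scripts and `scripts/acceptance.R`:

| parameter | default | meaning |
|---|---|---|
| `n_tf_genes` | 20 | TF genes, >= 50 kb apart on 2 x 1.8 Mb chromosomes |
| `k_core` | 5 | planted circuit size (a five-TF circuit) |
| `se_peak_cluster` | 5 | peaks per planted SE, gaps 0.8-2.5 kb (far below the 12.5 kb stitch distance) |
| `self_motif_copies` | 3 | instances of every core motif per core SE — the minimum that passes the strict "> 2" rule |
| `motif_width` | 8 | consensus detectable at $p \le 10^{-4}$ (width 7 is the floor; the config validates this) |
| `signal_high` | lnorm(4, 0.3) | per-bp signal of planted constituents |
| `signal_low` | lnorm(1, 0.3) | background/singleton peaks; the high median must exceed the low 99th percentile |
| `decoy_signal_factor` | 0.35 | decoy clusters stay super-enhancers but below every planted SE |
| `n_background_peaks` | 150 | low-signal singletons, each > stitch distance from any other peak |

Three structures probe the rules' boundaries: a *near-miss pair* with full
cross-wiring but exactly two self-motifs each (must be excluded by the
strict rule), a *trio* with one directed edge removed (must never form a
size-3 circuitry), and ten TFs with only a weak singleton peak (must not
become SE-associated at all). PWMs are mutually dissimilar (pairwise
consensus Hamming distance at least half the width, also against reverse
complements), and planted instances are consensus-sampled — per column the
argmax base with probability 0.9, otherwise a draw from the column — so
the scanner sees realistic near-consensus sites.

Two deliberate idealisations keep the ground truth exact rather than
approximate. First, signal is written only over peak footprints. Second,
the genome is i.i.d. at the configured GC *except* inside
enhancer-cluster neighbourhoods, which are made motif-clean: after
embedding, any additional window that reaches the scan threshold is
re-sampled away and any planted instance that fails to reach it is
re-drawn (pure consensus from the second pass), iterating to convergence
and then verifying that observed hit counts equal planted counts exactly.
Without this, a width-8 motif at $p \le 10^{-4}$ would leave roughly 2-3
chance hits per motif per extended region — enough to randomly promote
decoys past the "> 2" rule. Real data, of course, has no such guarantee:
passing the recovery experiment shows the chain of rules is implemented
faithfully and is identifiable under clean conditions, not that the method
is robust to the motif-hit noise, replicate variation, mappability and
copy-number artifacts of patient ChIP-seq.

## Worked run

```{r}
library(crcscan)

cfg <- synthetic_config(seed = 1)
res <- simulate_and_recover(cfg, keep = FALSE)
res$validation$recovered     # TRUE: top circuitry == planted core set
res$run$circuitries[1, ]     # the five-TF circuit, score 15

# or stage by stage (see analysis/01...05 for the scripted version):
sim <- plant_epigenome(cfg, "sim")
genes <- read_gtf_genes(sim$files$genes)
peaks <- exclude_promoter_peaks(read_narrowpeak(sim$files$peaks), genes)
tab <- call_superenhancers(quantify(stitch(peaks),
                                    read_bedgraph(sim$files$signal)))
plot_hockey(tab)
```

Under the default conditions the ranked curve has ~170 regions: ~160
low-signal background/singleton regions, five decoy clusters (signal
around 5 x 10^4) and five planted SEs (above 10^5); the cutoff lands below
the decoy clusters, all ten clusters are called super, the five core TFs
plus the trio are autoregulated, and the enumerated universe (28
circuitries under the defaults: the core clique's downward closure plus
the two surviving trio pairs) ranks the full planted five-TF set first.

## Numerical and degenerate-input choices

* A single stitched region cannot define a ranked curve; it is flagged
  typical. An empty region set is an error.
* All-equal signals: slope 0, tie resolves to the top index, zero SEs.
* Sequences shorter than the motif scan to an empty hit table; windows
  containing N score those positions as zero bits.
* `score_distribution()` requires finite log-odds entries, i.e. a positive
  pseudocount whenever the PWM contains zeros.
* More than 25 autoregulated TFs without a `max_size` is an error rather
  than an exponential enumeration.
* Coordinates are BED (0-based half-open) in every file and GRanges
  (1-based closed) in memory; conversion happens only at the I/O boundary.
  bedGraph input with overlapping steps is rejected rather than guessed.
* The paper-facing defaults (500 bp extension, strict "> 2", FIMO-style
  $p \le 10^{-4}$) and the ROSE conventions (12.5 kb, 2.5 kb, 50 kb) are
  all plain `crc_params()` arguments.

## Problem sizes

The shipped experiments use 2 x 1.8 Mb genomes, 20 TFs, 210 peaks and 20
motifs per sample; one simulate-and-recover cycle takes on the order of ten
seconds. The recovery experiment (`analysis/05_validate_recovery.R` and
`scripts/acceptance.R`) repeats it across 20 seeds. Oracle-backed property
tests run stitching against a transitive-closure oracle on up to 1,000
peaks, the cutoff against exhaustive tangent search on curves up to
10,000 points, exact p-values against full-word enumeration up to width 6,
and circuitry enumeration against power-set filtering up to 15 nodes.

## Limitations

* One sample per run; cross-sample consensus circuitries and SE
  conservation analyses are out of scope.
* One motif per TF symbol (counts sum if several are supplied); no
  higher-order background, no q-value correction across motifs.
* No BAM/bigWig input — peaks and signal enter as narrowPeak/bedGraph.
* The inflection cutoff, assignment window and autoregulation threshold
  are conventions, not fitted quantities; on real data the candidate list
  should be read as a hypothesis set for orthogonal validation (e.g.
  TF-binding profiling), not as a definitive circuit.
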