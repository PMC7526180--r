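---
title: "Whole-genome subtraction for Y-chromosome marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome subtraction for Y-chromosome marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksubtract)
```

## The problem and the method

In a species with XY sex determination, recombination suppression around
the sex-determining locus lets the Y accumulate sequence the X does not
carry: insertions, diverged gametologs, repeat expansions. Any such
sequence is hemizygous — present in males, absent in females — and can be
turned into a presence/absence PCR sex test. `ksubtract` finds candidate
sequence of this kind from nothing more than low-coverage short reads of
one male and one female, with no reference genome, linkage map, or
assembly:

1. **Merge.** Overlapping read pairs are combined into fragments
   (`merge_pairs()`), so that each sequenced molecule is represented once
   rather than twice over its overlap.
2. **Count.** Fragments are decomposed into all overlapping k-mers
   (k = 27 by default) and counted in canonical (strand-merged) form
   (`count_kmers()`). Reads sample both strands, so a k-mer and its
   reverse complement are the same observation; counting them separately
   would make the subtraction strand-sensitive.
3. **Threshold.** The k-mer spectrum — how many distinct k-mers occur at
   each multiplicity — separates into a sequencing-error peak at count 1
   and a genomic peak near the effective k-mer depth. K-mers below the
   valley between the peaks are discarded (`find_error_threshold()`,
   `filter_by_count()`).
4. **Subtract.** Every k-mer present in the female's filtered table is
   removed from the male's (`subtract_kmers()`). What survives is
   enriched for Y-specific sequence, admixed with false positives
   discussed below.
5. **Reassemble.** The surviving k-mers are assembled into contigs by
   inchworm extension (`assemble()`): a focal k-mer grows one base at a
   time, left and right, for as long as *exactly one* unused k-mer
   matches the terminal k−1 bases; any ambiguity stops the walk. This is
   deliberately stringent — no graph cleaning, no bubble popping — so a
   contig never mixes paths.
6. **Select and verify.** Contigs at least 80 bp long are ranked by
   length and the longest taken forward for primer design
   (`filter_and_rank()`); given primers, `insilico_pcr()` verifies the
   expected product sizes, and `p_distance()` quantifies divergence
   between aligned amplicons.

A recovered Y insertion of length L appears, ideally, as a single contig
of length L + 2(k−1): the insertion plus k−1 bases of flanking shared
sequence on each side, because every k-mer overlapping the insertion by
at least one base is male-specific.

## The validation-panel probability model

A contig that amplifies in the sequenced male and not in the sequenced
female may still be an autosomal or X-linked presence/absence
polymorphism rather than Y-specific sequence. The PCR validation panel
screens each candidate in three stages (the focal pair, then 4 males and
4 females, then 20 more of each sex). Under Hardy–Weinberg with
presence-allele frequency $q$ and dominant amplification, a non-Y
polymorphism survives a panel of $n_m$ males and $n_f$ females with
probability

$$P(q) = \left[1-(1-q)^2\right]^{n_m}\left[(1-q)^2\right]^{n_f}.$$

For the full 25/25 panel, maximising over $q$ (`max_false_positive_prob()`)
gives $P^\* = 0.25^{25} \approx 8.9\times10^{-16}$, attained at
$q^\* = 1 - 1/\sqrt{2} \approx 0.293$; for a single male/female pair the
maximum is exactly 0.25. Note that the model's maximiser is
$1-1/\sqrt{2}$, not 0.5: the commonly quoted bound of $0.25^{24}$ holds
regardless, and `panel_report()` also reports the compounded probability
$1-(1-P^\*)^m$ that *any* of $m$ screened markers survives spuriously.
An X-linked variant (hemizygous males amplify with probability $q$) is
available via `x_linked = TRUE`.

## What the simulator emulates

`simulate_genome_pair()` and `simulate_reads()` generate the synthetic
study on which everything is tested:

* a uniform-random shared background (default 100 kb) standing in for
  the autosomes and X;
* Y-specific insertions of novel sequence (defaults 200, 500, 2000 bp)
  recorded exactly in 0-based half-open truth intervals. Insertions are
  made *junction-distinct* — the first/last inserted base differs from
  the adjacent shared base — because an insertion whose boundary repeats
  the neighbouring base is shift-ambiguous and cannot be exactly
  delimited;
* heterozygous substitutions on the male copy of the shared sequence
  (default rate 10⁻³), emulating the polymorphic differences between the
  two sequenced individuals that contaminate the subtraction;
* one region (default 2 kb) substituted at 2% on the male copy,
  emulating a diverged X/Y gametolog pair;
* paired 150 bp reads from 220 ± 40 bp fragments drawn from either
  strand, at 8× expected base coverage with 0.5% substitution error and
  constant Phred-40 qualities.

It does **not** emulate indel polymorphism or indel sequencing error,
quality-score profiles, GC or PCR bias, duplicate reads, or repeat
families; passing tests on this generator therefore demonstrate the
pipeline's set-algebraic and assembly behaviour, not robustness to every
artefact of real libraries. Real genomes are also far less unique than
uniform-random sequence, so real subtractions see many more ambiguous
extension stops.

`evaluate_against_truth()` scores a run by exact-matching contigs onto
the male genome: *recall* is the fraction of truth-interval bases
covered, *precision* the fraction of contig bases inside truth intervals
extended by k−1 (the legitimate shared flanks).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 27 | k-mer size; odd, so no k-mer equals its own reverse complement |
| `min_overlap` / `max_mismatch_frac` | 10 bp / 0.1 | pair-merging overlap acceptance |
| threshold `t` | auto per sex | minimum retained k-mer count; the spectrum valley |
| `min_contig_length` | 80 bp | shortest contig carried into marker selection |
| `top_n` | 92 | contigs taken forward for primer design |
| `coverage` | 8× | expected sequenced base coverage per individual |

The per-sex thresholds matter most. Too high and genuine Y k-mers at
coverage dips are lost; too low and error k-mers flood the subtraction.
The two sequenced libraries can genuinely need different thresholds when
their error rates differ, which is why each sex's spectrum is
thresholded independently.

## Numerical and design choices

* **Valley detection.** The threshold is the first multiplicity
  $m \ge 2$ with $h_m \le h_{m-1}$ and $h_m < h_{m+1}$, on the histogram
  with absent bins as zeros. A valley presupposes an error peak, so the
  finder requires a descending origin ($h_1 > h_2$) and otherwise raises
  a no-valley error rather than latching onto sampling noise in the
  spectrum tail — error-free input has no valley by construction. The
  pipeline responds to that error by retaining everything (t = 1) and
  flagging the fallback in its manifest. An optional 3-bin median
  smoother (`smooth = TRUE`) guards against one-bin glitches in noisy
  real spectra; toy and simulated spectra are evaluated raw.
* **Order of operations.** Each sex's table is filtered by its own
  threshold *before* subtraction. The male-unique set therefore contains
  k-mers whose female counterpart was sequenced but fell below the
  female threshold — a differential-coverage false-positive source that
  scales with error rate and inverse coverage.
* **Subtraction** is by key only; multiplicities are irrelevant to
  membership. The streaming merge is a sorted join over canonical
  k-mers, so output order is deterministic.
* **Assembly determinism.** Extension candidacy is evaluated against
  unused k-mers only, and consuming one orientation consumes both, so
  every k-mer ends in exactly one contig
  ($\sum_c (\mathrm{len}_c - k + 1) =$ number of distinct k-mers).
  Focal k-mers are taken in sorted order by default (bit-identical
  reruns); `seed_order = "random"` with an explicit seed reproduces the
  historical take-a-focal-k-mer-at-random behaviour. If both
  orientations of a candidate match a terminal overlap, the extension
  stops as ambiguous rather than risking a hairpin.
* **Merging ties** go to the longest qualifying overlap; disagreeing
  overlap bases resolve to the higher-quality read, ties to read 1.
* **In-silico PCR** is exact-match only, on both template strands, with
  product size inclusive of both primer footprints. Its job is verifying
  subtraction contigs against primers designed on those same contigs;
  a thermodynamic mismatch model is out of scope.
* **p-distance** excludes any alignment column containing a gap or N.

## Problem sizes and what the bundled checks show

The test-suite scenarios use a 100 kb background at 8× (about 2,700 read
pairs per sex), which runs the whole pipeline in seconds while leaving
every stage's accounting exactly checkable; insertion-recovery checks
use exhaustive error-free k-mer tables of 20 kb pairs, where the
expected counts are analytic (L + k − 1 unique k-mers, one contig of
L + 2(k−1)).

Under confound-free conditions at 20× (no error, no heterozygosity, no
gametolog divergence), the pipeline recovers all three implanted
insertions exactly: recall 1.0, precision 1.0. Under the full noisy
conditions (8×, 0.5% error, heterozygosity 10⁻³, 2% divergence), recall
of truth bases by ≥80 bp contigs is typically 0.8–1.0 but precision is
only ~0.35–0.5: the male-unique set is dominated by false positives from
female threshold dropout, heterozygous sites, and the diverged gametolog
region, which assemble into short contigs interleaved with the real
ones. This is not an implementation artefact but the method's behaviour
at low coverage — precisely why the original protocol validates every
candidate against a PCR panel, and why only a minority of screened
contigs survive it. Increasing coverage, sequencing multiple homogametic
individuals, or choosing less heterozygous individuals all shrink the
false-positive load.

## Known limitations

* Substitution-only models throughout; an indel in a read or between
  individuals shifts every downstream k-mer and is not modelled.
* The in-memory k-mer table is a sorted string-keyed table; it is
  comfortable to ~10⁷–10⁸ distinct k-mers on a workstation but is not a
  2-bit-packed disk-backed counter, and whole-vertebrate-genome runs at
  billions of k-mers are outside its design envelope.
* Contigs are capped only by ambiguity, never by an explicit length
  limit; on highly repetitive input the stringent unique-extension rule
  stops early and yields many short contigs by design.
* `p_distance()` is a plain proportion of differing sites; it is a
  stand-in for, not a replica of, model-based divergence estimators.
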