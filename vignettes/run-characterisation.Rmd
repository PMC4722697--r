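---
title: "Simulating and characterising nanopore sequencing runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and characterising nanopore sequencing runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porewise)
```

## What porewise models

A MinION-era nanopore experiment records, for each sequenced molecule, a
series of current *events*; a base-caller turns these into *template*
and *complement* 1D base-calls and, where both strands are usable, a
higher-accuracy *2D* consensus call. A flow cell has 512 channels, each
wired to four wells; a mux scan ranks each channel's usable wells into
well-groups g1--g4 by quality, and a standard 48 h run sequences on g1
for 24 h before switching to g2. Run quality degrades over time: pores
die, the per-pore event rate declines, and base quality drifts
downward, with transient dips after the −5 mV bias-voltage step applied
every 4 h.

`porewise` provides (i) a generative simulator of such runs with ground
truth, and (ii) the analyses used to characterise runs: time-binned
yield profiles normalised per active pore, per-read error decomposition
into miscall/insertion/deletion percentages, target-versus-control
spike-in classification, 5-mer representation bias, quality
calibration, and majority-consensus accuracy as a function of
theoretical fold coverage. Because every simulated read carries an edit
script that replays byte-for-byte against its source interval, every
analysis stage can be validated without external aligners or data
downloads.

## The generative model

**Flow cell.** Each of the 2,048 wells holds a usable pore
independently with probability `well_active_prob` (default 0.60).
Within a channel, active wells are ranked by an i.i.d. continuous
quality score, so the expected number of channels contributing to group
k is `512 * P(Binomial(4, p) >= k)` — about 499, 420, 243 and 66 at the
default. Assigned pores receive exponential lifetimes
(`pore_lifetime_mean`, default 18 h, clocked from activation).

**Read production.** A pore starts reads as a non-homogeneous Poisson
process whose intensity is the per-pore event rate divided by the mean
read length in events. The per-pore event rate declines linearly in
global run time, `r(t) = r0 (1 - 0.015 t)` by default; the decline does
*not* reset at the 24 h group switch. This choice is deliberate: the
switch restores the pore *count* (fresh g2 pores), and with the default
group sizes the expected fraction of events produced in the first 24 h
is then 0.67 by direct integration, matching the profile of a standard
run in which roughly two thirds of the data arrive in the first day and
the event rate keeps falling through the second half. Resetting the
decline at the switch would leave the ratio of halves at the g2/g1
group-size ratio (about 0.84) and a first-day fraction near 0.54, which
does not resemble observed profiles.

**Read lengths.** Event counts are log-normal with median 10,700
(`read_len_sdlog` 0.8, chosen so about 20% of reads have at least
21,000 events). No log-normal matches all tail statistics of real runs
simultaneously — the real event-mass-weighted tail is heavier — and
this is a known limitation of the single-distribution choice. Reads
outside the callable range of 200--230,000 events appear in the run log
with no base-calls. The 2D base-call length is 0.367 × the event count
(the 2.7 : 1 events-to-bases ratio). Fragments are placed uniformly
over all positions overlapping the reference and clipped at the edges,
which keeps expected coverage uniform along the reference; a clipped
molecule is shorter, so its event count shrinks proportionally and the
events-to-bases slope is preserved. On a genome-scale reference the
clipping is negligible; on a 50 kb desk-scale reference it avoids
undercovered margins the width of a read.

**Errors.** The corruption model is column-wise: each alignment column
is an insertion with probability `ins_rate`; otherwise it consumes a
reference base, which is deleted or miscalled with per-base
probabilities `del_rate/(1 - ins_rate)` and
`miscall_rate/(1 - ins_rate)`, or emitted as a match. The 1/(1 − ins)
scaling makes the *per-column* operation frequencies unbiased estimates
of the configured rates, so recovery tests can compare observed column
fractions to configuration directly. Defaults are 3%/4%/5%
miscall/insertion/deletion for 2D calls and twice that for the 1D
calls. Deletion probability is multiplied by
`homopolymer_del_multiplier` inside single-base runs of length ≥ 3,
reproducing the characteristic under-representation of homopolymer
5-mers. A per-read log-normal error multiplier (`error_sdlog`, median
1) models molecule-to-molecule variability.

**Qualities.** Per-base Phred scores are normal around a mean that
starts at `q_start_2d` (12.5), declines by `q_decline_per_24h` (2) per
24 h, and drops by `q_dip_depth` during the first 30 min after each 4 h
bias step. The per-read mean is additionally offset by
−`q_error_coupling` × log10 of the read's error multiplier, tying
reported quality to realised accuracy; this is what makes mean quality
anticorrelate with log total error across reads, and it also produces
the declining fraction of 2D *pass* reads (pass requires a 2D call with
mean quality > 9) over the run. During dip windows quality drops
without a matching error increase, so the calibration statistic
10^(−Q/1000)/E shows the characteristic 4 h artefacts.

The 10^(−Q/1000)/E statistic uses the run-summary convention
Q = −1000·log10(1 − p) rather than standard Phred; both conventions
are exposed in `quality_error_stat()` and neither is silently
corrected, since FASTQ base qualities remain standard Phred+33.

## Analysis conventions

* **Error denominator.** Total alignment columns (matches + mismatches
  + insertions + deletions), so miscall% + insertion% + deletion% +
  identity% = 100 exactly and total error is the exact sum of its
  parts. The aligned-read-length denominator is available via a flag;
  soft-clipped ends are excluded either way.
* **Binning.** 15 min bins, left-closed right-open; a read is counted
  in the bin containing its start, and its events are spread over the
  bins it overlaps assuming a steady event rate within the read. A
  pore is "active" in a bin iff it starts a read in that bin or later —
  the only definition computable from read metadata alone. Summaries
  skip the first hour, the hour after the group switch, and the last
  hour.
* **Classification.** A 2D read is target iff exactly the target
  reference has a significant alignment (mapping quality ≥ 10 by
  default), control symmetrically, and unclassified when both or
  neither do. An alternative primary-alignment mode is not implemented.
* **Consensus.** Majority vote per reference site; match/mismatch
  columns vote bases, deletion columns vote "absent" (which can win,
  making the site incorrect), insertions are ignored. Ties break by
  the fixed order A < C < G < T < absent. Zero-coverage sites count as
  incorrect in the headline accuracy and are also reported separately.
* **k-mers.** Read k-mers counted on the strand as written; the
  reference is counted on both strands by default (disable with a
  flag) so comparisons are strand-balanced. Top-10 ties break
  lexicographically.
* **Anchored alignment.** Banded global affine-gap alignment (match
  +1, mismatch −1, gap of length k costs −(2 + k)); if the optimal
  path touches the band the band widens once (×4) before erroring.
  Intended for desk-scale inputs lacking alignments; simulator output
  is analysed through its ground truth.

## Problem sizes and what the tests show

The packaged checks run at desk scale: a 50 kb target (GC 0.508,
matching the E. coli value) plus a 3,555-base synthetic control
spike-in, runs of a few hundred reads (run-level initial event rate
near 150 × 10³ events/h), and consensus experiments at up to 63-fold
coverage averaged over 5 replicates. At these sizes the consensus
reaches ≥ 99.9% site accuracy at 20-fold and ≥ 99.99% at 60-fold with
the default error profile, and parameter-recovery checks resolve the
configured rates within binomial tolerance.

The simulator reproduces the *statistical structure* of a run —
rates, declines, dips, length and error distributions — not its
physics. Raw current, event-level base-calling, ASIC temperature, and
FAST5 containers are out of scope; metadata travels in FASTQ comments
and a TSV run log instead. Real runs also contain structure the
simulator omits: chimeric and repeated reads, non-uniform genomic
coverage, modified bases, and heavy-tailed length mixtures. Passing
tests therefore validate the analysis implementations and the
internal consistency of the model, and calibrate expectations for
well-behaved runs; they do not certify behaviour on adversarial real
data.

## A short example

```{r example, eval = FALSE}
cfg <- sim_config()
refs <- reference_set(seed = 1)
run <- simulate_run(cfg, refs, seed = 1)

series <- exclude_windows(bin_reads(run$reads))
prof <- error_profiles(run$truth, run$calls, run$reads)
aggregate_errors(prof, by = c("read_type", "read_class"))

sim <- simulate_reads_at_coverage(refs$target_seq, fold = 25,
                                  config = cfg, seed = 2)
accuracy_vs_coverage(sim$calls, sim$truth, refs$target_seq,
                     levels = c(5, 10, 20))
```

`run_pipeline()` chains every stage and writes all artifacts plus a
JSON report; `inst/cli/porewise.R` exposes the same stages as shell
subcommands.
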