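---
title: "The low complexity triangle: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The low complexity triangle: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lctriangle)
library(dplyr)
```

## The model

Protein low complexity conflates two local properties that are useful to
keep apart: how *periodic* a segment is, and how *compositionally biased*
it is. The low complexity triangle scores every overlapping window of
fixed length WL (step 1; windows extending past either terminus are
discarded) on both:

**Repeatability (x): MMPR.** The minimum number of substitutions needed to
turn the window into a perfect tandem repeat of some unit of length
`p ≤ ⌊WL/2⌋`. For each candidate period p, window positions `0..WL−1` are
partitioned into modulo classes `C_j = {i : i mod p = j}`; a perfect
period-p repeat is exactly a window in which every class is
monochromatic, so the cheapest way to reach one is to keep each class's
most frequent residue and substitute the rest:

$$\mathrm{cost}(p) = \sum_{j=0}^{p-1}\bigl(|C_j| - \max_a |\{i \in C_j : s_i = a\}|\bigr),
\qquad \mathrm{MMPR} = \min_{1 \le p \le \lfloor WL/2 \rfloor} \mathrm{cost}(p).$$

The modulo-class construction allows a partial final repeat unit, so WL
need not be a multiple of p. Candidate periods stop at `⌊WL/2⌋`: longer
"units" repeat less than twice inside a window and would make every window
trivially near-perfect; this period set also reproduces the documented
x-axis range (0–5 at WL = 10, 0 to WL/2 in general). MMPR counts
substitutions only — insertions and deletions are outside the model.

**Composition (y).** The fraction of the most frequent amino acid,
`max residue multiplicity / WL`, from `1/WL` to 1.

The period-1 cost equals `WL − (mode count) = WL·(1 − y)`, so
`x ≤ WL·(1 − y)` always: the attainable (x, y) set is a triangle. Pooling
windows of a whole dataset into a count grid over the attainable
coordinates (y keyed by the integer mode count to keep cell keys exact)
gives a 2D histogram in which homorepeats sit at (0, 1), direpeats at
(0, 0.5), degenerate tandem repeats in the centre, and random or globular
sequence in the bottom-right corner.

## Parameters that matter

- **Window length WL** (residues; default 20; command-line menu
  10/15/20/25/30, any WL ≥ 2 at the library level). Shorter windows
  shrink the grid (x spans 0..⌊WL/2⌋, y has WL levels), giving a coarser
  triangle but sharper localisation of short repeats; longer windows
  resolve long tandem repeats. WL = 10 is appropriate for regions of a
  few dozen residues, like the ataxin-1 polyQ tract.
- **Step** (default 1). The definition of the method; larger steps are
  exposed for exploration only and simply subsample windows.
- **Regions**: red (x > 8.5, y < 0.275) ⊂ green (x > 7.5, y < 0.325) ⊂
  orange (x > 6.5, y < 0.375), strict inequalities. These absolute
  thresholds were calibrated at WL = 20, where they fall between
  attainable grid values (e.g. 8.5 between x = 8 and x = 9), so strict
  versus non-strict cannot change a count. For any other WL the report is
  still computed with the same absolute thresholds but flagged with a
  warning, and thresholds are user-overridable: no WL-scaled variant of
  the regions is defined anywhere, and inventing one silently would
  change the meaning of the percentages.
- **Alphabet**: the 20 standard residues always; `X`, `B`, `Z`, `U`, `O`
  accepted by default as ordinary distinct symbols (this keeps MMPR well
  defined without guessing what an ambiguity code "really" is), with a
  strict mode to reject them. Gap characters are always rejected — the
  model is defined on ungapped sequence.

## Numerical and degenerate-input choices

- Ties among periods attaining the minimum cost go to the smallest
  period; ties among modal residues go alphabetically. Neither choice can
  affect the (x, y) values, only the reported `best_period` and
  `mode_residue`.
- Sequences shorter than WL yield an empty result at the library level
  (the command-line driver, following the original server's rules,
  instead rejects any record shorter than WL + 5).
- For even WL, pairing positions at period WL/2 caps MMPR at WL/2. For
  odd WL the cap does not hold: an all-distinct window of length 15 costs
  `15 − p` at every period, minimised at `p = 7` giving 8 > ⌊15/2⌋. The
  grid therefore sizes its x axis to the larger of ⌊WL/2⌋ and the
  observed maximum and sets `x_exceeds_half` when extended.
- Counts of 1 map to log10(1) = 0 in the heatmap; the fill scale spans
  `[0, log10(max count)]` and empty cells are left as background rather
  than painted as log10(0).
- Percentages are reported to 2 decimal places; the "outside" percentage
  complements the widest region (most windows, ties broken by the most
  permissive thresholds), which under the defaults is orange.
- One window costs `O(WL · ⌊WL/2⌋)` in the compiled scan; whole-dataset
  analysis is a single pass over all windows with no sliding-count
  shortcuts, so every window is scored by the definition verbatim.

## What the synthetic generators emulate

`generate_sequence()` produces the sequence classes whose triangle
signatures are known a priori — homorepeats (0, 1), direpeats (0, 0.5),
perfect tandem repeats (x = 0 whenever the unit length is at most
⌊WL/2⌋), mutated tandem repeats (central x), uniform-random and
composition-biased i.i.d. sequence — each from an explicit per-call seed
that never touches the global RNG state. Substitutions planted by the
tandem generator never replace a residue with itself, so the nominal
mutation rate is an effective substitution rate. `polyq_atx1()`
reconstructs the 29-residue ataxin-1 polyglutamine region
(`[Q]12 H Q H [Q]14`) and `collagen_like()` a Gly-X-Y tandem region with
random X/Y per unit.

These generators emulate *local window statistics*, not real proteomes:
i.i.d. draws have no domain architecture, no species-specific amino-acid
usage, and no correlation between neighbouring regions. Tests passing on
them demonstrate that the measures, the grid and the occupancy summaries
behave as the model predicts on sequences of known structure; they do not
certify occupancy percentages for any real proteome, which depend on real
compositional statistics.

Test problem sizes were chosen so the full suite exercises each claim at
scale while staying quick to run: exhaustive oracle comparison over all
3-letter strings up to length 8 (~9,800 windows against a brute-force
tiling oracle), 10⁵ random windows for the WL = 10 maximum, 1.2 × 10⁴
random windows for the triangle-constraint sweep, and a 200 × 200-residue
uniform-random dataset (36,200 windows) for the globular-proxy occupancy
check.

## Design decisions that were genuinely open

- **Id handling**: the record id is the first whitespace-delimited header
  token (UniProt convention); the rest of the header is kept as metadata.
  Duplicate ids are an error — pooled counts would otherwise silently
  merge proteins.
- **Mixed valid/invalid multi-FASTA** at the command line: the run is
  rejected with per-record diagnostics by default; `--skip-invalid`
  drops offenders with a warning instead. Silently skipping by default
  would make batch occupancy figures depend on which records happened to
  fail.
- **Region sets from feature tables**: users supply pre-sliced FASTA (or
  use `slice_region()`/`--split` with explicit coordinates); no feature
  parsing or retrieval is built in, keeping the tool offline and
  deterministic.
- **Occupancy pooling** is a plain sum over windows irrespective of
  protein length — long proteins weigh more, by design, because the unit
  of observation is the window, not the protein.

## Known limitations

- MMPR is substitution-only; a single indel inside an otherwise perfect
  repeat can raise the score disproportionately.
- Region thresholds are only calibrated for WL = 20; occupancy numbers at
  other window lengths are comparable to each other but not to the
  WL = 20 literature values.
- The consensus repeat unit is not reconstructed beyond its length
  (`best_period`); no alignment of repeat copies is produced.
- For proteome-scale inputs the per-window table grows as one row per
  residue; the grid and occupancy summaries remain tiny.
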