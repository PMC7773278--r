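# lctriangle

Low complexity triangle analysis of protein sequences in R.

Low complexity regions (LCRs) — homorepeats, direpeats, degenerate tandem
repeats, compositionally biased segments — are widespread in proteomes and
hard to summarise with a single score because "low complexity" mixes two
distinct properties: *repetitiveness* and *compositional bias*. The low
complexity triangle separates them. Every overlapping window of fixed
length WL (default 20, step 1) is scored on two axes:

- **x = MMPR**, the *minimum number of mutations to a perfect repeat*: for
  each candidate period `p ∈ 1..⌊WL/2⌋`, window positions are partitioned
  into modulo classes `C_j = {i : i mod p = j}`; the cost of period p is
  `Σ_j (|C_j| − max residue multiplicity in C_j)`, and MMPR is the minimum
  cost over p. MMPR = 0 means the window is a perfect tandem repeat of some
  short unit; high MMPR means no periodic structure.
- **y**, the *fraction of the most frequent amino acid* in the window,
  ranging from `1/WL` (all distinct) to 1 (homorepeat).

Because the period-1 solution is always available, `x ≤ WL·(1 − y)`: high
compositional bias forces high repeatability, so the pooled 2D histogram of
all windows occupies a triangle. Homorepeats sit at (0, 1), direpeats at
(0, 0.5), degenerate tandem repeats in the centre, and random/globular
sequence piles into the bottom-right corner. Occupancy of three nested
bottom-right regions — red (x > 8.5, y < 0.275), green (x > 7.5, y < 0.325)
and orange (x > 6.5, y < 0.375), strict inequalities, calibrated at
WL = 20 — summarises how much of a dataset is ordinary high-complexity
sequence; everything outside orange is some flavour of low complexity.

The package is tidyverse-native: records and per-window measures are
tibbles, results chain with the pipe, grids have `tidy()`/`glance()`
methods and a ggplot2 `autoplot()`.

## Worked example: the ataxin-1 polyQ region

The wild-type polyglutamine tract of human ataxin-1 (positions 197–225) is
27 glutamines with two inserted histidines, `[Q]12 H Q H [Q]14`. Being only
29 residues long it is analysed at WL = 10:

```r
library(lctriangle)

m <- analyze_sequence(polyq_atx1(), wl = 10)
m
#> # A tibble: 20 × 8
#>   id          start    wl  mmpr best_period max_fraction mode_residue mode_count
#>   <chr>       <int> <int> <int>       <int>        <dbl> <chr>             <int>
#> 1 ATX1_polyQ…     1    10     0           1          1   Q                    10
#> 2 ATX1_polyQ…     2    10     0           1          1   Q                    10
#> 3 ATX1_polyQ…     3    10     0           1          1   Q                    10
#> 4 ATX1_polyQ…     4    10     1           1          0.9 Q                     9
#> 5 ATX1_polyQ…     5    10     1           1          0.9 Q                     9
#> # ℹ 15 more rows
```

The 29-residue region yields 29 − 10 + 1 = 20 windows. All-glutamine
windows score (0, 1.0); windows holding one histidine score MMPR 1, and
windows holding both histidines score MMPR 2 — the two residues that would
have to be mutated back to glutamine to restore a perfect repeat. The
signal cloud stays in the top-left corner of the triangle:

```r
g <- triangle_grid(m)
glance(g)
#> # A tibble: 1 × 6
#>      wl total_windows x_max occupied_cells max_count x_exceeds_half
#>   <int>         <int> <int>          <int>     <int> <lgl>
#> 1    10            20     5              3         8 FALSE

region_occupancy(g)
#> Triangle region occupancy (20 windows, wl = 10)
#> # A tibble: 3 × 3
#>   region windows percent
#>   <chr>    <int>   <dbl>
#> 1 red          0       0
#> 2 green        0       0
#> 3 orange       0       0
#> outside orange: 100.00%
```

No window enters the high-complexity corner — 100% of the region is low
complexity (the report also warns that the region thresholds were
calibrated at WL = 20). Contrast with a uniform-random 200-residue
sequence at WL = 20, which behaves like globular sequence:

```r
rnd <- generate_sequence("random_uniform", length = 200, seed = 42)
glance(region_occupancy(triangle_grid(analyze_sequence(rnd, wl = 20))))
#> # A tibble: 1 × 6
#>     red green orange outside total_windows    wl
#>   <dbl> <dbl>  <dbl>   <dbl>         <int> <int>
#> 1  77.9  96.7    100       0           181    20
```

`autoplot(g)` (or `save_triangle(g, "triangle.png")`) renders the
heatmap with log10 window abundance and the region outlines.

## Command line

A thin wrapper over `lct_run()` mirrors the original web server's input
rules (valid residues, each sequence ≥ WL + 5 residues, WL from
10/15/20/25/30) and adds batch mode:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/lct.R", package="lctriangle"))')" \
    --wl 10 --out results/ input.fasta
```

writing the per-window TSV, the grid TSV, the occupancy JSON and (with
`--plot`) the heatmap.

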