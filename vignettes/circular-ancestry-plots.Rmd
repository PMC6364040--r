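---
title: "Circular ancestry-composition plots: model, layout and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular ancestry-composition plots: model, layout and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(admixring)
```

## The problem

Model-based clustering programs such as ADMIXTURE, structure and frappe
estimate, for each individual, the fractions of its genome contributed by
each of K assumed ancestral source populations. The result is an N x K
matrix Q of ancestry proportions whose rows sum to one. The conventional
display is a rectangular stacked-bar plot, which stops being publishable
once a study spans hundreds of populations or thousands of individuals:
the bars become too thin and the page too wide.

admixring draws the same information on a circle of fixed perimeter.
Each individual is a length-fixed radial bar partitioned into K colored
segments whose radial extents are proportional to the individual's ancestry
fractions. Crucially, every population receives the **same angular space**,
360/P degrees for P populations, regardless of how many individuals it
contains — large cohorts never crowd out small ones. A population of
interest can additionally be highlighted as a pie chart of its mean
composition at the center of the ring.

## The sorting rule

The ring is only readable if neighboring populations are similar. The
ordering used here is:

1. For each population, compute the arithmetic mean of its members'
   proportion vectors. The component with the largest mean is the
   population's **representative ancestry** (ties resolve to the lowest
   ancestry index).
2. Populations are categorized into K groups by representative ancestry.
   Groups are arranged around the circle in ascending ancestry index —
   the Q-file column order is the only canonical order available, and a
   group whose ancestry is nobody's maximum is simply empty and takes no
   space.
3. Within each group, populations are sorted in descending order of the
   representative mean proportion; exact ties fall back to ascending
   lexicographic label order so the output is deterministic.
4. Individuals within a population are sorted in descending order of their
   own proportion of the *population's* representative ancestry; exact
   ties keep the input row order. (The alternative reading — sorting each
   individual on its personal argmax — would interleave colors within a
   population block; sorting on the population's representative component
   produces the smooth within-block gradient the display is known for, and
   is the reading adopted here.)

The whole ordering is a pure function of the proportion values and the
labels, never of input row order (up to runs of exactly tied individuals),
which the test suite checks by shuffling inputs and by comparison with a
naive brute-force reference on a thousand random datasets.

## Input formats

* **Q matrix** (`read_q_matrix()`): whitespace-separated proportions, one
  row per individual, no header, no IDs — exactly what ADMIXTURE writes.
  Rows must sum to one within a tolerance of 1e-4 (real files carry
  rounding error from their 6-decimal output); `renormalize = TRUE`
  instead divides each row by its sum, which any proportion data that sums
  to 100% per item can use. Proportions from any method are acceptable as
  long as rows sum to one.
* **Individual file** (`read_individual_file()`): one row per individual,
  row-aligned with the Q matrix. The first column is the individual ID and
  the last is the predefined group identifier (population, sampling
  location, phenotype class...). The three-column EIGENSTRAT `.ind` layout
  is therefore accepted as-is, its middle sex column ignored, as is a
  minimal two-column `id group` file. No published schema exists for this
  file; this column convention is a documented assumption.

## Geometry

`circle_geometry()` collects the tunable geometry, all in relative figure
units:

| parameter      | default     | meaning                                      |
|----------------|-------------|----------------------------------------------|
| `start_angle`  | 90 degrees  | first population starts at the top            |
| `direction`    | clockwise   | winding of the population sequence            |
| `inner_radius` | 0.45        | inner edge of the bars                        |
| `outer_radius` | 1.0         | outer edge of the bars (bar length is fixed)  |
| `label_radius` | 1.04        | anchor radius of population labels            |
| `pie_radius`   | 0.40        | radius of the central highlight pie           |

The orientation defaults match the common convention for circular
population-structure figures; nothing in the method depends on them and all
are configurable. Within each population span, individuals occupy
equal-width wedges; within each wedge the K radial segments stack from
ancestry 1 innermost to K outermost (a stacking direction has to be picked;
column order is the natural one). Separators are zero-width radial lines at
population boundaries — they consume no angular space and can be switched
off when P is large. Labels sit at each span's angular midpoint, rotated
radially; labels landing on the left half of the circle (screen angles
between 90 and 270 degrees) are flipped 180 degrees with their anchor
swapped so the text still reads outward.

The central pie shows the **mean** proportion vector of the target
population, each slice spanning 360 times the mean proportion. For a
single-individual target this reduces to that individual's personal
ancestry, so the same mechanism highlights individuals. By default the
target stays in the ring *and* appears as the pie; `target_in_ring = FALSE`
removes it from the ring.

## Numerical choices

* Row validation tolerance 1e-4 by default; renormalized rows sum to one
  to machine precision.
* Argmax, population and individual tie-breaks are all fixed (lowest
  ancestry index, ascending label, original row order) so that two runs on
  identical inputs are byte-identical.
* Label ordering for ties uses radix (C-locale) string order,
  locale-independent.
* The plot specification — the canonical text listing of every drawn
  primitive — rounds coordinates to 6 decimals and normalizes negative
  zeros, making it a stable golden surface for diff-based testing. The
  serialized Q matrix uses 17 significant digits, so a parse/serialize
  cycle is lossless.
* Zero-proportion segments and zero-width pie slices are skipped at
  drawing time rather than emitted with zero extent.
* Degenerate inputs are first-class: a single population occupies the full
  360 degrees, a single-individual population fills its whole span, and a
  pure-ancestry individual draws as one segment.

## The synthetic generator

`simulate_admixture()` emulates the statistical structure of a clustering
run's output: each population receives a center drawn from a flat Dirichlet
on the K-simplex, and its individuals are drawn from
Dirichlet(concentration x center). The defaults — 203 populations of about
a dozen individuals each (`survey_scale_sizes()` reproduces the exact
2345-individual split) and K = 8 — mirror the scale of a large worldwide
ancestry survey, the regime the circular display exists for; the default
concentration of 50 gives within-population standard deviations of a few
percent, comparable to real clustering output for well-sampled populations.

What the generator does *not* emulate: spatial autocorrelation between
neighboring populations, the characteristic near-zero noise floor of
ADMIXTURE estimates, correlated ancestries across adjacent K values, or
label errors. Passing tests therefore demonstrate the geometric and
ordering contracts of the display, not robustness to the pathologies of any
particular inference tool — which is the appropriate scope, since the
package consumes proportions and never infers them.

## Testing strategy and problem sizes

The suite verifies the ordering against an independent 30-line brute-force
reference over 1000 random datasets (up to 10 populations, K up to 6, N up
to 50), equal-space and bar-partition conservation over 500 random layouts
with population sizes from 1 to 30, pie exactness on 100 random targets
plus closed-form cases, byte-identical repeated runs at the full
203-population / 2345-individual / K = 8 scale, and the command-line
contract (including the `-i/-q/-t` invocation shape) in subprocesses.
These sizes exercise every code path at the scale the tool is intended for
while keeping the default test run under a minute.

## Worked example

```{r example}
ds <- simulate_admixture(n_populations = 12, k = 5,
                         size_range = c(3, 10), seed = 1)
ord <- resolve_order(ds)
head(vapply(ord$populations, `[[`, character(1), "label"))

lay <- compute_layout(ord, ds$Q, target = "Pop007")
lay

f <- file.path(tempdir(), "ring.svg")
spec <- render_figure(lay, default_palette(5), f)
length(spec)
```

## Known limitations

* One ring per figure: displaying several K values as concentric circles
  is out of scope.
* No collision-avoiding label placement beyond the 180-degree flip; with
  hundreds of populations, labels shrink and may still overlap (the
  separator lines can be disabled in the same regime).
* Ancestry columns are matched by index only; aligning components across
  different clustering runs is a separate problem this package does not
  attempt.
* The custom-order file pins the complete display list: populations not
  listed are omitted, which doubles as a coarse inclusion filter.
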