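# admixring

Circular visualization of ancestry composition for population geneticists.

Model-based clustering tools (ADMIXTURE, structure, frappe) summarize each
individual's genome as a vector of K ancestry proportions summing to one —
an N x K "Q matrix". The standard rectangular stacked-bar display breaks
down for modern surveys with hundreds of populations: bars get too thin and
the page too wide. `admixring` draws the same data around a circle of fixed
perimeter:

* every population gets the **same angular space** (360/P degrees),
  regardless of sample size;
* each individual is a **length-fixed radial bar** split into K colored
  segments proportional to its ancestry fractions;
* populations are grouped by their **representative ancestry** — the
  component with the largest mean proportion, argmax<sub>a</sub>
  (1/n<sub>p</sub>) Σ<sub>i∈p</sub> q<sub>ia</sub> — with groups in
  ascending ancestry index, populations within a group in descending
  representative proportion, and individuals within a population in
  descending order of the population's representative component;
* a target population can be highlighted as a **central pie chart** whose
  slice for ancestry a spans 360 × (mean proportion of a).

Inputs are the plain-text formats already in circulation: an ADMIXTURE-style
`.Q` matrix and a row-aligned individual label file (EIGENSTRAT-style
`.ind` or minimal `id group`). Outputs are the figure (PDF/PNG/SVG), the
color scheme used, the sorted proportion table, and a deterministic
plot-spec text file that fully describes every drawn primitive.

## Worked example

```r
library(admixring)

ds  <- simulate_admixture(n_populations = 12, k = 5,
                          size_range = c(3, 10), seed = 1)
ds
#> ancestry dataset: 68 individuals, 12 populations, K = 5 ancestries

ord <- resolve_order(ds)
head(vapply(ord$populations, `[[`, character(1), "label"))
#> [1] "Pop004" "Pop011" "Pop009" "Pop010" "Pop001" "Pop003"

s <- summarize_population(ds, "Pop007")
s
#> population 'Pop007': 9 individuals, representative ancestry 5 (0.457)
round(s$mean_proportions, 3)
#> [1] 0.123 0.030 0.017 0.373 0.457

lay <- compute_layout(ord, ds$Q, target = "Pop007")
lay
#> circular layout: 12 populations (30.0000 degrees each), 68 individuals, K = 5, center pie
round(lay$center_pie$end_deg - lay$center_pie$start_deg, 1)
#> [1]  44.2  10.8   6.2 134.4 164.4

spec <- render_figure(lay, default_palette(5), "ring.svg")
length(spec)
#> [1] 370
```

Reading the output: the twelve populations each occupy 30 degrees; the
ring starts with the populations whose representative ancestry is
component 1 (led by `Pop004`, the one with the highest mean of it) and
proceeds through the ancestry indices. `Pop007` is highlighted in the
center: its pie slices (44.2, 10.8, 6.2, 134.4, 164.4 degrees) are exactly
360 times its mean proportions, so the 0.457 representative component
spans 164.4 degrees. The plot spec's 370 lines enumerate one header plus
every segment, separator, label and pie slice drawn.

The same pipeline from a shell, mirroring the classic invocation shape:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "admixring.R", package = "admixring"))')
Rscript "$CLI" synth -o data --pops 12 -k 5 --seed 1
Rscript "$CLI" plot -i data.ind -q data.Q -t Pop007 -o ring -f pdf
Rscript "$CLI" plot -i data.ind -q data.Q -o ring_only   # no center pie
```

`plot` writes `<out>.pdf`, `<out>.plotspec.tsv`, `<out>.colors.tsv` and
`<out>.sorted.tsv`; `validate` checks inputs without plotting. See
`vignettes/circular-ancestry-plots.Rmd` for the full account of the
sorting rule, geometry defaults, numerical choices and limitations.

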