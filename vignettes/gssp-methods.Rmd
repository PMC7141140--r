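---
title: "Gaze self-similarity plots: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze self-similarity plots: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gssp)
```

## The model

An eye tracker reports a raw gaze sample — a point $(g_x(i), g_y(i))$ in
screen pixels — at each sampling instant. Classic visualizations (scan-paths,
heat maps) show *where* gaze went but hide *when*; recurrence plots show
temporal structure but require a fixation detector and a similarity
threshold, both of which change the picture. The gaze self-similarity plot
avoids both choices: for a recording of $n$ samples it is the $n \times n$
matrix

$$\mathrm{gssp}(i, j) = \frac{\sqrt{(g_x(i) - g_x(j))^2 +
(g_y(i) - g_y(j))^2}}{N}, \qquad N = \sqrt{x_{max}^2 + y_{max}^2},$$

the pairwise Euclidean distance between raw samples normalized by the screen
diagonal, so every entry lies in $[0, 1]$. Rendered with 0 as black and 1 as
white, fixations appear as dark squares on the diagonal, saccades as bright
bands, and returns of gaze to an earlier location as dark off-diagonal
blocks. There is no threshold and no event detection anywhere in the
construction.

The plain matrix is symmetric, so half of it is redundant. The directed
variant removes the redundancy: for each pair $a < b$ (sample $a$ recorded
first) the upper-right cell $(a, b)$ stores the *directed horizontal*
distance $d_x = (g_x(b) - g_x(a)) / x_{max}$ and the lower-left cell
$(b, a)$ the *directed vertical* distance $d_y = (g_y(b) - g_y(a)) /
y_{max}$, both in $[-1, 1]$. With the screen origin at the top-left,
positive means rightward (horizontal triangle) or downward (vertical
triangle). The color rendering maps a cell value $v \ge 0$ to the red
channel and $v < 0$ to the green channel, so at full resolution a pixel is
only ever black, red or green.

Because the directed matrix stores every pairwise displacement on both axes,
it is invertible up to translation: given the absolute position of any one
sample, every other position follows by adding the rescaled displacements
(`reconstructScanpath()`). The package validates the sign conventions through
this roundtrip property rather than by trusting any single formula
transcription: for every generator archetype and every anchor index,
reconstruction must reproduce the input to $10^{-9}$.

Two conventions had to be fixed where the method's description is internally
inconsistent or silent:

* **Triangle assignment.** The piecewise definition of the directed matrix
  can be read as putting $-d_x$ at $i \ge j$ (the lower triangle), which
  contradicts the accompanying figure legend and every interpretive use of
  the plots (horizontal distances upper-right, vertical lower-left, diagonal
  running upper-left to lower-right). The package follows the figure
  convention and records it in the object's `convention` slot.
* **Reconstruction rescaling.** The reconstruction formulas add matrix
  values directly to pixel coordinates, but the stored values are normalized
  by $x_{max}$ / $y_{max}$; the implementation rescales before adding. The
  roundtrip tests are the arbiter that this (and the piecewise signs) is the
  consistent reading.

## Texture metrics

A self-similarity plot is an image, so image-texture statistics quantify it.
The values are first discretized onto $K + 1$ levels, $I(x, y) = \lfloor
\mathrm{gssp}(x, y) \cdot K \rfloor$ (with 1 mapping to $K$; default
$K = 10$). The co-occurrence matrix $CM(a, b)$ then counts how often level
$a$ occurs at a cell whose offset partner (displacement $(d_x, d_y)$ applied
as row$+d_x$, column$+d_y$) has level $b$. For the directed matrix the count
domain is restricted to one triangle at a time — strict upper for the
horizontal part (`"H"`), strict lower for the vertical part (`"V"`) — and
partners falling outside the domain are skipped, not wrapped.

Three statistics summarize a co-occurrence matrix:

* homogeneity $\sum_{i,j} \frac{cm(i,j)}{1 + |i - j|} \in [0, 1]$, 1 for a
  constant image;
* contrast $\sum_{i,j} (i - j)^2\, cm(i, j) \in [0, K^2]$, 0 for a constant
  image, sensitive to long jumps between gaze positions;
* uniformity (energy) $\sum_{i,j} cm(i, j)^2 \in [0, 1]$, high when the same
  paired values repeat throughout the plot.

These ranges, and the constant-image values, hold for a *frequency*
co-occurrence matrix; the counting definition alone leaves raw counts. The
package therefore always normalizes by the number of counted pairs — the
only reading under which the stated ranges are true.

Two further choices where the method description is silent:

* **Directed values vs. discretization.** The discretization assumes values
  in $[0, 1]$ but directed cells lie in $[-1, 1]$. The default discretizes
  the magnitude $|v|$, because the metric interpretations (long jumps,
  repeated distances) are about distance size; a `signed = TRUE` switch maps
  $\lfloor (v + 1)/2 \cdot K \rfloor$ instead for analyses where direction
  matters at the co-occurrence level.
* **Diagonal cells.** The triangular domains are strict (diagonal excluded),
  matching the summation limits of the counting definitions; the `"full"`
  part includes the diagonal.

Evaluating the three metrics for both triangles and the offsets $(0,1)$,
$(1,0)$ and $(1,1)$ yields 18 named attributes per observation
(`featureVector()`). Uniformity at the two axis-aligned offsets is in
practice nearly collinear with uniformity at $(1,1)$ within each direction;
`pruneCorrelated()` reports all same-direction, same-metric pairs above a
Pearson threshold (default .9) and drops, by default, uniformity at $(0,1)$
and $(1,0)$ in both directions, leaving 14 attributes.

## Moving-window analysis

For long recordings one large matrix is unreadable and $O(n^2)$ in memory;
instead `slidingWindows()` cuts the recording into windows (default length
1 s, step 0.16 s), `metricSeries()` builds the directed matrix of each
window and evaluates a keyed metric, and `indicatorCorrelation()` correlates
the series with a binary task indicator sampled at the window centers.
Alignment choices, stated once: the series timestamp is the window *center*
(symmetric lag against the indicator); windows cover $t \in [start, start +
length)$, the last window is the last one fully inside the recording (a
window closing exactly at the recording end keeps the final sample); windows
with fewer than 3 valid samples yield `NA` rather than an error; the
indicator is a right-continuous step function of half-open intervals.

## Synthetic gaze generators

No public gaze recordings accompany the method, so the package generates
sequences with the statistical structure of the classic stimulus archetypes.
The generators define the package's study conditions; their defaults were
fixed once, on field-typical values, and are not tuned per analysis:

* sampling rate 100 Hz — a common remote-tracker rate; the method itself is
  index-based, so the rate only scales matrix sizes;
* fixation/saccade sequences: Gaussian within-fixation scatter (no drift or
  microsaccade model), instantaneous saccades by default (fixation blocks
  dominate the plots at analysis scale; an optional linear transition mode
  exists);
* ambient preset: 20 fixations of 0.2 s spread widely; focal preset: 4
  fixations of 1.5 s within a small central region — the short/long
  fixation, long/short saccade contrast between exploratory and inspecting
  viewing;
* reading: lines of 8 evenly spaced word fixations, 0.18 s per word, 2 px
  jitter, rapid return sweeps, vertical position never decreasing; the
  backward mode mirrors the within-line direction;
* smooth pursuit: constant-speed traversal of a piecewise-linear path
  (default 200 px/s) with 3 px tracking noise where used;
* movie-with-text (`genMovieWithText()`): 6 reading segments of 7–9 s
  separated by 2–5 s pursuit breaks, mirroring the kind of cartoon-plus-
  overlay-text schedule the moving-window analysis is designed for.

All randomness flows from one explicit `seed` argument per generator
(restored afterwards, so the caller's RNG stream is untouched); a fixed seed
gives bitwise-identical output.

What passing tests on these generators shows — and what it does not: the
generators reproduce the *geometry* of the archetypes (block structure,
sweep directionality, recurrence lines, outlier crosses), so they exercise
every code path and pin down the direction of the metric contrasts (reading
raises horizontal contrast and lowers uniformity relative to pursuit or
focal viewing, windowed horizontal contrast correlates positively and
uniformity negatively with text visibility). They do not model tracker-
specific noise spectra, blink artifacts, saccade dynamics or individual
differences, so numeric metric *values* on real recordings will differ;
only the signs and orderings carry over.

## Numerical choices and degenerate inputs

* Matrix equality (symmetry checks, roundtrips) uses absolute tolerance
  $10^{-9}$; oracle comparisons in the test-suite use $10^{-12}$.
* Discretization clamps to $[0, K]$ after flooring, so a value of exactly 1
  (or floating-point dust above it) lands on level $K$, not $K + 1$.
* A co-occurrence request whose domain admits no pair (e.g. $n = 1$)
  returns a degenerate object flagged by `pairCount = 0`; the metric
  functions refuse it explicitly rather than returning 0/0.
* Empty sequences are an error for matrix construction; unparsable rows in
  gaze files are flagged invalid in place (dropping them would silently
  shift sample indices), and validation resolves them under an explicit
  drop/clamp/error policy. Validation is idempotent.
* Sliding-window arithmetic adds $10^{-9}$ slack before flooring so that
  accumulated floating-point error in `start + k * step` cannot drop the
  final window.
* Indices are 1-based throughout, as everywhere in R; fixation annotation
  files are accepted in the 0-based half-open on-disk convention and
  converted on read.

## Problem sizes

The test-suite and the acceptance analyses run on deliberately moderate
sizes, chosen as representative rather than stress-testing: oracle
equivalence on 200 random matrices with $n \le 30$; roundtrip reconstruction
on sequences up to $n = 200$ at every anchor; 20 seeded replicates for every
distributional claim (archetype orderings, indicator-correlation signs) with
movie recordings of roughly 60–80 s at 100 Hz analysed in ~400 windows each.
A full-resolution plot of a 60 s recording at 250 Hz would be a
$15000 \times 15000$ matrix; the block-mean `downsample` argument of the
render functions exists for exactly that case.

## Known limitations

* The package consumes fixation annotations but never produces them; no
  event detection (dispersion- or velocity-based) is included, by design.
* No statistical testing or classification is built in: the feature table is
  a plain matrix, and standard tools (`kruskal.test`, `randomForest`, ...)
  apply directly.
* Proprietary tracker formats are not parsed; input is delimited text.
* The matrix interchange format (dense CSV) carries no screen provenance;
  reading a matrix back requires restating the geometry.
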