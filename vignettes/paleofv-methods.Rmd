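---
title: "Methods behind paleofv: stop-codon dating and virus-host codivergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind paleofv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleofv)
```

`paleofv` packages the bespoke computations of endogenous foamy virus (FV)
paleovirology: dating an endogenous retrovirus (ERV) integration from the
in-frame stop codons its reading frames have accumulated, and testing
whether a virus phylogeny tracks its host phylogeny — by event-based
reconciliation, a permutation test, and a codivergence regression that can
be inverted to date virus nodes against a host fossil calibration. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the bundled synthetic data generators do and do not
emulate.

## 1. The stop-codon clock

After a retrovirus integrates into the germ line its reading frames evolve
neutrally: premature stop codons appear at a rate governed by the host's
neutral substitution rate, so the in-frame stop-codon frequency of a
proviral gene carries a time signal.

**Census.** `census_stop_codons()` counts stops (`TAA`, `TAG`, `TGA`;
standard code, as appropriate for mammalian nuclear genomes) over the
framed span of a `coding_sequence`. Two conventions matter:

* the *terminal* codon of the span is excluded by default
  (`exclude_terminal = TRUE`), so an authentic ancestral stop is not
  counted as a post-integration mutation;
* codons containing any non-`ACGT` symbol are excluded from numerator and
  denominator alike — counting them either way would bias the frequency,
  and the process model below says nothing about ambiguous bases. Gaps are
  stripped before framing, so the census is alignment-invariant.

The frequency is kept at full floating precision; a 3-significant-figure
rendering (`frequency_display`) is provided because that is how such
frequencies are conventionally reported.

**Substitution model.** The mutation process is taken as neutral,
homogeneous, and independent across sites and base types. The unique chain
with these symmetries is the equal-rates (Jukes–Cantor-type) process: a
site leaves its base at total rate $r$ (substitutions/site/year) and the
replacement is uniform over the other three bases. Its transition
probability is closed form,
$$P(\text{same after } t) \;=\; \tfrac14 + \tfrac34 e^{-4rt/3},$$
with the remaining mass split equally. `evolve_sequence()` samples each
site's *endpoint* directly from this law — distributionally identical to
simulating every substitution event, but exact and $O(\text{sites})$.
The default rate, $r = 2.2\times10^{-9}$ subs/site/year, is an average
neutral rate for mammalian genomes; a deliberate overestimate of
$1\times10^{-8}$ is used when stress-testing whether neutral change alone
could displace a sequence in a phylogeny (the "pseudogene effect"
experiment, `mutate_alignment_members()`, which also translates the
mutated sequences with stops rendered `*`; no realignment is performed —
sequences stay in their original alignment coordinates).

**Analytic oracle.** `analytic_stop_probability()` gives the exact
expected stop frequency at time $t$: for each codon, the product over its
three sites of stay/change probabilities, summed over the three stop
codons, averaged over codons. Every simulator in the package is tested
against this closed form (at $3$ Monte-Carlo standard errors), and as
$t\to\infty$ it approaches the uniform-stationary value $3/64$.

## 2. Grid Monte-Carlo dating

`date_erv()` implements the dating procedure. A stop-free *model sequence*
(the intact pol gene of an extant relative) is mutated in silico over a
grid of hypothetical durations — by default 5 to 200 Myr in steps of
5 Myr — with 1,000 independent replicates per grid time, and each
replicate is censused.

**CDF construction.** At each grid time $t_k$ the exceedance probability
$\hat q(t_k) = \Pr\{f_{\text{sim}}(t_k) \ge f_{\text{obs}}\}$ is
estimated from the replicates. Because stop accumulation is
(near-)monotone in time, $\hat q$ is read as a first-passage CDF of the
time needed to reach the observed frequency. Monte-Carlo noise can make
$\hat q$ locally non-monotone, so the running maximum over increasing $t$
is taken. This exceedance reading is one defensible formalisation of
"CDF of time duration to accumulate stops at the observed frequency"; a
trajectory-wise first-passage construction would differ only through
replicate-level correlation across grid times, which the independent
per-time replicates deliberately do not model.

**Summaries.** With $\Delta q_k = q(t_k) - q(t_{k-1})$ renormalised by
$q(t_{\max})$: mean $\sum_k t_k\,\Delta q_k$ (right-endpoint convention on
the 5-Myr grid), median the smallest $t_k$ with $q \ge 0.5$, mode the grid
cell with the largest mass, and the 95% interval from the 0.025/0.975
crossings. Renormalisation is allowed only when $q(t_{\max}) \ge 0.99$;
otherwise `summarize_age()` refuses rather than silently truncating the
tail of an unreached target. With several model sequences, `date_erv()`
reports per-model summaries, the min–max range of per-model means (the
usual presentation convention), and a pooled summary from the average of
the per-model renormalised masses — pooling convention being ambiguous in
the field, both views are exposed.

**Seeding.** One master seed; each (model sequence, grid time) gets a
substream derived from the master seed, the grid index, and a hash of the
sequence *content* — so identical model sequences give identical results
regardless of their labels, and any single cell can be reproduced in
isolation.

## 3. Cophylogeny reconciliation

`reconcile()` maps a rooted binary virus tree onto a rooted binary host
tree under the event model of Jane-style reconciliation: cospeciation,
duplication, duplication-and-host-switch, loss, and failure-to-diverge,
with vertex costs $(-1, 0, 0, 0, 0)$ by default — i.e. the optimum
*maximises cospeciations*, the natural question when asking how much of a
virus phylogeny codivergence alone explains.

Design choices:

* **Exact dynamic programming, not a genetic algorithm.** At the tree
  sizes of host–virus studies (≤ 25 tips) the $(virus\ node \times host\
  node)$ DP is exact and instantaneous; stochastic search would add
  irreproducibility for no benefit. Oversized inputs are refused.
* **Untimed host tree.** Switches may land on any non-ancestral host
  position. Timed (zoned) reconciliation can only forbid switches, so this
  relaxation can only *increase* attainable cospeciation counts — worth
  remembering when comparing against timed reconciliations.
* **Free losses.** With loss and failure-to-diverge at cost 0 (required;
  nonzero values are rejected), the optimum depends only on the three
  priced internal-node events. Losses are still counted from the traceback
  embedding for reporting; with a bijective tip association
  failure-to-diverge cannot arise.
* **Determinism.** Among equal-cost solutions the solver prefers more
  cospeciations, then fewer switches, then the smallest host assignment in
  postorder, making the reported embedding reproducible.

The DP is validated against an independent brute-force enumerator (every
internal virus node tried at every host node, feasibility and event labels
evaluated from first principles) on random small instances.

**Random tip mapping.** `random_tip_mapping_test()` replaces the observed
associations with uniform random bijections, re-solves each, and reports
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_{\text{perm}})$
(add-one estimator, so $p$ is never zero and the test is valid at
finite sample size). The observed count can be overridden — e.g. to test a
conservative manual re-reading of one ambiguous event — which can only
enlarge $p$. The null treats branches as interchangeable; it does not
distinguish close from distant host switches.

## 4. Codivergence regression and node dating

Along codivergent lineages, virus branch lengths (amino-acid
substitutions/site) should be proportional to host branch durations (Myr).
`extract_branch_pairs()` collects exactly the virus branches whose two
ends track host time: parent end a cospeciation, child end a cospeciation
or an associated tip; branches ending in duplications or switches carry no
host-time interpretation and are excluded, as is the virus root branch
(no parent event). Host durations come from a `node_ages` table keyed by
clade tip sets — the stable key when ages come from a published timetree
rather than from the tree's own branch lengths. Zero-duration host
branches are dropped with a warning rather than fitted at $x = 0$.

**Fit.** `fit_codivergence()` regresses virus branch length on host
duration by OLS, *with* an intercept: forcing the line through the origin
is an extra assumption nothing in the data model justifies, and the
intercept absorbs terminal-branch artefacts. Influence is screened by
Cook's distance with the conventional $3\times$-mean threshold, removing
the single worst point and refitting until the largest current distance
falls below the threshold.

One numerical subtlety is load-bearing: the threshold is **fixed at
$3\times$ the mean Cook's distance of the initial fit**. Cook's distances
are strongly right-skewed, so in an outlier-free Gaussian sample of ~23
points the largest distance exceeds $3\times$ the *current* mean in ≈ 98%
of datasets; a threshold recomputed after every removal therefore keeps
firing and erodes the sample point by point. Fixing the threshold at the
pre-pruning scale — which gross, high-leverage outliers inflate — removes
exactly those outliers and then stops. The fully recomputed variant
remains available (`recompute_threshold = TRUE`) for comparison. A
numerically perfect fit (RSS $\le 10^{-20}\,$TSS) is declared outlier-free
outright, since its Cook's distances are floating-point noise. Every
removal is recorded in order in a ledger, so `n_used + removals = n`
always.

**Inverse prediction.** `estimate_node_date()` inverts the fit at a new
branch length $\ell$: duration $\hat d = (\ell - \hat a)/\hat b$ (clipped
at 0), date $= \text{calibration} - \hat d$. The 95% interval propagates
the coefficient covariance through $\hat d$ to first order (delta method)
with a $t$ quantile on the residual degrees of freedom. Fieller's
construction is the classical alternative; on small $n$ with a
well-determined slope the two agree closely, and the delta interval is
always finite and well-defined, which suits automated pipelines. Fits with
non-positive slope are refused — they cannot be inverted meaningfully.

## 5. What the synthetic generators emulate

`make_coding_sequence()` draws sense codons i.i.d. from a codon usage
profile (uniform by default; a GC-biased preset exists for sensitivity
checks), plants a requested number of stops at random positions, and
appends a terminal stop — so a census of the output returns exactly the
planted counts. It emulates reading-frame structure and codon composition
only: no codon-position rate heterogeneity, no selection, no indels, no
SINE insertions interrupting the frame. Real pol genes have non-uniform
codon usage, so absolute dating results on synthetic models demonstrate
the *machinery*, not the composition-specific ages of real elements —
which is why analytic self-consistency (recovering a known age planted via
the closed form) is the primary correctness check, and why the validation
fixes its six stand-in pol model sequences (1,143–1,155 codons, realistic
pol lengths) once rather than redrawing them per run: the model sequences
play the role of fixed study inputs.

`make_cophylo_pair()` grows an ultrametric Yule host tree (default birth
rate 0.05/lineage/Myr — mammal-like depths for tens of tips), copies it as
the virus tree with branch lengths scaled by a protein clock (default
0.007 subs/site/Myr, an FV-like value), and plants host switches as
single-tip SPR moves constrained to change the rooted topology, recording
the moved tips as ground truth. It emulates codivergence-with-switches
only: no incomplete sampling, no duplication events, no rate variation
across virus lineages.

`make_regression_pairs()` draws durations uniformly, adds Gaussian noise
around a chosen line, and appends planted outliers verbatim. The
validation scenario places three gross outliers at high leverage (extreme
durations, large residuals of alternating sign) because that is the
configuration in which influence-based pruning is well identified — and
the configuration the real outlying branches (the two deepest, longest
branches and one fast terminal branch) actually occupy. Clustered
same-sign outliers at low leverage can mask one another; no one-at-a-time
deletion diagnostic is reliable there.

The bundled 17-taxon virus/host tree pair
(`inst/extdata/*_17_synthetic.*`) is likewise a constructed stand-in, not
transcribed published data: a mammal host timetree with FV-like tip
associations, congruent except for a bat-virus/aye-aye-virus sister pair
and a shuffled New World monkey clade. Its exact reconciliation yields 14
cospeciations of 16 internal nodes, with the two non-cospeciating nodes at
precisely those planted mismatches.

## 6. Validation problem sizes

The test suite runs entirely from code-generated data: censuses up to
1,163 codons; simulator-versus-oracle comparisons at 500–1,000 replicates
per grid time on 400–1,000-codon sequences; dating self-consistency as 12
seeded runs of the full 1,000-replicate procedure on a 5–100 Myr grid
(the planted 40 Myr age sits comfortably in the interior); reconciliation
oracles on exhaustively enumerated placements for 4–6-tip tree pairs; the
permutation test at 400–1,000 permutations; and regression coverage over
200 seeded datasets of 23 points. These sizes make every stochastic check
a 3-standard-error comparison with comfortable power while keeping the
whole suite in the minutes range.

## 7. Known limitations

* The stop-codon clock assumes strict neutrality from integration onward
  and a single homogeneous rate; lineage-specific rates or gene conversion
  would bias ages.
* The dating CDF inherits the grid: nothing finer than the step (5 Myr by
  default) is resolved, and all summaries are grid-valued.
* Reconciliation supports binary trees only, and its untimed switch model
  is permissive; counts should be read as upper bounds relative to timed
  analyses.
* The codivergence regression treats branch pairs as independent
  observations; phylogenetic correlation between adjacent branches is not
  modelled.
* Inverse-prediction intervals are first-order; for poorly determined
  slopes (relative SE above ~25%) Fieller-type intervals would be wider
  and more honest — the fit refuses only the sign, not the precision.
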