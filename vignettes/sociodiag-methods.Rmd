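---
title: "Network diagnostics for small intervention groups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network diagnostics for small intervention groups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociodiag)
```

## The measurement model

Group-delivered behavioral interventions (lifestyle programs, support
groups, skills classes) often assume that social ties form among members
and that those ties carry the behavior change. `sociodiag` implements a
monitoring cycle for that assumption: measure the group's network at
strategic points during delivery, compare a panel of diagnostics to
thresholds fixed *before* the data are seen, and hand the group leader a
concrete, participant-named action plan when the structure looks
sub-optimal.

The data are roster-based name generators: each respondent sees the full
list of group members and marks those with whom they share a stated
relation (e.g., going to someone for advice outside of sessions, or
discussing program topics outside of sessions). This yields, per wave and
relation, a directed graph on the **full roster**. Two modeling
commitments follow from the survey design:

* **Non-respondents stay in the network.** A member who skipped the
  survey can still be *nominated*, so they appear as a node that may
  receive arcs but sends none, and they stay in every metric denominator.
  Densities are consequently depressed by non-response — deliberately so,
  since a member nobody can reach is a real structural deficit of the
  group, not a missing-data artifact to be normalized away.
* **Self-nominations and off-roster alters are rejected, not dropped.**
  In a roster design both indicate data-entry errors, and silent repair
  would hide them.

Wave and relation labels are matched case-insensitively because field
usage is inconsistent ("week4", "Week 4", "session four").

## The diagnostic panel

All metrics are computed on the directed adjacency matrix $A$ with $n$
roster members and $m$ arcs; "dyad" always means an unordered pair,
classified mutual / asymmetric / null (the MAN census).

* **Density** $= m / n(n-1)$.
* **Isolates**: members with zero total degree.
* **Degree**: in-, out- and total degree per member; the threshold rule
  is applied to each member's total degree.
* **Reciprocity**: the headline value is dyad-based *non-null*
  reciprocity, mutual $/$ (mutual $+$ asymmetric), because weak one-way
  ties are the actionable unit; arc-based reciprocity
  ($2\cdot$mutual$/m$) is reported alongside.
* **Subgroups**: weakly connected components computed *among
  non-isolates*, reported as the count in excess of one. Isolation and
  splintering are distinct findings with distinct remedies, so isolates
  are excluded here to avoid double-counting them as one-member
  "components".
* **Centralization** (Freeman form): $\sum_i (c_{\max} - c_i)$ divided by
  the theoretical maximum of that sum at size $n$. The centrality
  conventions are fixed as: total degree (maximum $2(n-1)(n-2)$, attained
  by a star of mutual ties); raw in-/out-degree (maximum $(n-1)^2$);
  closeness as reachability-scaled closeness
  $\frac{r}{n-1}\cdot\frac{r}{\sum d}$ over the $r$ reachable targets,
  with 0 for a node reaching no one (maximum sum $n-1$, attained by an
  out-star — this denominator keeps the value in $[0,1]$ for *every*
  digraph, which the classical undirected star denominator does not);
  betweenness on directed geodesics scaled by $(n-1)(n-2)$ (maximum sum
  $n-1$). The diagnostic threshold is applied to the total-degree
  variant; all five are exposed because peaked in-degree (a guru) and
  peaked out-degree (a broadcaster) call for different responses.
* **Transitivity percent**: the fraction of directed two-paths
  $i \to j \to k$ with $i, j, k$ distinct that are closed by $i \to k$.
  Two-paths returning to their origin ($i = k$) are excluded: closure
  through a 2-cycle is reciprocity, not transitivity.
* **Compactness cohesion**: the mean of reciprocal geodesic distances
  over all ordered pairs, with unreachable pairs contributing 0. Unlike
  average path length it is defined for disconnected networks, which
  early-stage groups almost always are.

A metric whose denominator is empty (reciprocity of an empty network,
transitivity with no two-paths) is **undefined**, carried as `NA`, and
treated by the diagnostics as "cannot evaluate" — never as 0 and never as
a violation.

Values are kept at full precision internally; rendered tables round to 3
decimals, half away from zero.

## Thresholds and the action report

The shipped default rules are: isolates $= 0$; every total degree $> 1$;
non-null reciprocity $> 0.50$; excess components $= 0$; density in the
open band $(0.15, 0.50)$ — some density is needed for anything to
diffuse, while very dense groups spend their time redundantly;
total-degree centralization $< 0.25$; transitivity percent $> 0.3$;
compactness cohesion $> 0.25$. The cohesion bound deserves a note: the
source threshold conventions are ambiguous about direction for this
metric, while its rationale (more cohesion is better) is not, so the
default flags *low* cohesion ($< 0.25$) and the rule — like every rule —
lives in a YAML config the analyst can override per study.

Every flagged metric triggers its numbered menu of teaching methods
(pair isolates with hubs, pair the endpoints of one-way ties, bridge
subgroups, ice-breakers for low density, sideline the most central member
for high centralization, and so on). The method texts live in a data
file, not code, so wording can be versioned; rendering substitutes the
actual display names of the targeted participants (isolates, hubs,
low-degree members, unreciprocated dyads, one suggested bridge pair
across the two largest subgroups, the most central member). Tie-breaks
are always roster order, and reports are pure functions of their inputs —
regeneration is byte-identical. A panel that passes everything produces
the explicit instruction *not* to change teaching methods; a flagged
report carries the standing instruction to implement at least two
recommendations per subsequent session.

## The bootstrap density comparison

Dyadic observations are not independent — each member sits in $n-1$ of
them — so a classical t-test on tie indicators is invalid. The
between-wave test resamples **nodes**: each replicate draws $n$ members
with replacement, applies that *same* node sample to both waves
(preserving the dependence between waves induced by shared membership),
and measures the density difference of the induced networks. Arcs are
inherited from the original members at the sampled positions; dyads
formed by two copies of the same original member have no defined tie
value and are excluded from numerator and denominator alike. Then

$$ t = \frac{d_2 - d_1}{\widehat{SE}_{boot}}, $$

with $\widehat{SE}_{boot}$ the standard deviation of the replicate
differences and a two-sided p-value from the standard normal reference.
Conventions at the edges: if every replicate difference is identical
(e.g., the two waves are the same network) the SE is 0 and $t$ is defined
as 0 when the observed difference is 0, signed infinity otherwise. A
replicate in which all $n$ draws landed on one member (probability
$n^{1-n}$) has no evaluable dyads and is dropped. Seeds are mandatory;
the same seed gives bit-identical results, and the caller's RNG state is
restored.

**Calibration.** The test's operating characteristics are checked by
simulation under a null in which both waves are drawn independently from
the same **sender/receiver random-effects model**
(`simulate_heterogeneous()`: tie probability
$\mathrm{logit}^{-1}(\mu + a_i + b_j)$ with normal activity and
popularity effects, SD 1 on the logit scale — moderate heterogeneity).
This is the appropriate null because it *has* the row/column dependence
the node bootstrap is built to handle; under it the empirical type-I
error at nominal 0.05 sits within $[0.03, 0.08]$ (500 null pairs,
$B = 1000$). Under a dyad-independent (Erdős–Rényi) null the same test is
markedly conservative (rejection rate well below nominal): with
multinomial node counts $k_i$, a replicate weights dyad $(i,j)$ by
$k_i k_j$, inflating the bootstrap variance by roughly
$E[k_i^2 k_j^2] \approx 3$–$4\times$ when no true node-level dependence
exists. That behavior is asserted as such in the tests (conservative,
never anti-conservative); users should know the test trades power for
validity when ties happen to be independent.

## Perceived Cohesion Scale

The six-item scale (7-point Likert) is scored as belonging (items 1–3),
morale (items 4–6) and total (all six) — per respondent first, then
averaged within wave; missing items are excluded pairwise. Reliability is
Cronbach's alpha over complete rows,
$\frac{k}{k-1}\bigl(1 - \sum_j s_j^2 / s_T^2\bigr)$ with $k = 6$.
Unidimensionality is summarized by the first eigenvalue of the $6\times6$
item correlation matrix, i.e., principal-component extraction: with the
handful of respondents a small group yields, richer factor estimators
(ML factor analysis, polychoric correlations) are not identified, and the
first eigenvalue is the statistic that remains meaningful at that scale.
Between-wave change is a one-way ANOVA F on respondent-level totals,
df $(1, n_1 + n_2 - 2)$; with two groups this is exactly the squared
pooled t.

## Synthetic data: what it emulates, and what it does not

* `simulate_dyad_census()` draws a network with an **exact** MAN census —
  which dyads are mutual/asymmetric is uniform, but the counts are hit
  exactly, never merely in expectation. Density and non-null reciprocity
  of the result are therefore deterministic functions of the spec, which
  is what makes worked examples and acceptance checks reproducible rather
  than flaky.
* `simulate_two_waves()` evolves a census-exact wave 1 by keeping each
  arc with a retention probability and forming each absent arc with a
  formation probability, with per-wave respondent masks (non-respondents
  send nothing). Wave-2 expected density is analytically
  $r\,d_1 + f\,(1 - d_1)$, which the tests verify by Monte Carlo.
* `simulate_heterogeneous()` is the dependent-null generator described
  above.
* `simulate_pcs()` generates one-factor Likert items:
  $\mathrm{round}(\mathrm{latent}_i \cdot \lambda_j + \varepsilon)$
  truncated to $[1,7]$. Rounding adds variance $\approx 1/12$, which the
  analytic alpha used in the recovery tests accounts for; pushing the
  latent mean near the ceiling reproduces the compressed,
  socially-desirable response pattern typical of cohesion self-reports.
* `pilot_demo()` is a deterministic, hand-constructed 11-member group in
  the canonical two-wave shape: 8 then 7 respondents of 11, four
  never-connected isolates, a pre-existing pair that starts as a separate
  subgroup and is integrated by wave 2, advice censuses (3m, 3a) →
  (7m, 6a) and discussion censuses (0m, 3a) → (1m, 4a). It is labelled
  synthetic: it reproduces the published *summary structure* of a pilot
  group of this kind, not any real group's raw data.

None of the generators model homophily, selective attrition, or
tie-formation feedback (members befriending their friends' friends over
time). Passing tests on this synthetic universe therefore validate the
*measurement and decision machinery* — parsing, metric arithmetic,
thresholding, report generation, resampling — not the sociological
realism of any particular group's evolution.

## Numerical and design choices

* Presentation rounding is 3 decimals, half away from zero; internal
  computation never rounds.
* Undefined (0/0) metrics are `NA` end to end; JSON renders them `null`.
* All orderings (arc lists, target lists, tie-breaks for hubs and central
  members) follow roster order, making every output deterministic.
* Graph algorithms with standard definitions (geodesic distances, weak
  components, Brandes betweenness) are delegated to igraph; every metric
  is nevertheless verified against independent brute-force enumeration
  (Floyd–Warshall distances, matrix-power geodesic counting, triple
  loops) on 1000 random digraphs of up to 7 nodes in the test suite.
* Validation problem sizes: 1000 digraphs for oracle equivalence, 500
  null pairs at $B = 1000$ for calibration, $n = 500$ respondents for PCS
  parameter recovery, 100 random specs for the pipeline smoke test.
  Default $B$ for real analyses is 5000.

## Limitations

The tool diagnoses *structure*, not mechanism: it cannot tell whether a
flagged low density reflects failing group formation or merely
non-attendance, and it does not model diffusion of behavior through the
measured ties. Thresholds are field-informed starting points, not
validated cut-points; studies on existing (rather than newly formed)
networks should expect to shift them upward. The bootstrap p-value relies
on a normal reference for the studentized difference, which is a large-
sample argument applied to small networks — interpret borderline p-values
accordingly. And with typical group sizes around a dozen, every
individual-level finding (who is isolated, who is central) is one survey
answer away from changing; the reports are prompts for a group leader,
not estimates with standard errors.
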