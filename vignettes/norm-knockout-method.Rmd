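---
title: "The norm knockout method: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The norm knockout method: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`normknockout` simulates the evolution of cooperation under indirect
reciprocity with **private reputations**. A population of $N$ agents plays
the *giving game*: a donor either cooperates, paying cost $c$ so that the
recipient gains benefit $b$ ($b > c > 0$), or defects, transferring
nothing. A donor's action rule is fixed — cooperate if and only if its
private image of the recipient is Good — so all behavioural variation
comes from *assessment norms*.

A norm is a 4-locus binary genotype over alleles G/B. The loci answer, in
order: how do I judge a donor who (1) cooperated with a Good recipient,
(2) cooperated with a Bad recipient, (3) defected against a Good
recipient, (4) defected against a Bad recipient? All $2^4 = 16$ norms are
present in the model. Six have established names: ALLG (GGGG), ALLB
(BBBB), Shunning SH (GBBB), Stern Judging SJ (GBBG), Image Scoring IS
(GGBB) and Simple Standing ST (GGBG); the package labels the other ten by
their genotype strings. Internally a norm is an integer 0–15 with locus 1
as the most significant bit and G = 1, which makes assessment an O(1) bit
lookup and crossover/mutation bit arithmetic; the encoding is exercised
exhaustively in the tests.

Each generation consists of $R$ rounds. A round has two phases:

* **Phase A (games).** Every agent donates once, to a recipient drawn
  uniformly from the other $N-1$ agents. The intended action follows the
  donor's image of the recipient and is inverted with the
  *implementation-error* probability $q$. Payoffs accumulate as
  $U_i = bW_i - cV_i$, with $W_i$ donations received and $V_i$ given.
* **Phase B (images).** Every agent privately re-evaluates **every**
  donor: observer $i$'s new image of donor $j$ is $i$'s norm applied to
  ($j$'s realized action, $i$'s current image of $j$'s recipient), then
  inverted with the *perception-error* probability $p$. The whole matrix
  updates synchronously from its pre-phase-B state; self-images are
  pinned to Good.

At the end of a generation norms evolve by a genetic algorithm: each of
the $N$ offspring slots draws two parents (with replacement, self
allowed) by roulette selection with probabilities
$\Pi_i = (U_i - U_{\min})^2 / \sum_j (U_j - U_{\min})^2$, applies
per-locus uniform crossover, then inverts each locus with mutation
probability $m$. Generations do not overlap. A new generation restarts
with all images Good and payoffs zero.

**The norm knockout method** excludes one norm (or several) from ever
existing: the initial population is drawn uniformly from the remaining
norms, and any agent whose offspring genotype lands on a knocked-out norm
is reassigned a norm drawn uniformly from the complement. Comparing runs
with and without the knockout identifies *indispensable* norms: norms
whose absence leaves the replication-averaged terminal cooperation ratio
below 0.1, even though some of them (SH, IS) are minorities once
cooperation is established.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `N` | agents | 500 (`paper`), 200 (`desk`) | — |
| `G` | generations | 1000 / 500 | generations |
| `R` | rounds per generation | 500 / 200 | rounds |
| `b` | benefit of a donation | 5 (studied range 3–6) | payoff |
| `c` | cost of a donation | 1 | payoff |
| `p` | perception error | 0 or 0.001 | probability/update |
| `q` | implementation error | 0 or 0.001 | probability/action |
| `m` | mutation rate | 0.01 | probability/locus |

The `desk` preset (N = 200, R = 200, G = 500, 10 replications) is the
package's working scale for tests and the acceptance script; the `paper`
preset (N = 500, R = 500, G = 1000, 50 replications) is the full scale,
several CPU-hours per sweep. The choice of desk dimensions keeps the
per-agent interaction density (R games per agent per generation) of the
same order as the full scale while making a replication a matter of
seconds. Scale matters for the knockout results — see *Limitations*.

## Design choices

**Evaluation timing.** The model description ties phase B to the donor's
action "in the last round", yet round 1 would then evaluate an undefined
record (resolved there by attributing a random action). The package ships
both readings. The default, `same_round`, lets phase B of round $t$
evaluate round $t$'s realized actions and pairings against the pre-update
images: it is self-consistent, leaves nothing undefined, and every action
gets evaluated exactly once. The literal `lagged` mode evaluates round
$t-1$'s record and attributes a uniformly random action and recipient to
every donor in round 1; the per-generation injection of that random
round-1 evaluation turns out to be hostile to the rise of cooperation,
which is a further reason `same_round` is the default. Both modes are
engine-tested; the emergence phenomena in the acceptance suite are
properties of the default.

**Synchronous updates.** All phase-B evaluations read the pre-update
image matrix. A sequential update would make the result depend on an
agent ordering the model never defines.

**Degenerate roulette.** When every payoff is equal (e.g. a generation
with no cooperation at all, or `R` so small that all agents tie) the
selection formula is 0/0; the package uses the uniform distribution, the
unique symmetric completion, and tests cover the case.

**Counting realized actions.** The cooperation ratio counts realized
(post-`q`) actions — what recipients actually experience — divided by
$N \cdot R$ per generation.

**Ties in the majority norm.** At census ties the lowest integer code
wins, deterministically; ties are practically impossible at N = 500 but
common in small test populations.

**Terminal averaging.** "Average cooperation after the run" is read as
the mean over a terminal window, by default the final 10% of generations
(50 generations at desk scale), averaged over replications. The window is
a parameter so the final-value reading is equally testable.

**Majority-transition window.** Transitions are sampled every generation
in a window of 20 generations before and 100 after the first generation
whose cooperation ratio exceeds 0.8, truncated at the first ALLG majority
(after cooperation is established, tolerant norms trade the majority
frequently and later majorities carry no signal).

**RNG discipline.** One seeded stream per replication with a fixed draw
order — per round: recipient uniforms, implementation-error uniforms,
then perception-error flips via geometric skipping over the off-diagonal
entries in column-major order (an exact i.i.d. Bernoulli($p$) process
that costs $O(pN^2)$ draws instead of $N^2$); per generation: parent,
crossover, mutation, then knockout-reassignment uniforms. The compiled
production engine and the naive double-loop reference engine consume the
stream identically and are verified bit-identical over 100 random small
configurations. Experiment sweeps derive the seed of replication $r$ in
cell $k$ as `master + 1000k + r`.

## What the simulations show — and what they cannot

The package's tests demonstrate, at desk scale: the emergence of
cooperation from the all-norm melting pot (cooperation exceeds 0.8 in
most seeds), the strict-to-tolerant majority alternation with SH
appearing before the ST/ALLG regime, and the collapse of cooperation when
SH is knocked out. These are stochastic, scale-dependent phenomena of the
model — not of any empirical system. The model has no spatial structure,
no partner choice, no gossip, a single action rule, and full private
observation of every interaction; none of these idealisations are
features of real reputation systems.

Scale is a real limitation: with N = 200 and 500 generations the
knockout of IS, and of SJ at large $b$, suppresses cooperation far less
reliably than published full-scale behaviour — smaller populations let SH
fixate by drift before its antagonists matter — so the desk-scale values
the acceptance script reports for those cells sit above the
indispensability threshold. The escalation path is the `paper` preset
(50 replications, overnight) via `sim_preset("paper", ...)` or the CLI's
`--preset paper`: in exploratory full-scale runs with this package the
IS-knockout collapse and the ≈30% SJ-knockout ceiling reappear. The
error-regime ST knockout is a separate known limitation: in the same
exploratory full-scale runs this implementation sustained intermediate
cooperation in that cell rather than a collapse, while reproducing the
other full-scale phenomena (emergence with and without errors, the
strict-to-tolerant alternation, the SH and IS knockout collapses, the SJ
benefit ceiling), so that cell likely hinges on an unstated detail of
the error regime.

## Numerical notes

* Payoffs are exact: $\sum_i U_i = (b-c) \times$ total realized
  cooperations holds to machine precision and is asserted over random
  configurations.
* `p = 0`, `q = 0`, `m = 0` short-circuit to exact no-noise paths
  (`p = 1` likewise forces inversion), so boundary configurations are
  deterministic given the pairing sequence.
* All simulation state is integer except payoffs; image matrices are
  0/1 integers, norms 0–15.
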