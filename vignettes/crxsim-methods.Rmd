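---
title: "Modeling information diffusion from a clinic-based community resource referral intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling information diffusion from a clinic-based community resource referral intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crxsim)
```

## The problem

Community resource referral interventions hand a patient, at the point of
clinical care, a personalized printed list of local health-promoting
resources (a "HealtheRx"): food pantries, fitness programs, smoking
cessation services, housing support, and so on. Clinical trials of such
interventions repeatedly find that around half of recipients *share* what
they learned with other people. A trial that randomizes individuals cannot
measure that second-hand reach, yet it may be the intervention's largest
effect. crxsim is a desk-scale agent-based model built to study exactly
that: how resource information injected at clinical encounters ("clinical
doses") diffuses through a population as people go about their days,
co-locate, and talk ("social doses") — and how delivery choices change the
spread.

## Model structure

The world holds **agents** (ages 16--94, with sex, race, ethnicity, a
household, optionally a workplace or school, and an activation threshold
$\alpha_i$), **places** (households, workplaces, schools, clinics,
resource sites on a planar kilometre frame), and **resources** — a
specific service at a specific place, with an inertia $\gamma_j$.

Time advances in one-hour steps. Each simulated day every agent draws a
fresh 24-hour activity template, uniformly, from the pool matched to their
(age band, sex, race, ethnicity) stratum and day type — emulating the
time-use-survey matching structure in which each demographic stratum owns
a pool of plausible days. Each hour the engine:

1. moves agents to their activity's location (home / work / school / a
   uniform out-of-home draw within 5 km of home / the nearest site
   providing a mapped service);
2. issues and delivers a HealtheRx to any agent doing a medical-care
   activity at a clinic (at most one per agent per day), dosing each of
   its up to 40 items with the delivery mode's source;
3. lets co-located agents exchange information;
4. resolves use-or-not (A/B) decisions for eligible health-maintenance
   activities;
5. leaves knowledge decay to lazy evaluation.

### Knowledge dynamics

Agent $i$'s knowledge of resource $j$ is a score
$\beta_{ij} \in [0,1]$. An information dose from source $x$ updates it as

$$\beta' = \lambda\,\beta^{\varepsilon_x}(1-\beta) + \beta,$$

with $\lambda = 0.991$ (allowable range $[0.991, 0.9994]$) and source
exponents $\varepsilon = \{\text{Doctor } 0.05,\ \text{Nurse } 0.15,\
\text{ClinicalStaff } 0.25,\ \text{Use } 0.2,\ \text{Peer } 0.9,\
\text{None } 1\}$; smaller exponents mean stronger boosts, so a
physician-delivered dose moves $\beta$ more than hearing the same thing
from a peer. The update has fixed points at 0 and 1 and never decreases
$\beta$.

Two numerical consequences drive design choices documented here:

* **Decay.** Taken literally with $\varepsilon_\text{None} = 1$, the
  update *raises* $\beta$ (0.5 becomes 0.74775), although $\lambda$ is a
  decay parameter. The package therefore defaults to geometric decay
  ($\beta \leftarrow \lambda\beta$ per idle hour), which is strictly
  decreasing and matches the jump-then-decline trajectory shape the model
  is meant to produce; the literal form is retained as
  `decay_mode = "as_printed"` for fidelity experiments. Decay is applied
  lazily from each entry's `last_update`; because
  $\beta\lambda^{t-s}$ ranks identically to $\beta\lambda^{-s}$ for every
  $t$, the per-agent "best-known resource" is order-stable between doses,
  which the engine exploits with an incrementally maintained cache.
* **New knowledge.** Since 0 is a fixed point, a dose about a previously
  unknown resource can never create knowledge under the raw update. New
  entries therefore start at `beta_init` (default 0.1) before their first
  boost. Initial seeded scores are Uniform(0.1, 0.5).

Stores are capped at 200 entries; at capacity a new entry is admitted only
if it beats the current minimum-$\beta$ entry, which is evicted (ties
resolved toward the lower resource id). Eviction is the model's notion of
forgetting.

At initialization agents are seeded with knowledge of 10--100 resources
within 1 mile (1.609 km) of home, 1--5 at 1--3 miles, and 1--5 beyond,
clipped to what exists in each ring.

### Information sharing

Each activity carries an ordinal propensity to *receive* information
(p-score: none / low / medium / high), parameterized into rates 0 / 0.05 /
0.15 / 0.30 by default. Sleeping is always `none`; grocery shopping
`medium`; socializing on the job and obtaining medical care `high`. Each
hour, a receiver co-located with $s-1$ others samples up to
$m = 10$ potential givers without replacement; each potential pair fires
independently with the receiver's activity rate (equivalently, the number
of fired contacts is $\text{Binomial}(\min(m, s-1), p)$). A fired giver
transmits their current top-$\beta$ resource (`share_policy = "top_beta"`,
$k = 1$ per exchange; a $\beta$-weighted draw is available), and the
receiver takes a Peer-source boost. Receiver characteristics never
modulate the probability. Transmissions within an hour read the knowledge
state at the start of the exchange step — an hourly-snapshot semantics
that also makes the vectorized engine provably equivalent to a
straight-line reference implementation, which the test suite checks event
for event. The contact cap $m$ keeps dense places $O(nm)$; with groups
smaller than $m$ it is inactive, so small-world runs recover full mixing.

HealtheRx provenance is tracked per entry: clinical doses set an
`rx_derived` flag, and a Peer transmission propagates the giver's flag to
the receiver's entry. This is what lets the experiments separate agents
who ended up holding HealtheRx-derived information through clinical versus
exclusively social routes.

### Resource-use decisions

Health-maintenance activities mapped to services (fitness, spiritual
practice, weight management, ...) face an A/B choice: among known
resources offering a mapped service, the agent scores each as
$\beta_{ij}\,\delta_{ij}\,\gamma_j$ and uses the best one iff the score
exceeds their activation $\alpha_i$ (drawn Beta(2, 2)); otherwise they
continue their previous activity. Distance enters as
$\delta = e^{-d/d_0}$ with $d_0 = 2$ km: the printed multiplicative form
of the rule rewards raw distance, but distance is effort, so the package
implements a factor that decreases with it. A resource's inertia
$\gamma_j \sim$ Uniform(0.5, 1) is the friction of actually using it.
Using a resource logs a use event and applies a Use-source boost.

One deliberate deviation from a literal reading: *scheduled* medical-care
activities resolve to the nearest primary-care resource directly rather
than through the A/B threshold. Routing clinic visits through the decision
rule would make clinical dosing contingent on already knowing a clinic
with a high score — essentially no HealtheRxs would ever be issued at
default parameters — whereas the intervention's premise is that people
present for care and receive the prescription there. A/B gating still
governs all other health-maintenance activities.

## Synthetic data

The generator *is* the study condition set. Defaults: 10,000 agents on a
16 km × 16 km planar box (a desk-scale stand-in for a ~106 mi² urban
region), 56% female, mean age ≈ 44.5 (uniform within bands 16--30 /
31--45 / 46--65 / 66--94 at weights 0.30 / 0.28 / 0.27 / 0.15, chosen so
the implied mean sits within 44 ± 1), race 59/25/16% and ethnicity 84/16%
marginals, ~4,000 households, 300 workplaces, 20 schools, 10 clinics and
250 resource sites offering 1--4 of 12 service types. Schedule pools hold
20--80 templates per stratum and day type; each weekday template has a 1%
chance of containing a clinic-visit hour (0.5% weekends), so with daily
redraws roughly 10--15% of agents are clinically dosed over four weeks.
A ~10-condition catalog with age-graded prevalences stands in for the
clinical indication logic; every agent carries a base service indication
by age status so prescriptions are never empty.

What the generator does **not** emulate: real household co-residence and
commuting structure beyond shared anchors, seasonality of schedules
(deliberately omitted), digitally mediated sharing, negative information,
and the empirical calibration of the source intervention's full-scale
population. Passing tests therefore demonstrate mechanism correctness and
qualitative reproduction of the diffusion findings at desk scale — not
calibrated absolute reach counts, which depend on the real population,
schedule and resource-inventory data.

## Experiments

* `dosing_reach_experiment()`: replicated four-week runs; per run it
  classifies, at the end of week 3 (weeks 1--2 are burn-in, flagged but
  never dropped), agents retaining `rx_derived` entries into clinically
  dosed versus social-only, and reports the social-to-clinical ratio.
  "Retained" means present in the capped store at the window end (an
  optional $\beta$ floor is exposed, default 0); both the
  retaining-clinical and any-clinical denominators are reported because
  the reach ratio is meaningful under either reading.
* `delivery_mode_experiment()`: the same pipeline per delivery mode
  (physician / nurse / clerk), matched seeds, with a descriptive
  Kruskal–Wallis rank test across modes.
* `pscore_sweep()`: scales the low/medium/high rates by ordered
  multipliers (0.5 / 1 / 2 by default), builds the week-3 diffusion
  network of each run — a directed multigraph with one edge per exchange
  event — and summarizes degree structure.

Problem sizes used by the shipped test suite: the reach experiment runs
the full default 10,000-agent world for 28 days × 5 replicates; the
delivery-mode comparison and propensity sweep use a 1,200-agent world
with the same temporal design, a size at which the qualitative contrasts
are already stable across replicates. The reference-equivalence check
runs 5 agents / 3 places / 48 hours, small enough to hand-trace.

## Reproducibility

A run consumes a single seeded RNG stream with a documented draw order
(seeding, then one template draw per agent per day, then per hour:
out-of-home draws, exchange Binomials, giver samples). That contract is
what allows an independently written loop-based reference simulator to
reproduce the engine's event logs byte for byte, and it makes every
pipeline deterministic given its seed. Replicate seeds are derived from
the plan seed with a fixed integer recurrence.

## Known limitations

Agent activation is static; capacity is global rather than heterogeneous;
the exchange rule ignores giver characteristics (as specified) and
transmits a single resource per fired contact by default; the in-silico
prescription ranks resources nearest-first round-robin across indicated
services, a documented stand-in for the unpublished production ranking;
and absolute reach counts are out of scope at desk scale. The
`as_printed` decay mode exists so the sensitivity of results to the decay
interpretation can be measured rather than argued.
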