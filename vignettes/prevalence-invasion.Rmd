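---
title: "Quasi-stationary prevalence and invasion probability for SIS dynamics on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-stationary prevalence and invasion probability for SIS dynamics on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisnet)
```

## The model

`sisnet` implements continuous-time Markovian
susceptible-infectious-susceptible (SIS) dynamics on a finite, static,
weighted, possibly directed contact network. The parameterisation is a rate
matrix $T$, where $T_{ij} \ge 0$ is the rate of the Poisson process by which
individual $i$ infects individual $j$ while $i$ is infectious and $j$
susceptible, together with a vector $g$ of strictly positive individual
recovery rates ($T_{ii} = 0$; recovered individuals return to the
susceptible state). The pair $(T, g)$ is a `contact_network`. The process is
a continuous-time Markov chain on the $2^N$ subsets of infectious
individuals, with the empty set as its unique absorbing state: on a finite
network, extinction of the infection is certain in the long run.

All exact theory in the package requires the positive-rate digraph of $T$ to
be strongly connected, so that infection can travel, by some route, from any
individual to any other. This makes the $2^N - 1$ non-empty states a single
communicating transient class.

## The two quantifiers

**Endemic prevalence.** Although no non-trivial stationary distribution
exists, the chain conditioned on non-extinction converges to a unique
quasi-stationary distribution (QSD) $\nu$, the normalised left Perron
eigenvector of the sub-generator $Q$ (the master-equation rate matrix
restricted to the transient states):
$\nu Q = -\alpha \nu$. The decay parameter $\alpha > 0$ is the exponential
rate at which a system started in the QSD drifts to extinction; $1/\alpha$
is its expected remaining lifetime. The quasi-prevalence of a set $W$ is the
QSD probability that at least one member of $W$ is infectious
(`qsd_event_probability()`); for a single individual this is its marginal
quasi-prevalence $p_i$.

**Invasion probability.** The quasi-invasion probability from an initial set
$A$ is defined as the limit of the ratio of survival probabilities
$$ P_A(\text{survive to } t) \,/\, P_{\text{all}}(\text{survive to } t)
   \;\longrightarrow\; w(A), \qquad t \to \infty, $$
where the denominator starts from the all-infected state, the initial
condition with maximal expected time to extinction. Invasion from the
all-infected state is certain by construction. Computationally we realise
this limit spectrally: $e^{Qt} \to e^{-\alpha t}\, w\, \nu^{\top}$ for the
irreducible transient class, so the ratio converges to the entry of the
dominant *right* eigenvector $w$ (normalised to 1 at the all-infected
state) at the state $A$. This spectral identity is an implementation
theorem; the test suite validates it against the finite-$t$ ratio computed
with the matrix exponential at $t = 50$–$60$.

**The relationship.** The duality property of SIS dynamics gives, for any
strongly connected $T$ and any set $A$,
$$ \text{invasion probability from } A \text{ on } T
   \;=\; \text{quasi-prevalence of } A \text{ on } T^{\top}. $$
For undirected networks ($T = T^{\top}$) the process is self-dual: invasion
probability from an individual equals that individual's own endemic
quasi-prevalence, and the population-mean single-seed invasion probability
equals the expected fraction infected in the QSD.
`verify_relationship_exact()` checks the identity to eigensolver precision;
`transpose_decay_check()` checks the complementary invariances
($\alpha(T) = \alpha(T^{\top})$, equal survival curves from all-infected,
equal self-marginals $P_i(\text{$i$ infectious at } t)$).

## The graphical (percolation) representation

`sample_realisation()` draws the Harris construction: each individual gets a
time line carrying a Poisson process of *cure points* at rate $g_i$, and
each ordered pair $(i, j)$ with $T_{ij} > 0$ carries a Poisson process of
*infection arrows* at rate $T_{ij}$. Individual $j$ is infectious at time
$t$, for initial set $A$, exactly when a time-respecting path (following
arrow directions, blocked by cure points) runs from the bottom of some time
line in $A$ to $(j, t)$; `reachable_set()` evaluates this by a
chronological sweep. Turning the diagram upside down
(`reverse_realisation()`) maps it to a realisation for $T^{\top}$ with the
same law, which proves duality *realisation by realisation*:
`duality_check()` confirms the forward and time-reversed indicators agree
exactly, not merely on average. One sweep of `reachable_matrix()` answers
all single-source reachability queries at once.

Numerical choices here: simultaneous events have probability zero, but
sampled times are ordered with a stable global index assigned at sampling,
so sweeps are deterministic and reversal is an exact involution on the
event multiset. Reversal about an interior time first restricts the diagram
to $(0, t]$; arrows into an already-infectious target are no-ops, which
keeps sweep semantics and path semantics identical.

## Exact numerics

* **State encoding.** Non-empty subsets are integers with bit $i-1$ set for
  node $i$; states are ordered by that integer, the all-infected state is
  index $2^N - 1$. The exact machinery materialises $2^N - 1$ states and is
  capped at $N = 12$ by default (32,767 states); the cap is an explicit
  argument, not a hidden limit.
* **Eigenpairs.** Below 1,300 states both eigenpairs come from a dense
  `eigen()` on $Q$ and $Q^{\top}$; above, from power iteration on the
  nonnegative matrix $I + Q/\Lambda$ refined by sparse-LU shift-invert
  iterations. Both paths must deliver residuals
  $\lVert \nu Q + \alpha \nu \rVert_\infty$ and
  $\lVert Q w + \alpha w \rVert_\infty$ below $10^{-10}$ or they raise an
  error; the two paths are compared on their overlap ($N = 8$) in the
  tests. Sign conventions: $\nu$ is flipped positive then normalised to sum
  1; $w$ is scaled by its all-infected entry.
* **Matrix exponential action.** Transient probabilities use
  uniformisation: with $\Lambda \ge \max_i |Q_{ii}|$ and
  $P = I + Q/\Lambda$ nonnegative,
  $e^{Qt} v = \sum_k \text{Pois}_{\Lambda t}(k)\, P^k v$ with all terms
  positive (no cancellation), horizons split so $\Lambda\,\Delta t \le 200$
  per chunk. The independent oracle in the tests is `Matrix::expm()` on the
  dense sub-generator; the two routes agree to $10^{-10}$.
* **Degenerate inputs.** $N = 1$ has a single transient state
  ($\nu = w = 1$, $\alpha = g_1$); empty node sets are rejected wherever a
  probability of "at least one member" is requested; $t = 0$ returns the
  indicator of the initial condition.

## Stochastic simulation and estimators

The simulator is the direct (Gillespie) method with incremental per-node
rate bookkeeping, written in C++: exponential waiting times at the total
rate, events chosen proportionally to their rates. Replicate RNG streams
are derived deterministically from (master seed, replicate index) with a
self-contained xoshiro256++ generator, so any replicate is reproducible in
isolation and batches are order-independent. R's own RNG is used (and
restored) only by the network generators and the graphical sampler.

**Prevalence (time-average) estimator.** `estimate_qsd_marginals()`
implements $\hat p_i = \sum_k \tau_k 1^{(i)}_k / t_\sigma$ over post-burn-in
inter-event intervals, discarding post-extinction data. Two regimes arise:

* *Long-lived systems* (expected lifetime far beyond the event budget):
  the estimator is one long run with the first fraction of events
  discarded -- the classical protocol for measuring the QSD by simulation.
* *Short-lived systems*: replicates restart from the initial state; each
  must survive its own burn-in before contributing, and post-burn-in
  pre-extinction intervals are pooled until the kept-event budget is met.
  This regenerative ratio estimator is consistent because, once the
  survival-conditioned state is reached, the expected pre-extinction
  occupancy of a state is proportional to its QSD mass. The burn-in
  therefore needs to cover the *relaxation* to the conditioned law (set by
  the sub-dominant spectral gap, typically a few time units), not the much
  longer extinction time. A replicate dying during burn-in counts towards a
  consecutive-retry cap (default 100), after which the estimator refuses
  with a diagnostic: if no replicate can survive burn-in, quasi-stationarity
  has no practical relevance at that configuration and a time-average is
  not measuring it.

Standard errors come from batch means over 50 contiguous batches of kept
events (calibrated against the empirical spread across independent seeds in
development; the reported SE is honest to within a few percent in both
regimes). Burn-in defaults to a fraction of the budget (the full-scale
protocol discards 10/11 of events; the default here is configurable and the
tests use burn-ins matched to the relaxation time of the small systems they
measure).

**Invasion (censored-fraction) estimator.**
`estimate_invasion_probability()` reports the fraction of replicates whose
infection-event count reaches a threshold $c$ before extinction, with exact
binomial standard errors. The measurement is only meaningful under
*dichotomised persistence*: the histogram of infection events per replicate
(`infection_event_histogram()`) must be clearly bimodal -- early
extinctions near zero and persistent runs at the censoring bin. The
diagnostic requires the middle third of $[0, c]$ to hold under 5% of
replicates *and* at least one replicate to reach $c$; failing either, the
estimate carries a warning. Two distinct regimes defeat the estimator, and
the diagnostic flags both: subcritical systems where no run persists, and
*small* systems where even "invaded" runs die before accumulating $c$
infection events (there the censored fraction estimates the first-passage
probability of $c$ infections, which the tests verify against an exact
jump-chain recursion, but it under-states the spectral quasi-invasion
probability; no threshold uncovers a dichotomy that the system does not
possess). The default $c = 500$ follows the full-scale measurement
protocol; on toy networks the diagnostic, not the default, is the guide.

**Survival curves.** `empirical_survival_curve()` estimates
$P(\text{extinction time} > t)$ on a grid; the ratio of curves from $A$ and
from all-infected plateaus at the quasi-invasion probability, which is how
invasion can be measured when dichotomised persistence is not observable.
`paired_quantifier_experiment()` assembles the two Monte-Carlo quantifiers
across a grid of scalar multipliers of $T$ -- invasion from a seed node on
$mT$, prevalence of that node on $(mT)^{\top}$ -- whose pairs fall on the
diagonal within sampling error.

## What the generators emulate

`lattice_network()` (non-periodic 4-neighbour square lattice, symmetric
weight $\beta$), `complete_network()` and `random_connected_network()`
(directed Hamiltonian cycle guaranteeing strong connectivity, plus
independent extra edges, default weights $U(0.1, 1)$) supply the structures
used in the tests: homogeneous lattices, the smallest non-trivial complete
networks, and heterogeneous directed networks. Recovery rates default to 1.
These fixtures probe the exact identities on arbitrary strongly connected
topologies, but they do not reproduce the features of realistic transmission
networks -- thousands of nodes, rates spanning orders of magnitude, spatial
clustering -- so a green test establishes correctness of the machinery, not
fidelity of any particular epidemiological scenario. Large empirical
networks enter through `read_network()`/`largest_scc()` and are served by
the simulation side only; the exact side is limited by its $2^N$ state
space by nature, not implementation.

## Known limitations

* Exact computations are exponential in $N$ (cap 12 by default); there is
  deliberately no mean-field or moment-closure approximation in scope.
* Event selection in the simulator is a linear scan per event -- fine up to
  tens of thousands of nodes at test scale, not tuned for millions of
  events on very large networks.
* The censored-fraction estimator and the time-average estimator both
  presuppose a practically relevant QSD; on small or subcritical systems
  their diagnostics fire instead of producing numbers, by design.
* `survival_ratio()` computes at finite $t$; for $\alpha t \gtrsim 700$ the
  survival probabilities underflow and the function asks for a smaller $t$
  rather than silently extrapolating.
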