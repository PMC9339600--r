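---
title: "A coupled-network rumor model with variation and oyster states: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled-network rumor model with variation and oyster states: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isovrnet)
```

## The model

`isovrnet` simulates a rumor spreading through a population that lives in
two places at once: an *online Internet layer*, where interactions are
sporadic (people are mostly offline), and an *offline entity layer*, where
the same people interact continuously. The two layers are static undirected
graphs of equal size connected by a one-to-one counterpart mapping, and the
rumor's micro-state is richer than in classic ignorant–spreader–stifler
models: a carrier can be an ordinary **spreader** (S), a **variation** (V)
spreading a distorted version of the rumor, or an **oyster** (O) who holds
the rumor silently. **Recovered** (R) is absorbing; "no after-effects" is a
structural property of the state machine, verified on full state logs in the
test suite.

Three mechanisms interlock.

### Threshold activation and extinction

Each node draws two static traits at initialization, an arousal threshold
and an extinguishing threshold, i.i.d. from normal distributions truncated
to $[0,1]$ (rejection resampling, so the realized law is the conditional
normal, not a clipped one). An ignorant node activates when the fraction of
carriers among its *participating* neighbours reaches its arousal threshold;
the boundary case activates. The denominator is the number of participating
neighbours — reading it as "carrier neighbours" would pin the ratio at 1 and
make the threshold vacuous, so the neighbourhood-fraction reading is the
only self-consistent one.

A newly activated node adopts S, V or O with probability proportional to
the summed influence of its activated neighbours per role, where a node's
influence is the product of its degree centrality, its eigenvector
centrality and a role attribute weight ($Ar_S = 1$, $Ar_V = 1.5$,
$Ar_O = 0.5$). If no activated neighbour has positive influence (possible on
degenerate topologies where eigenvector centrality vanishes on a component)
the node falls back to S; the engine counts these events and the standalone
operation warns.

Recovery ("extinction") opens at the immunity-onset step, `immune_start`
(default 15), so the recovered density is identically zero before it. From
then on, a participating carrier recovers when the carrier fraction among
its participating neighbours falls **below** its extinguishing threshold —
the rumor's perceived energy around the node has faded; a carrier with no
participating neighbours perceives zero support and recovers. The opposite
inequality (recover when the fraction is *above* threshold) is exposed as
`extinction_direction = "as_printed"`. The two readings circulate because
the defining formula is sometimes typeset with the inequality pointing
against the accompanying prose; we default to the fading-support semantics
because it is the reading under which immunity reliably *appears* at the
onset step — under the opposite direction a default-parameterization online
layer (97 % of nodes masked per step) essentially never satisfies the
high-support condition and first recovery drifts tens of steps past onset.

### Bounded-confidence opinions and the silence intervals

Every carrier holds an opinion $x \in [-1, 1]$. Against the mean opinion
$\bar X$ of its participating carrier neighbours (recovered and masked
neighbours excluded; no interlocutor means no update), with
$\Delta = |x - \bar X|$:

* $\Delta < d_1$: attraction, $x' = x + \mu(\bar X - x)$;
* $\Delta > d_2$: repulsion, $x' = x + \mu(x - \bar X)$;
* otherwise: no willingness to interact, $x' = x$;

clamped to $[-1,1]$. We implement the *signed* forms: the unsigned textbook
variants ($x \pm \mu\Delta$) coincide with them when $x < \bar X$ but move
opinions away from the interlocutor under attraction (and toward under
repulsion) when $x > \bar X$, contradicting what attraction and repulsion
mean. The unsigned forms remain available as
`literal_opinion_rule = TRUE` for comparison. Attraction contracts the
distance to $\bar X$ by exactly $(1-\mu)$ and repulsion expands it by
$(1+\mu)$ whenever no clamp or ratchet binds — both are property-tested.

Opinion space carries four silence coefficients
$-1 < \rho_1 < \rho_2 \le 0 \le \rho_3 < \rho_4 < 1$. Roles are read off the
opinion: V on $[-1,\rho_1) \cup (\rho_2, 0)$, O on the closed silence
intervals $[\rho_1,\rho_2] \cup [\rho_3,\rho_4]$, S on
$[0,\rho_3) \cup (\rho_4, 1]$. Assigning the interval endpoints to O and
$x=0$ to S makes the map total and deterministic; carriers are reclassified
from their opinion every step. A ratchet protects committed spreaders: an
opinion in $[0, \rho_3]$ never decreases, which also implicitly prevents a
node in that band from drifting back into variation territory. (The
variation-side interval is stated in some sources as $[-\rho_2, 0]$, which
with $\rho_2 < 0$ is inverted and would leave opinion space unpartitioned;
we read it as $[\rho_2, 0]$.)

### Interlayer coupling

Two mechanisms tie the layers together.

*Offline masking.* Each step every online-layer node is offline with
probability `offline_prob` (default 0.97). A masked node is fully inert for
in-layer dynamics that step: it is excluded from every neighbourhood count
and opinion mean, cannot be aroused, cannot recover, and does not update its
opinion. We chose one uniform rule rather than masking some mechanisms and
not others; the consequence — a nearly frozen online layer whose carriers
recover within a few dozen steps of immunity onset — is exactly the
"high offline probability throttles online spreading" regime. The
`invert_offline` flag reinterprets the parameter as an *online* probability
without guessing intent.

*Social-reinforcement synchronization.* Once per step, before in-layer
dynamics, each source node may copy its state onto its counterpart with
probability $\bar\omega(n) = \xi n / (1 + \gamma n)$, where $n$ counts the
*target's* neighbours already in the source's state (carrier sub-roles
matched exactly). The curve is zero without reinforcement, monotone, and
saturates strictly below $\xi/\gamma$; raw values above 1 (possible for
large $\xi$) are capped. Opinions travel with carrier states; recovered
targets are never overwritten; an ignorant source exerts no pressure (an
unaware counterpart is not social reinforcement). Synchronization is not
gated by the offline mask — it models cognitive carry-over between a
person's two embodiments, not in-layer transmission. The default direction
is online→offline, the direction in which reinforcement from online events
drags the physical layer along; `sync_direction = "bidirectional"` applies
the mirrored rule as well, both directions reading the pre-synchronization
snapshot. The "transition layer" between the two graphs is exactly this
mechanism; it has no topology of its own.

### Event order and update scheme

All updates are synchronous ($t \to t+1$ maps). Per step: (1) draw the
offline mask; (2) synchronization; (3) arousal of ignorants; (4) role
assignment and opinion initialization of the newly aroused; (5) opinion
updates of existing carriers; (6) opinion-based reclassification;
(7) extinction. Every neighbourhood quantity in (3)–(7) is computed from the
post-synchronization snapshot, so newly activated nodes do not transmit
until the next step, and extinction (applied to snapshot carriers) overrides
same-step reclassification. Densities are recorded after the full step;
$C(t)$ is derived as $S+V+O$, never stored, so the carrier identity is
structural, and $I+C+R=1$ holds exactly because states partition the nodes.

## Parameters

| key | default | meaning |
|---|---|---|
| `n`, `m` | 2000, 5 | layer size and preferential-attachment edges per node (mean degree ≈ 10) |
| `offline_prob` | 0.97 | per-step probability that an online node is inert |
| `phi_mean`, `phi_sd` | 0.2, 0.5 | arousal threshold distribution (truncated normal) |
| `varphi_mean`, `varphi_sd` | 0.2, 0.15 | extinguishing threshold distribution |
| `immune_start` | 15 | first step at which recovery is possible |
| `xi`, `reinforcement` | 0.1, 0.2 | synchronization scale $\xi$ and reinforcement $\gamma$ |
| `alpha_s`, `alpha_v`, `alpha_o` | 1, 1.5, 0.5 | role attribute influences |
| `mu` | 0.1 | trust/convergence rate of opinion interactions |
| `d1`, `d2` | 1, 1.5 | assimilation and exclusion distances |
| `rho1..rho4` | −0.4, −0.2, 0.2, 0.3 | silence coefficients |
| `horizon` | 100 | steps per run |
| `initial_carriers` | 1 % of `n` | seeded carriers (counterpart pairs in both layers) |

All values are the case-study parameterization the model was calibrated
against; `horizon` and replicate counts (20 in the sweep tooling and tests)
are our choices, sized so a default run completes in about a second.

## Seeding

The seeding rule is genuinely open, and two choices interact with the
model's core phenomenon.

*Which layers get seeds.* Synchronization counts same-state neighbours
around the *target*, so an all-ignorant offline layer offers $n = 0$ to
every incoming carrier state and can never leave ignorance. Seeding the
counterpart pairs in both layers (each side drawing its own opinion) boots
the offline layer without inventing a second mechanism.

*Initial opinions.* A node entering the propagation state draws its opinion
at random on $[-1, 1]$; we apply that to the seeds too
(`initial_opinion = "uniform"`), classifying their starting role from the
draw. The alternative — all seeds start as spreaders with spreader-interval
opinions — is available (`"role_interval"`) but degenerate: with only
positive opinions in play, pairwise distances never exceed $d_1$, repulsion
never fires, the ratchet and attraction keep every opinion nonnegative, and
the variation state is unreachable for the entire run. Since variation
dynamics are the point of the model, the non-degenerate rule is the default.

Newly aroused nodes (after the seeds) get their role from the
influence-proportional rule and an opinion drawn uniformly from the union of
that role's intervals, each sub-interval weighted by its length.

## Numerical choices

* **Eigenvector centrality** is computed by power iteration on $A + I$:
  the shift leaves eigenvectors untouched but makes the dominant eigenvalue
  strictly largest in magnitude, so the iteration also converges on
  bipartite graphs (stars, rings of even length), where plain iteration
  oscillates between $\pm\lambda_{\max}$. Tolerance $10^{-10}$ on the
  iterate change, at most $10^4$ iterations, unit Euclidean norm — the free
  normalization constant only rescales influence ratios. Tests check the
  fixed-point residual ($<10^{-8}$), the closed-form star ratio
  $\sqrt{n-1}$, and agreement with a dense eigendecomposition oracle.
  Edgeless graphs return all zeros with a warning, and every division by a
  summed influence or neighbour count is guarded.
* **Truncated normal sampling** by rejection keeps the support exactly
  $[0,1]$; the empirical mean is tested against quadrature of the truncated
  density. `sd = 0` short-circuits to the degenerate distribution.
* **Opinion initialization** is an inverse-CDF transform of a single
  uniform draw per node; boundary hits that would classify into a
  neighbouring role are nudged inward by $10^{-9}$ (events of probability
  zero in exact arithmetic).
* **Coupling tie-breaks**: assortative/disassortative matching sorts by
  degree with ascending node id as tie-break, so all three coupling modes
  are deterministic given the seed.
* **Randomness tape**: each step consumes fixed-length uniform vectors
  (mask, synchronization, one role and one opinion draw per node and layer)
  whether or not they are used. RNG consumption therefore never depends on
  the trajectory, which (i) makes the $\xi = 0$ layer-independence test an
  exact A/B comparison and (ii) lets the test suite replay a step's exact
  randomness through an independent straight-line per-node implementation of
  all the update rules and demand equality node by node.

## What the generator emulates — and what it does not

The default network is a Barabási–Albert scale-free graph ($N = 2000$,
$m = 5$), emulating the heavy-tailed interaction structure of a real
social-media discussion; the offline layer defaults to an independent
scale-free graph of the same size (a Watts–Strogatz option and user-supplied
edge lists / GraphML are available, since offline contact structure is not
necessarily scale-free). Real interaction networks additionally show
community structure, degree correlations, temporal rewiring and
heterogeneous per-node offline behaviour, none of which the generator
produces; the topology is static by stipulation. Passing tests therefore
demonstrate internal correctness and the model's qualitative regimes
(throttled online spreading, offline cascades, variation dominance followed
by silence) on idealized topologies — not calibrated predictions for any
particular empirical event.

## Test and experiment sizes

The verification suite runs full-size checks where they are cheap (default
$N = 2000$ runs for conservation and immunity onset; 20 seeded graphs for
the network-scale check) and scaled-down stochastic comparisons where
replication matters: $n = 500$, horizon 30, 20 replicates per arm for the
one-sided rank tests that higher trust $\mu$ does not slow early variation
growth and higher $\xi$ does not reduce the offline carrier peak. At this
scale the offline cascade is near-critical, so per-run outcomes are
bimodal and the rank tests are deliberately framed as "no significant
decrease" rather than as effect-size estimates.

## Known limitations

* Parameters are static over a run; real events show phase-dependent
  behaviour (parameter drift is out of scope).
* The offline probability applies one scalar to all online nodes; per-node
  vectors are accepted via configuration of user-supplied inputs but not
  generated.
* Opinions are one-dimensional with homogeneous $\mu$, $d_1$, $d_2$.
* With `extinction_direction = "as_printed"` and the default mask, online
  recovery is extremely rare; the flag exists for comparison, and the two
  directions produce qualitatively different online layers.
* The synchronization mechanism is the only cross-layer channel; there is
  no explicit third graph, and no feedback from opinions to the mask.
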