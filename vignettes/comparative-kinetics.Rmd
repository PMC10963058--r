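---
title: "Comparative kinetics: models, simulation and the percentage-change map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative kinetics: models, simulation and the percentage-change map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netkin)
```

## The model and its assumptions

netkin represents a biochemical system as a deterministic kinetic
reaction network: a set of metabolites $X_1,\dots,X_m$ with
concentrations $x_i(t)$ (nM by default), a set of reactions
$r_1,\dots,r_n$ with integer stoichiometry, and one rate law
$v_j(x;\theta_j)$ per reaction. The dynamics are the usual mass-balance
ODEs

$$\frac{dx}{dt} = S\,v(x), \qquad S_{ij} = s^{\text{prod}}_{ij} - s^{\text{sub}}_{ij},$$

with fixed (boundary) metabolites clamped to their initial value (their
row of $S$ is zeroed). This is the standard well-mixed, continuous,
deterministic approximation: no spatial effects, no stochasticity, no
events or algebraic rules (those SBML constructs are rejected
explicitly rather than silently dropped).

The built-in rate-law library covers what ordinary metabolic and
signalling models need: irreversible mass action
$k\prod_i [R_i]^{s_i}$, reversible mass action
$k_f\prod_i [R_i]^{s_i} - k_r\prod_j [P_j]^{t_j}$, irreversible and
reversible Michaelis--Menten, the competitive-inhibition form
$V S / (K_m (1 + I/K_i) + S)$ used for inhibitor drugs, and a
constant-flux source law. Mass-action laws are *structural*: their
velocity follows the stoichiometry of whatever reaction they are
attached to. Michaelis--Menten forms are unimolecular and use generic
symbols `S`, `P`, `I` that are substituted for the concrete metabolite
ids at attachment. User-defined laws are restricted to a safe
arithmetic grammar (`+ - * / ^`, parentheses, `pow`, `exp`, `log`); no
other function calls evaluate, so a model file can never execute code.

Reaction equations are entered in the conventional text grammar
(`"2 A + B <-> C"`). `->` marks irreversible, `<->` reversible, and `=`
is accepted as a synonym for `<->` since both dialects circulate among
modelling tools. Stoichiometric coefficients are restricted to positive
integers; fractional coefficients are rejected with a clear error
rather than rounded. Inhibitors and activators never appear in the
equation string — they are attached as modifiers so rate expressions
can reference them, mirroring how inhibition edges are drawn in pathway
diagrams. Catalyst modifiers may carry external identifiers (e.g. gene
ids from pathway files) that are not model species; only
inhibitor/activator modifiers, which enter rate expressions, must
resolve to metabolites.

## Numerical choices

**Integration.** Time courses use the stiffness-switching LSODA method
via `deSolve::lsoda`, the default deterministic integrator of the
established simulation tools in this field. Default tolerances are
`rel_tol = 1e-6`, `abs_tol = 1e-12`; output is sampled on a uniform
grid of `n_points + 1` times including $t=0$ and $t=$ `duration`
(default `n_points = 1000`).

**Negative concentrations.** A stiff integrator can legitimately
undershoot zero by an amount of the order of its own error estimate.
Solutions with components below $-(\texttt{abs\_tol} + \texttt{rel\_tol}
\cdot \max|x|)$ — i.e. beyond the solver's accuracy promise — raise a
solver error; smaller negatives are clamped to 0 in the output. A
fixed $-\texttt{abs\_tol}$ cutoff would misfire on benign integrator
noise whenever concentrations span many orders of magnitude, which they
do in the bundled signalling fixture.

**Steady states.** `find_steady_state()` first runs a damped Newton
iteration on the ODE right-hand side (free species only, numerical
Jacobian, step halving up to 30 times, iterates clamped to the
non-negative orthant, at most 100 iterations). If Newton stalls it
falls back to integrating over geometrically growing horizons
($10^2, 10^3, \dots, 10^7$ s) until
$\lVert dx/dt \rVert_\infty < \texttt{tolerance}$ (default $10^{-9}$
nM/s). Divergent systems report `status = "not_found"` rather than
raising, because a missing steady state is an analysis result, not a
program failure. The result records which path succeeded.

**Parameter scans.** A scan evaluates only the two endpoint states:
every item at its initial value (baseline) and every item at its final
value (perturbed). Intermediate grids are out of scope — the comparison
statistic below only consumes the endpoints. Scans operate on copies,
so the input model serializes byte-identically before and after.

## The percentage-change statistic and its visual map

Comparative analysis reduces two simulation outputs — reference values
$A_1,\dots,A_n$ and perturbed values $B_1,\dots,B_n$ over the
intersecting metabolites — to per-metabolite percentage changes

$$PC_i = 100 \times \frac{B_i - A_i}{A_i}.$$

The zero-reference edge cases are conventions chosen here, since the
ratio is undefined at $A_i = 0$: both values zero gives $PC_i = 0$ (no
change), and $A_i = 0, B_i > 0$ gives an infinite sentinel (`Inf`,
rendered as "appeared" and given the maximum node size). Negative
concentrations are a domain error. Two useful identities hold and are
tested as metamorphic properties: swapping the roles of reference and
perturbed flips every sign, with magnitudes related by
$PC' = -100\,PC/(100 + PC)$.

Metabolites are matched between models by id first, then by exact
display name for ids unmatched on both sides; ambiguous duplicate
names are an error rather than a silent pairing. Time-course
comparisons use the final sampled time by default (any sampled time can
be selected with `at_time`); steady-state comparisons require both
steady states to be found and name the culprit model otherwise.

The visual encoding maps $|PC_i|$ to node size through a log-compressed
normalization,

$$\text{size}_i = s_{\min} + (s_{\max} - s_{\min}) \cdot
\min\!\left(1, \frac{\log_{10}(1+|PC_i|)}{\log_{10}(1+PC_{\text{cap}})}\right),$$

with $PC_{\text{cap}}$ the largest finite $|PC|$ in the comparison. A
linear map would be unreadable: in the disease scenario below the
changes span more than eight orders of magnitude, and everything except
the top change would collapse to the minimum size. Direction is
encoded as red (up) versus cyan (down), and metabolites with
$|PC| < 10^{-6}\,\%$ are hidden entirely — floating-point simulation
output is never exactly unchanged, so "did not vary" needs a
threshold, and $10^{-6}\,\%$ sits far below anything biologically
interpretable while far above accumulated solver error.

## Pathway import rules

KGML pathway files are parsed record-for-record; unresolvable
references are collected as diagnostics and warned about, never
silently dropped. Conversion into a kinetic model applies four fixed
rules: map-type entries are dropped; compound entries aliasing the same
KEGG compound id merge into one metabolite (so the metabolite count can
only shrink relative to the entry count); catalyzing gene/enzyme
entries become catalyst modifiers; and a missing reaction type defaults
to irreversible. Duplicate reactions — identical substrate and product
sets — merge. The result is a topology with `rate_law` unset,
awaiting parameterization; KGML carries no module tags inline, so
module membership arrives through a JSON side file mapping module id to
reaction ids, which keeps the whole workflow offline-testable.

SBML import covers the species/reaction/kineticLaw core of Levels 2 and
3. Kinetic-law MathML is translated into the restricted expression
grammar; local parameters stay local to their reaction (each reaction
evaluates its own bindings, locals shadowing globals), so name
collisions between local and global parameters need no renaming and
round-trip unchanged. Export writes Level 3 Version 1 with the
instantiated rate expression as MathML. Structural equality across a
round trip (ids, stoichiometry, reversibility, parameter values to 12
significant digits) is the tested contract.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_model()` produces weakly connected unimolecular
networks with rate laws drawn from a user-set mix and parameters
log-uniform over ranges typical of cellular kinetics: first-order
constants $10^{-3}$–$10^{-1}\,\mathrm{s}^{-1}$, limiting rates
0.1–10 nM/s, Michaelis constants 10–1000 nM, initial concentrations
1–1000 nM. Connectivity is guaranteed by construction (the first
$m - 1$ reactions form a spanning tree over a shuffled species order),
which is why the generator requires at least $m - 1$ reactions.
Generated networks exercise the solver, the comparison machinery and
the file formats; they do *not* emulate bimolecular association,
allosteric regulation, compartmentalization, or the fat-tailed
parameter distributions of curated models, so passing property tests on
them says nothing about those features.

The bundled signalling fixture (`signaling_demo_model()`) is a
synthetic stand-in for a curated growth-factor signalling model: a
receptor with expression (global `V1`), saturable maturation and
first-order degradation (global `k4`); a Ras → Raf → MEK → ERK cascade
with phosphatase back-reactions (`r8b` deactivates Ras; `r17a`/`r17b`
dephosphorylate pBRaf); a receptor-driven Akt arm; and ERK/Akt-gated
GSK3β control of β-catenin turnover. Its constants were chosen once,
from two qualitative regimes reported for such networks, and not
revisited: basal phospho-occupancy is sub-percent (fast phosphatases
relative to basal kinase drive), so that deleting a deactivation
reaction produces the characteristic $10^5$–$10^6\,\%$ overactivation
signature; and receptor maturation is saturated at baseline expression,
so that raising expression alone barely moves the signalling profile
while abolishing degradation (`k4 = 0`) produces constitutive
activation. Drug treatment adds one metabolite and one
dephosphorylation-facilitating reaction — saturable
(competitive-type Michaelis--Menten in the drug) or reversible mass
action — targeting pBRaf. Because the Akt arm hangs directly off the
receptor, a BRaf-directed drug provably cannot move pAkt, which is the
fixture's built-in negative control.

## Problem sizes and runtime

The test-suite property checks run random networks of up to 8 species
against an independent fixed-step fourth-order Runge--Kutta oracle at
1000 steps, and the scenario checks use the 17-metabolite fixture over
15 000 s with 500 output points; the whole suite completes in well
under a minute on a single core. The acceptance script re-runs the
same computations from scratch at the same sizes.

## Known limitations

* No events, assignment/algebraic rules, delays, or function
  definitions; SBML files using them are rejected with the construct
  named.
* Michaelis--Menten built-ins are unimolecular; multi-substrate
  saturable kinetics must be written as user expressions.
* The BRENDA live SOAP client is not implemented — live mode requires
  an injected transport; the offline cache (recorded JSON responses)
  is the stable contract, and KEGG live fetching uses plain HTTP GET.
* Images are static renderings; tooltip content (PC, reference,
  perturbed value) is embedded as GraphML attributes rather than hover
  behaviour.
* The steady-state Newton solver uses a dense numerical Jacobian;
  systems with thousands of species would need an analytic or sparse
  Jacobian.
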