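---
title: "Methods: enzyme-cost optimality of pathway splitting in a two-member consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-cost optimality of pathway splitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsplit)
```

## The model

`metsplit` studies when it pays, in protein cost, for two co-occurring
bacterial populations to split a linear biosynthetic pathway between them —
the pattern known from endosymbiotic consortia, where for instance the
tryptophan pathway is divided between *Buchnera aphidicola* (anthranilate
synthase) and *Serratia symbiotica* (the remaining steps).

Two cell types (population fractions $n_1 + n_2 = 1$) both encode the chain

$$S \rightarrow X_1 \rightarrow \cdots \rightarrow X_m \rightarrow P,$$

with a clamped substrate concentration $[S]$ (its supply is outside the
model).  Each synthesis step follows reversible Michaelis–Menten kinetics;
the first step is feedback-inhibited by the end product.  In the default
uncompetitive form,

$$V_S = \frac{k_{cat}[E_S]}{1+[P]/K_I}\,
  \frac{([S]-[X]/K_{eq})/K_M^+}{1+[S]/K_M^+ +[X]/K_M^-},$$

so the inhibitor scales the whole rate; in the competitive variant the term
$[P]/K_I$ is added to the saturation denominator instead, so saturating
substrate out-competes the inhibitor.  With $1/K_I \to 0$ both recover the
plain reversible law.  The intermediates and the product cross the membranes
passively, $U_\alpha = D_\alpha([\alpha]_{in}-[\alpha]_{out})$ (positive =
excretion; endosymbionts are notoriously transporter-poor, which motivates
the non-saturating law).  The product is consumed irreversibly,
$V_P = k_{cat}[E_P][P]/([P]+K_M)$, and each cell must sustain a demand
$V_{P,i} \ge J_{P,i}$; a host demand $J_{P,0}$ drains the medium.  All
quantities are in dimensionless model units; the canonical parameterization
(`default_consortium()`) sets every kinetic constant to one, $[S]=10$,
$n_1=n_2=1/2$, $J_{P,1}=J_{P,2}=1$, $J_{P,0}=0$.

The total population size $N$ multiplies the extracellular balance equations
and cancels at steady state; the package exposes it (`total_cells`) for the
dynamics but steady-state solutions are provably independent of it, which a
test asserts at $N=1$ versus $N=10^6$.  Species with $D=0$ carry no
extracellular pool at all — the degenerate variable is removed rather than
retained.

## The optimization and its reformulation

The fitted object minimizes the population-weighted total enzyme
concentration

$$C=\sum_{i=1,2} n_i \sum_\alpha [E_{\alpha,i}]$$

subject to steady state of every pool, the demands, and nonnegativity.  Two
structural facts make an exact reformulation possible: every reaction rate
is *linear in its enzyme concentration*, and every exchange flux is *linear
in the concentrations*.  Consequently, once the intracellular metabolite
concentrations are fixed, (i) the extracellular concentrations follow in
closed form from exchange closure ($\sum_i n_i U_{X,i}=0$,
$\sum_i n_i U_{P,i}=J_{P,0}$), (ii) the steady-state flux each reaction must
carry follows by propagating the demands up the chain (demands are imposed
with equality — over-producing the product is never cost-optimal, and the
returned solution's consumption fluxes are verified against the demands),
and (iii) each enzyme concentration is recovered as required flux divided by
its per-enzyme rate.  The decision variables are therefore only the
$2(m{+}1)$ log intracellular concentrations, steady state holds *exactly*
(typical residual max-norms are $10^{-12}$; solutions are accepted below
$10^{-8}$), and enzyme nonnegativity becomes a set of affine constraints on
the concentrations.

This is a deliberate design choice over the more literal alternative —
treating enzymes and concentrations jointly with steady state as nonlinear
equality constraints — because it removes all equality constraints from the
search, reduces the dimension, and represents the hallmark zero-enzyme
optima exactly rather than to a constraint tolerance.

The search combines:

* a seeded multistart (default 24 starts, log-uniform in
  $[10^{-3},10^2]$) of Nelder–Mead in the full concentration space, with
  hinge penalties on the affine nonnegativity constraints;
* structured *branches*: the fully symmetric allocation (cells share one
  concentration vector; no exchange) and, for every chain position $k$, the
  active-set branches in which cell 2 drops enzymes $1..k$ (partial split)
  and additionally cell 1 drops enzymes $k{+}1..m{+}1$ (clean split).  On a
  branch the zeroed fluxes are affine constraints, eliminated through a
  null-space parameterization, so the zeros are exact.  Branch solves are
  seeded both by random starts and by the symmetric/interior solutions
  (continuation across branches).

The best feasible candidate is refined with a doubled iteration budget, then
polished: enzymes below $10^{-6}$ of the total are promoted to exact zeros
and the reduced problem is re-solved.  Ties between the symmetric and an
asymmetric branch within a relative $10^{-6}$ are resolved in favour of the
symmetric solution and flagged as a regime boundary, so output near the
transition line is deterministic.  For a mirror-symmetric consortium (equal
fractions and demands) solutions come in $\pm$ pairs; the reported
orientation is canonicalized to $A_S \ge 0$, where
$A_\alpha = ([E_{\alpha,1}]-[E_{\alpha,2}])/([E_{\alpha,1}]+[E_{\alpha,2}])$
is the enzyme asymmetry ($0/0$ is defined as 0 and flagged).  When demands
or fractions differ the restriction is inert and both orientations are
searched.

The dual formulation (`maximize_flux_under_budget()`) — maximize the uniform
demand scale $\lambda$ under an enzyme budget — is solved by monotone root
finding on $\lambda \mapsto C(\lambda)$ and reproduces $\lambda = 1$ at the
primal optimal cost.

### What the demand-scaling law does and does not give

In the exchange-free symmetric regime every steady-state flux is
proportional to the demand at fixed concentrations, so the optimal cost is
*exactly* linear in a uniform demand scaling and the optimal concentrations
do not move; tests assert this at $\lambda \in \{0.5, 2\}$ to a relative
$10^{-5}$.  In asymmetric regimes the exchange fluxes are tied to
concentration *differences* ($U = D\,n_{j}\,\Delta c$), which must grow with
the demands while the rate laws remain nonlinear in the absolute
concentrations; exact linearity therefore cannot hold there.  Empirically
the deviation is small, and the meaningful invariances — the regime label
and $A_S$ — are preserved; the tests assert those plus cost linearity
within 10%.

## Regimes and experiments

`classify_regime()` labels converged optima: **neutralist** (all
$|A_\alpha|$ and exchange fluxes below tolerance), **cheater** ($A_S=1$,
cell 1 leaks intermediate that cell 2 consumes, no product returns —
arises when $D_P = 0$), **complementation** ($A_S=1$ with product shuttled
back, $U_{P,1}<0$), or **boundary**.  The tolerance is $10^{-3}$ on
asymmetries and, relative to the total demand, on fluxes.

`phase_diagram()` maps these regimes over $(D_X, D_P)$ grids for a set of
inhibition strengths, warm-starting along each row with a fresh-multistart
fallback when the cost jumps by more than 20%.  With weak inhibition
($1/K_I \le 0.1$) the whole grid is symmetric; with strong inhibition
($1/K_I = 10$) asymmetry occupies the large-$D_X/D_P$ wedge, with $A_S$
jumping between 0 and 1 while the cost stays continuous, and a
complete-splitting region ($[E_{S,2}]=[E_{X,1}]=0$, exactly) at large
permeabilities.  The acceptance suite runs $8\times8$ log-spaced grids on
$[10^{-2}, 30]$ — fine enough to exhibit all regimes, coarse enough that a
grid completes in about two minutes.

### Extended chains and the splitting point

With $m=5$ intermediates, $K_{eq}=4/3$ on every reversible step, $[S]=20$,
$1/K_I=10$, and only the product plus one chosen intermediate permeable
($D=15$; all others $10^{-3}$), the optimum assigns cell 2 the chain from
the permeable metabolite onward ($[E_{S,2}] = \dots = 0$ exactly).  A
finding worth stating precisely: the *clean* split — cell 1 expressing
nothing downstream of the permeable metabolite — is not the exact optimum.
Because the clean-split manifold is a constrained subset of the
partial-split branch, the unconstrained optimum generically sits just off
it, and here it retains roughly 2–3% of cell 1's enzyme budget in each
downstream enzyme; deleting them raises the cost by well under 1%
(e.g. 27.857 vs 27.873 at the first index).  `split_point()` therefore
reads the partition at the gene presence/absence level, with a default
expression threshold of 5% of the cell's total enzyme: enzymes below it are
metabolically dispensable in exactly the sense genomic complementation
implies.  With the default threshold the split point equals the permeable
index (1, 3, 5 in the three standard settings); with a strict numerical
threshold ($10^{-6}$) no clean partition exists, and a unit test documents
that too.

### Sensitivity analysis

Near the symmetric/asymmetric boundary, every positive kinetic parameter
(kinetic constants per step, $1/K_I$, $[S]$, nonzero permeabilities) is
perturbed multiplicatively, $k_i \mapsto k_i e^{u}$ with $u$ log-uniform on
$[-\delta, \delta]$, $\delta = 0.3$ by default — multiplicative because it
preserves positivity and treats all scales alike.  For each of $n=200$
samples the allocation is re-optimized (branch search with a few starts —
two orders of magnitude faster and sufficient because the optima of this
model are branch-structured) and the association between $|A_S|$ and each
parameter is summarized by the sample covariance, with the Pearson
correlation as a scale-free companion (the covariance is the minimal
reading of the statistic; the correlation is reported because covariances
across parameters of different magnitude are not comparable).

The base point matters.  The transition line is non-monotone in $D_P$: on
its low-$D_P$ branch, *faster* product exchange still promotes
complementation (the product must be shuttled back), while at larger $D_P$
product equilibration erases the inhibition asymmetry and restores
symmetry.  The reported sign pattern (positive for $1/K_I$, $[S]$, $D_X$;
negative for $D_P$) characterizes the second branch, so the default base
point is found by bisecting $D_X$ at fixed $D_P = 5$
(`find_regime_boundary()`), giving $D_X^* \approx 3.3$ at $1/K_I = 10$.
The signs are stable across seeds at $n = 200$, and the equilibrium
constant of the first step comes out weakly positive, as expected from the
larger shuttling fluxes it allows.

## Permeability descriptors and the biological splitting point

The cheminformatics module asks the converse question: given a real
pathway, where would it split?  The model's answer — at the most permeable
non-channeled intermediate — is operationalized with descriptors computed
by OpenBabel (via `ChemmineOB`): molecular weight, H-bond donors and
acceptors, an atom-contribution octanol–water $\log P$, and the topological
polar surface area (Ertl's fragment-contribution method).  Structures are
taken exactly as written: the shipped tryptophan-pathway fixture pins each
metabolite in its physiological charge state (carboxylates and phosphates
anionic, indole and tryptophan neutral), because fragment TPSA and
molecular weight depend on the protonation state.  Two caveats are pinned
down in the fixture tests rather than hidden: fragment TPSA sums for
phosphorylated intermediates differ between implementations (OpenBabel
includes the phosphorus atom's own 9.81 Å² contribution), and computed
$\log P$ of charged species is dominated by the formal charge — which is
why the classification rules treat $\log P$ as a calibrated cut, not a
mechanistic quantity, and why no reference value for the phosphorylated
intermediates is asserted anywhere.

Classification into H/MH/ML/L permeability classes is performed by two
declared, editable rules shipped as YAML: a TPSA-only ladder (strictly
below 60 / 120 / 200 Å²) and a three-parameter decision list on TPSA,
$\log P$ and MW.  Both are conventions calibrated once so that the seven
tryptophan-pathway metabolites reproduce their reference classes; a
descriptor exactly on a threshold falls to the less permeable class and is
flagged.  A property test asserts the only mechanistic content we rely on:
at fixed $\log P$ and MW, increasing TPSA never makes a compound more
permeable.  `predict_breaking_point()` ranks the interior, non-channeled
intermediates by class (ties: lower TPSA, then lower MW).  Channeling is an
input flag — that indole never diffuses freely is structural knowledge
about tryptophan synthase, not something computable from a SMILES — and
with it the tryptophan pathway splits at anthranilate, exactly where the
*Buchnera*/*Serratia* consortium splits it; ignoring channeling, indole
wins the tie on TPSA.

## The synthetic generator, and what passing tests do not show

`synthetic_pathway()` draws descriptor tables with a known ground-truth
split (one or more interior positions given firmly high-permeability
descriptors, all others firmly low), used to exercise the predictor's
ranking and tie-breaking on 100 seeded pathways.  It emulates separation in
descriptor space, not chemistry: real pathways have correlated descriptors,
borderline classes and channeled steps, so a perfect recovery rate on
synthetic tables validates the ranking logic, not biological accuracy.
Likewise `sample_perturbed_parameters()` emulates parameter uncertainty
as independent multiplicative noise; real kinetic parameters co-vary.  The
kinetic model itself idealizes: passive non-saturating exchange, no
transcriptional regulation, deterministic steady states, a clamped
substrate, and protein cost counted as summed concentration with equal
weight per enzyme.

## Numerical choices

* Steady-state acceptance: residual max-norm $\le 10^{-8}$ (typically
  $10^{-12}$ by construction).
* Zero detection: $10^{-6} \times$ total enzyme, then exact re-solve on the
  active set; reported zeros are exact.
* Penalties: hinge weight $10^5$ on affine infeasibilities; per-enzyme rate
  floor $10^{-8}$; concentration floor $10^{-9}$ in null-space branches.
* Nelder–Mead budgets scale with dimension (base 400 iterations, doubled
  restarts, doubled again for the final refinement).
* Feasibility prechecks: $J_{P,0}>0$ with $D_P=0$ is rejected before
  solving with a diagnostic, as is any branch whose affine constraints are
  inconsistent (e.g. a forced split across an impermeable metabolite).
* Problem sizes in the shipped tests: $8\times8$ permeability grids,
  $n=200$ sensitivity samples, 100 synthetic pathways, two-stage
  $12^3$/$9^3$ grid oracle — sized so the whole suite runs in minutes on
  one CPU while every regime and property is exercised.

## Limitations

Global optimality is not certified; it is supported by the exhaustive
branch enumeration (for this model class the optima observed are always
branch-structured), multistart, and the grid-search oracle agreeing within
2% where it applies.  The competitive-inhibition variant implements the
standard textbook form, as the inhibition mechanism is only qualitatively
specified in this model class.  Phase diagrams are characterized by their
structural features (regions, signs, extreme values); particular grid
choices and axis ranges are presentation, not part of the package's
contract.
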