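---
title: "Differentiable enzyme-constrained FBA and optimal flux modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable enzyme-constrained FBA and optimal flux modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofmdiff)
```

## The model

Enzyme-constrained flux balance analysis (ecFBA) extends classical FBA by
making flux capacity a consequence of finite enzyme supply.  The linear
program is

$$
\max v_r \quad \text{s.t.} \quad
S v = 0,\qquad v \ge 0,\qquad
v_i = k_{cat,i}\, e_i \;\; (i \in R),\qquad
\sum_{i \in R_k} w_i e_i \le E_k \;\; (k = 1,\dots,K),
$$

where $S$ is the stoichiometric matrix, $v$ the fluxes
(mmol gDCW$^{-1}$ h$^{-1}$), $e$ the enzyme concentrations
(mmol gDCW$^{-1}$), $k_{cat}$ turnover numbers (h$^{-1}$), $w$ gene-product
molar masses (mg mmol$^{-1}$) and $E_k$ pool capacities (mg gDCW$^{-1}$).
A pool can be a whole proteome budget, a compartment (the membrane is the
interesting one for overflow metabolism), or a single enzyme.  Reversible
reactions are split into forward/backward irreversible copies before
anything else happens, so the flux cone is pointed.  Fixed nonzero fluxes
$v_j = c_j > 0$ (ATP maintenance being the canonical case) make the
constraint set inhomogeneous: the feasible set is then a flux polyhedron,
not a cone, and elementary flux modes (EFMs) are no longer defined.

Isozymes and enzyme complexes are supported: each isozyme of a reaction
becomes a parallel flux variable with its own kcat coupling, and a complex
couples each subunit's concentration to the flux through its subunit count.
When a gene product serves exactly one isozyme with unit count, the
coupling row has the canonical two-nonzero form $v - k_{cat} e = 0$; shared
gene products get the aggregated usage row
$\sum_u (n_u / k_{cat,u}) v_u - e = 0$.

## Optimal flux modes

To recover a mode concept for inhomogeneous problems, the package
homogenizes the *pruned* optimal problem with a slack variable: the columns
of reactions held at known values — the active fixed fluxes *and the
objective reaction at its optimal value* $z^*$ — are aggregated into a
single column $w = S^{(2)} v^{(2)}$, and the cone

$$\mathrm{OFC}(A) = \{x \ge 0 : A x = 0\},\qquad
A = [\,S^{(1)} \mid w\,],\; x = [\,v^{(1)}; \bar v\,]$$

is enumerated.  Extreme rays with $\bar v > 0$, rescaled to $\bar v = 1$,
are the optimal flux modes (OFMs): support-minimal admissible modes that
achieve the optimal objective-to-maintenance ratio.  Folding the objective
is essential, not cosmetic: without it, "maintenance-only" rays appear,
the optimum needs more than $K$ rays to decompose, and the weight-sum
identity breaks.  With it, the optimum $[v^{(1)*}; 1]$ decomposes as a
convex combination of at most $K$ OFMs (one per enzymatic constraint),
with $\sum_k \lambda_k = 1$ coming directly from the $\bar v$ row.  For a
purely homogeneous model the same machinery with `fold_objective = FALSE`
degrades to classical EFM enumeration of $FC(S)$.

Enumeration uses the Double Description method in null-space form: a
pivoted null-space basis of $A$ gives a simplicial starting cone whose $d$
coordinate constraints hold by construction; the remaining nonnegativity
constraints are inserted one at a time (descending nonzero count of the
corresponding columns of $A$, a standard anti-blow-up heuristic), combining
adjacent opposite-sign ray pairs, with adjacency decided by the algebraic
rank test.  EFMs are reported at unit 1-norm (a convention; nothing
canonical fixes the scale of a homogeneous ray), OFMs at $\bar v = 1$
(which *is* canonical).  Output order is lexicographic by support, so runs
diff cleanly.  An exponential brute-force enumerator
(`brute_force_modes()`) certifies support-minimality independently on
small instances and serves as the oracle in the tests.  Genome-scale EFM
enumeration is out of scope — the combinatorics are hopeless and not the
point; the pruned optima this package enumerates have a handful of rays.

## Pruning and uniqueness

The derivative of an LP solution map is only defined where the optimum is
unique.  Pruning deletes every reaction carrying (numerically) zero flux
and every enzyme with zero concentration from the reference optimum; what
remains is a model whose optimum is unique whenever all metabolic
reactions carry an enzyme cost — generic kcats and molar masses make the
mode cost vectors linearly independent.  The package treats uniqueness
operationally rather than axiomatically: `verify_unique()` runs flux
variability analysis with the objective pinned and demands zero-width
ranges (tolerance `1e-6`), and the pipeline refuses to differentiate when
the gate fails.

Two practical notes discovered while exercising the gate.  First, plain
alternate optima are genuinely *resolved* by pruning: a branch model with
two equal-cost routes returns a vertex using one route, and the pruned
model is unique again.  Second, degeneracy can survive pruning when
equal-cost routes are forced jointly active (e.g. both capped below a
fixed demand they must jointly meet); this is exactly the case the gate
exists for, and the CLI maps it to exit code 3 so pipelines can
distinguish mathematical failure from user error.  Cost-free reactions
(exchanges conventionally, but also incompletely parameterized internal
reactions) weaken the uniqueness premise, so the validator flags them.

## Implicit differentiation

At a unique vertex optimum, the active constraints (all equalities, plus
inequalities fulfilled with equality) satisfy $M x = b(p)$ and
stationarity $c = M^\top y$.  Differentiating the system for parameter
$p_j$ gives

$$M \frac{\partial x}{\partial p_j} =
  \frac{\partial b}{\partial p_j} - \frac{\partial M}{\partial p_j} x,$$

where $\partial M / \partial p_j$ and $\partial b / \partial p_j$ come
from per-entry partials recorded at LP-build time (kcats appear in
coupling-row entries; capacities, fixed fluxes and bounds on the
right-hand side; a parameter occurring in several entries sums its
per-occurrence partials).  Redundant active rows — conserved-moiety
steady-state rows are the common case — are removed by rank-revealing
pivoted QR (tolerance `1e-9`, dropped rows logged); rank deficiency beyond
redundancy means the optimum was not unique and is an error pointing back
at the gate.  One factorization of $M$ serves every parameter, applied
column by column so that single-parameter and batched calls are bitwise
identical.  Parameters touching only inactive constraints yield exactly
zero columns, not small ones.  When strict complementarity fails (an
active row with zero dual) the derivative is one-sided; the package warns
and proceeds with the chosen active set rather than guessing.

Scaled sensitivities (control coefficients) are
$(p_j / x_i)\,\partial x_i / \partial p_j$; entries at $|x_i| \le$
`tol_zero` are reported `NA` (undefined), never zero.  On homogeneous
models the kcat control coefficients of every flux sum to one — the
summation-theorem analogue of the fact that scaling all kcats by $\alpha$
scales the optimum by $\alpha$ — and the tests assert it at `1e-6`.

The independent check is central finite differencing: each parameter
perturbed $\pm 0.1\%$ (`rel_step = 1e-3`, configurable), the pruned model
re-solved from scratch, slope taken.  The oracle shares nothing with the
implicit route except the simplex itself.

## OFM usage sensitivities

The weights solve $R(p)\lambda(p) = x^*(p)$.  A subtlety worth spelling
out: because the homogenized column $w$ contains the objective at its
optimal value $z^*(p)$, *the mode matrix itself moves with kinetic and
capacity parameters* — each OFM's values on its support solve
$A_S r = -w$ with $dw/dp = S_{obj}\, dz^*/dp$.  The implemented chain rule
is therefore

$$R_{sub}\,\frac{d\lambda}{dp} =
  \frac{dx^*_{sub}}{dp} - \frac{dR_{sub}}{dp}\,\lambda,$$

not the naive $R_{sub}^{-1} dx^*_{sub}/dp$, which disagrees with the
re-enumerating finite-difference oracle the moment $dz^*/dp \ne 0$ (i.e.
essentially always).  The row subset always contains the $\bar v$ row —
whose equation is $\sum_k \lambda_k = 1$, making the conservation
$\sum_k d\lambda_k/dp = 0$ exact rather than approximate — and is
completed by greedy maximal orthogonal pivots; a condition number above
`1e10` aborts with diagnostics.  Fixed-flux parameters $c_j$ change $w$
(and hence the cone) in a way that mode matching across the perturbation
does not cover; they are rejected with an explicit error rather than
silently mishandled.

## Solver

The LPs are solved by an in-package dense two-phase revised simplex with a
deterministic pivot rule (Dantzig with fixed tie-break, Bland fallback
against cycling).  This is a deliberate fit to the method, not a stopgap:
pruning and the $\le K$ decomposition presume a *basic* optimum, and KKT
differentiation needs exact basis duals — an interior-point solver would
return centres of optimal faces and break both.  The dense pure-R
implementation is entirely adequate at the sizes this package targets
(tens of variables; the basis system is re-solved each iteration for
numerical freshness).  Feasibility tolerance is `1e-9`; downstream
activity classification uses `tol_zero = 1e-6` relative to the largest
flux, and active-set detection `tol_act = 1e-6`.  All are configurable and
recorded in the output manifest.

## The generators, and what passing tests do not show

The named fixtures are constructed so that every headline property has a
closed form: the chain's optimum is $k_{cat} E / w$ with unit scaled
sensitivities; the branch model's faster route takes the entire shared
pool; the overflow model (respiratory route in a `membrane` pool,
fermentative route and biomass in a `cytosol` pool, maintenance fixed at
1) binds both pools at the optimum, so its optimum is a superposition of
exactly two OFMs with weights $5/9$ and $4/9$, and every cytosolic kcat
increases the fermentative weight while the membrane kcat increases the
respiratory one — the membrane-crowding mechanism at desk scale.

`random_ec_network()` emulates the *structural* situation of
enzyme-constrained models — a feasible backbone pathway, random bypasses
with small-integer stoichiometry, log-uniform kcats over three decades
$[0.1, 100]$ h$^{-1}$, molar masses in $[10, 100]$ mg mmol$^{-1}$, random
pool partitions — and rejection-samples until the optimum is positive and
unique after pruning (ties are measure-zero but floating point is not a
measure space).  It does not emulate genome-scale features: no
compartments, no cofactor coupling patterns, no reversibility mix, no
thousand-reaction scale, and its networks are acyclic by construction.
Passing tests therefore demonstrate correctness of the mathematics on
generic well-posed instances, not robustness to the pathologies of any
particular published reconstruction; the COBRA-JSON import path is
exercised against a small synthetic model, not a curated one.

Test problem sizes are deliberate: random models default to 6 metabolites,
10 reactions, 2 pools (large enough for multi-mode optima, small enough
that the brute-force mode oracle and 50-model sweeps stay instantaneous),
and Double Description is cross-checked against brute force on networks of
at most 12 reactions, where exhaustive support enumeration is exact and
fast.

## Known limitations

* Sensitivities are local: an infinitesimal analysis cannot see
  active-set changes (metabolic switching points); deliberately out of
  scope.
* OFM-usage sensitivity to fixed-flux values is unsupported (see above).
* SBML/fbc input is a non-goal; the native JSON schema and best-effort
  COBRA-JSON import are the supported formats.
* No MILP, quadratic objectives, or parsimonious-FBA variants.

## A worked run

```{r pipeline, eval = FALSE}
fx <- make_overflow()
res <- run_pipeline(fx$model, fx$params, out_dir = "overflow_run")
res$solution$objective_value        # 4.4
res$decomposition$lambda            # ofm1 = 4/9 (ferm), ofm2 = 5/9 (resp)
res$ofm_sensitivity$scaled          # membrane-crowding sign structure
```

The CLI wrapper (`inst/cli/ofmdiff`) exposes the same pipeline as
subcommands with exit codes 0 (success), 2 (usage/validation) and 3
(numerical gate), and `scripts/acceptance.R` recomputes every quantity
above from scratch.
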