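---
title: "Modeling learning traits in a two-armed bandit and their effect on insight problem solving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling learning traits in a two-armed bandit and their effect on insight problem solving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insightrl)
```

## The scientific question

Insight problems — puzzles such as the 8-coin problem (rearrange coins so
each touches exactly three others, which requires moving from two to
three dimensions) and the 9-dot problem (connect nine dots with four
straight lines, which requires drawing outside the implied square) — are
solved by relaxing constraints the solver imposes on themselves. This
package implements a computational pipeline for asking whether
*learning traits*, estimated from entirely separate reinforcement-learning
behavior, predict success on such insight tasks, and whether experience
with one insight task transfers to the other.

The pipeline has four stages, each usable on its own:

1. **Bandit task simulation** (`make_standard_schedule()`,
   `simulate_agent()`): a two-armed bandit (TAB) of 100 choices between a
   right and a left box, paying +10 or −10 points. The right box wins
   with probability 0.7 on trials 1–30, 0.3 on trials 31–70 and 0.7 on
   trials 71–100; the left box is complementary. The two reversals
   prevent simple convergence on one box.
2. **Cognitive model and estimation** (`fit_map()`, `fit_cohort()`): a
   prospect-utility Q-learning model fitted per subject by maximum a
   posteriori (MAP) estimation, yielding seven trait estimates.
3. **Synthetic cohort generation** (`generate_cohort()`): a full study —
   enrollment, exclusions, task order, binary insight outcomes with a
   configurable transfer effect — so the downstream analyses can be
   validated end to end without human data.
4. **Inference** (`run_table3_analysis()`, `run_table4_analysis()`,
   `success_rate_comparison()`, `descriptive_stats()`): probit
   regressions of task success on the estimated traits, order-split
   subsample analyses, and first-vs-second success-rate chi-square tests.

## The cognitive model

On trial $t$ the agent holds action values $Q_{i,t}$ for the two boxes
($i \in \{\text{right}, \text{left}\}$), starting at $Q_{i,1} = 0$.
Choices follow the softmax rule

$$P(a_t = i) = \frac{e^{\beta Q_{i,t}}}{\sum_j e^{\beta Q_{j,t}}},$$

where $\beta \ge 0$ is the inverse temperature: the larger $\beta$, the
more the agent exploits the higher-valued box; at $\beta = 0$ choice is
uniform. The obtained reward $R$ is transformed by a prospect utility
function

$$U(R) = \begin{cases} R^{\mu} & R > 0 \\ -\lambda (-R)^{\nu} & R < 0, \end{cases}$$

with gain curvature $\mu$ (risk aversion in gains), loss curvature $\nu$
(risk seeking in losses) and loss aversion $\lambda$ (how strongly
losses weigh against equal gains). The chosen box's value is updated by
the prediction error $\delta_t = U(R_t) - Q_{c,t}$ with asymmetric
learning rates and an additive perseveration control $\phi$:

$$Q_{c,t+1} = Q_{c,t} + \alpha^{+}\,\delta_t + \phi \quad (\delta_t \ge 0),
\qquad Q_{c,t+1} = Q_{c,t} + \alpha^{-}\,\delta_t + \phi \quad (\delta_t < 0),$$

while the unchosen box's value carries over unchanged. $\phi$ absorbs
the tendency to repeat choices regardless of value, which would
otherwise bias the learning rates.

Three conventions are fixed in code and worth stating: $\delta = 0$
takes the $\alpha^{+}$ branch; a zero reward maps to zero utility (both
utility branches exclude zero; continuity forces 0); and $\phi$ is
applied inside the value update on every trial, exactly as the update
rule is written, not as a choice-kernel bonus inside the softmax. The
additive-$\phi$ form has a known pathology: a nonzero $\phi$ accumulates
in whichever box is chosen, so large $|\phi|$ drives the model into
deterministic repetition or alternation. We implement the stated form
and manage the pathology at the estimation and generation stages (below)
rather than silently altering the model.

## MAP estimation

Each subject's traits $\theta = (\beta, \mu, \nu, \alpha^{+},
\alpha^{-}, \lambda, \phi)$ are estimated by maximizing
$\log p(D\mid\theta) + \log p(\theta)$, where the likelihood filters the
subject's choice/reward sequence forward through the model and the
priors are Beta(2, 2) on $\alpha^{\pm}$, Gamma(shape 2, scale 3) on
$\beta, \mu, \nu, \lambda$, and N(0, 1) on $\phi$.

Numerical choices:

* **Search coordinates.** The optimizer works in log coordinates for the
  non-negative traits and logit coordinates for the learning rates, but
  the posterior is evaluated in natural coordinates without a Jacobian
  term — the transform is a search device, not a reparameterized
  posterior, so the maximizer is the MAP of the stated objective.
* **Log-sum-exp likelihood.** Choice log-probabilities are accumulated
  as $\beta Q_c - \mathrm{logsumexp}(\beta Q)$, which stays finite (e.g.
  −800) where the softmax probability itself underflows to zero in
  double precision. Without this the objective has wide flat regions
  that trap gradient-based search.
* **Search bounds.** Log coordinates are bounded to $[-12, 5]$ (natural
  scale roughly $[6\times10^{-6}, 148]$). Curvatures above ~150 give
  utilities beyond $10^{150}$ whose Q values overflow, flattening the
  objective; nothing scientifically meaningful lives out there, since
  even $\mu = 5$ means a +10 reward is worth $10^5$ utility units.
  $\phi$ is searched within $[-50, 50]$ (configurable) to contain its
  drift pathology; fits that end on a bound are flagged, not dropped.
* **Multi-start.** Ten restarts per subject drawn from the priors
  (L-BFGS-B, relative tolerance $10^{-6}$, at most 2000 evaluations per
  start), best posterior wins, ties to the first found. In diagnostic
  runs at 1000 trials the returned optimum dominates the generating
  truth's posterior for every agent, so the search reliably attains the
  MAP in the regime the cohort occupies.

## What is — and is not — identifiable

With rewards fixed at $\pm 10$, the utilities take exactly two values:
$10^{\mu}$ for every gain and $-\lambda\,10^{\nu}$ for every loss.
Scaling all utilities by $c$ and $\beta$ by $1/c$ leaves every choice
probability unchanged. The data therefore identify only the two products
$\beta\,10^{\mu}$ and $\beta\,\lambda\,10^{\nu}$ (together with
$\alpha^{\pm}$ and $\phi$); the decomposition into $\beta$ versus
$\mu, \nu, \lambda$ is resolved by the priors alone. Parameter-recovery
simulations (`parameter_recovery()`, stage 4 of the analysis workflow)
make this visible: at 1000 trials the learning rates recover best
(true-vs-estimated correlations roughly 0.6–0.9, seed-dependent),
while $\beta$ plateaus far lower
(roughly 0.4–0.65) no matter how many optimizer restarts are used — an
attenuation that is structural to the two-outcome task design, not an
estimation defect, and that heterogeneous $\beta$ compounds: agents with
small $\beta$ barely express their values in choice, weakening the
learning-rate signal too. Interpretation of the curvature and
temperature estimates should respect this.

Recovery truths are drawn from the cohort generator's trait
distributions, except that $\phi$ is drawn from its standard-normal
prior: at the cohort-level $\phi$ spread (below), sessions collapse into
deterministic repetition that carries no information about any trait,
so recovery under those $\phi$ values measures nothing.

## The synthetic cohort

`default_study_config()` encodes the emulated study design: 364
enrolled, 7 excluded as incomplete, 32 excluded for prior task
experience (325 retained), and a 50/50 task order. Latent traits are
drawn from normal distributions truncated to each trait's support,
centered at the cohort-level means with matching SDs
($\beta$: 0.85/1.06, $\mu$: 0.48/0.28, $\nu$: 0.52/0.30,
$\alpha^{+}$: 0.42/0.27, $\alpha^{-}$: 0.59/0.29, $\lambda$: 0.51/0.28,
$\phi$: −12.57/213.86). One deliberate deviation: the $\phi$ parent
normal is truncated to $[-50, 50]$, the estimator's own search range,
because values beyond it are behaviorally degenerate under the additive
update rule; the cohort-level $\phi$ spread is hard to reconcile with
the model's stated standard-normal prior in the first place, and we
choose the estimable range rather than reproduce it literally.

Binary insight outcomes are generated at the level the analysis
consumes: a probit link on the *true* traits and TAB performance, with
an additional transfer coefficient on the other task's success for
whichever task is administered second. Default link coefficients are the
full-specification point estimates, including the 0.59 transfer terms
and the $-0.63$ loss-aversion effect on the 9-dot task. Because the
first-administered task has no transfer term, the transfer coefficient
is only cleanly recoverable from cohorts where the modeled task is
always second (`order_probability` 0 or 1); recovery tests use that
mode. Generating from true traits while the pipeline re-estimates them
reproduces the errors-in-variables structure of the real design, so
full-pipeline effect estimates are expected to attenuate relative to the
generating coefficients. Exclusion flags are assigned independently of
traits — a simplification; real dropout may be informative.

Regressors enter the links unstandardized, matching the scale convention
of the emulated analyses; `probit_fit()` accepts any regressor table, so
standardized sensitivity analyses are a `scale()` away.

## Inference stage

`probit_fit()` is maximum-likelihood probit regression (via
`stats::glm`) reporting coefficients, standard errors, z and p values
and AIC $= 2k - 2\log L$; degenerate outcomes and separation are
flagged rather than thrown. Significance markers are *** $p<0.01$,
** $p<0.05$, * $p<0.1$. The order comparison uses the Pearson
chi-square on the 2×2 success-by-order table with no continuity
correction. Non-converged subject fits are dropped listwise with a
logged count. No multiple-testing correction is applied, matching the
emulated analysis; the star legend and the order-split sizes are
configuration, not conclusions.

## Determinism and problem sizes

Every random quantity descends from one root seed through
`derive_seed()`, a modular mixing of (stage, subject, trial) keys; each
trial position owns its uniform draws, so probing one draw never
perturbs later ones, and two runs of `run_full_study()` with the same
seed write byte-identical tables (checksummed in the run manifest).

The shipped analysis scripts and tests use the study-design sizes where
they are the point (364 enrolled / 325 retained; 100-trial sessions;
10 restarts) and smaller or larger sizes where the quantity being
checked dictates them: 1000-trial sessions and 50 agents for recovery,
10,000 sessions for schedule calibration, 50,000 subjects in true-trait
mode for probit coefficient recovery, and cohorts of a few hundred for
structural checks.

## Known limitations

* The insight tasks are modeled only as binary outcomes through a
  probit link; no puzzle-solving process is simulated.
* The additive $\phi$ update is implemented as stated; its unbounded
  drift is contained, not resolved. A choice-kernel formulation would
  behave better but would be a different model.
* $\beta$, $\mu$, $\nu$, $\lambda$ are jointly under-identified in a
  two-outcome task (see above); cohort-level distributions of their
  estimates are prior-shaped and need not match the generating ones.
* The synthetic cohort is a design emulator, not a behavioral dataset:
  passing tests show the pipeline's statistics are correct and
  recoverable under the stated generative assumptions, not that those
  assumptions describe human participants.
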