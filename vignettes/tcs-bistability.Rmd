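---
title: "Modular gain analysis of autoregulated two-component systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular gain analysis of autoregulated two-component systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsgain)
```

## The model and its assumptions

`tcsgain` analyzes the steady states of a positively autoregulated
two-component system (TCS) whose transcription factor — the
phosphorylated response regulator (RR) — also binds a pool of competing
genomic sites. The analysis rests on a timescale separation: DNA binding
equilibrates in seconds, phosphorylation in minutes, and transcription
over tens of minutes to hours, so the circuit decomposes into three
modules composed in series,

$$\frac{1}{k_{dil}}\frac{dR_T^*}{dt} = F(B(A(R_T^*))) - R_T^*,$$

with growth dilution acting only on the slow (transcription) variable.
All concentrations are divided by the autoregulated-promoter affinity
$K_{auto}$, giving the dimensionless "starred" quantities used
throughout; `normalize_params()` performs the conversion once at the
boundary, and `molecules_from_concentration()` links concentrations to
per-cell copy numbers (default cell volume $10^{-15}$ L, configurable).

* **Activation** `rp_approx()`: the bifunctional histidine kinase (HK)
  phosphorylates and dephosphorylates the RR. When the RR is in excess
  over the HK, the steady-state phosphorylation level depends only on
  total RR $R_T^*$ and two composites: the capacity $Cp^*$ (the
  saturating phosphorylation level; the signal-dependent input) and a
  half-saturation scale $Ct^*$. The closed form is the smaller root of a
  quadratic, evaluated in a cancellation-free arrangement.
* **Binding** `forward_RP()`/`solve_Rf()`: $D^*$ identical decoy sites
  of relative affinity $K^*$ bind $l$ TF molecules per site through a
  single Hill lump, $R_P^* = R_f^* + l D^* {R_f^*}^l/({R_f^*}^l +
  {K^*}^l)$. At $l = 2$ (dimeric TF, two half-sites) this is the exact
  dimer-competition form; for other $l$ the single-lump Hill
  generalization is a deliberate simplification — the exact
  stoichiometric convention for partial site occupancy is not pinned
  down by the modeling literature this follows, and the lump reduces
  exactly to the reference case at $l = 2$.
* **Transcription** `production_F()`: Hill activation with fold change
  $f$ and cooperativity $h$, ranging from basal $R_b^*$ to induced
  $f R_b^*$.

Each module carries a logarithmic gain (slope on log–log axes): `lg_A()`
($\le 1$, crossing $1/2$ exactly at $R_T^* = Cp^* + Ct^*$), `lg_B()`
(equal to 1 without decoys; below 1 while decoys buffer free TF, above 1
once they saturate — the sign of $LG_B - 1$ is the sign of
$R_f^* - K^*$), and `lg_F()` (maximum $h(\sqrt f - 1)/(\sqrt f + 1)$ at
$R_f^* = f^{-1/2h}$). The open-loop product $LG_3 = LG_F LG_B LG_A$
exceeding 1 is a *necessary* condition for bistability; it is not
sufficient, because the basal level $R_b^*$ decides whether the
steady-state intersections actually reach the high-gain region. The
package therefore keeps both views: `phase_diagram()` maps where
$\max LG_3 > 1$ (bistability *possible*), and `steady_states()` /
`dose_response()` count actual fixed points.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `f` | fold change (max/basal production) | — | system-specific; 1–100 covers documented TCSs |
| `h` | promoter cooperativity | 2 | most RRs bind DNA as dimers |
| `Rb` | basal level $R_b^*$ | — | sets the reachable production range |
| `D`, `K`, `l` | decoy amount, relative affinity, cooperativity | 0, 1, 2 | no competition unless stated; dimer binding |
| `Cp`, `Ct` | phosphorylation capacity and half-saturation | `Inf`, 3 | `Ct* = 3` is the conventional fixed value for phase-diagram work; `Cp` is the swept signal |
| `K_rep`, `h_rep` | reporter-promoter occupancy | 1, 2 | dimensionless reporter with dimeric binding; `h_rep` is not pinned by the underlying model and is configurable |

All quantities are dimensionless ($K_{auto}$-normalized). Physiological
anchors used in tests and defaults: an affinity of 0.1 µM is about 60
molecules in a $10^{-15}$ L cell; RR abundances of 40–8000
molecules/cell motivate the $R_T^*$ working range 0.1–100.

## Numerical choices

* **Inverting the binding map.** The forward map is strictly increasing
  with a guaranteed bracket $[0, R_P^*]$, so `solve_Rf()` uses
  safeguarded Brent iteration with tolerance $10^{-12}$ and verifies the
  residual. The analytic $LG_B$ is used at $l = 2$; other $l$ fall back
  to a log–log central difference through the inverse map (flagged in
  the result's `method` attribute).
* **Fixed points.** `steady_states()` scans 2000 log-spaced points on
  $[0.9 R_b^*, 1.1 f R_b^*]$ (the production image with margin) for sign
  changes of $G(R_T^*) = F(B(A(R_T^*))) - R_T^*$, refines each by Brent,
  and labels stability by the sign of a central-difference $G'$
  (equivalently $LG_3 \lessgtr 1$ at a fixed point); $|G'| < 10^{-8}$ is
  reported as `degenerate` rather than silently classified. Since
  $G > 0$ at the lower edge and $G < 0$ at the upper edge, an even
  number of detected crossings signals a merged pair: the scan is
  repeated at 4× resolution and a warning is raised if the parity
  persists.
* **Saddle-node edges.** `dose_response()` brackets each fold between
  the last monostable and first tristate grid value and bisects the
  state count to $10^{-4}$ relative.
* **Full phosphorylation model.** The six-species mass-action scheme
  (free HK/HKP/RR/RRP plus explicit phosphotransfer and phosphatase
  complexes) is solved *exactly* at steady state: the complex and HKP
  balance equations reduce every species to a function of free RR, and
  the RR conservation law becomes one monotone scalar equation, solved
  by bracketed root finding and audited against both conservation laws
  ($<10^{-8}$ relative) and the phosphotransfer/phosphatase flux
  balance. This replaces stiff time integration entirely — the steady
  state of this subsystem is unique and monotone in total RR, so
  root-finding is both faster and more accurate. Degenerate rate sets
  without a dephosphorylation sink are handled as explicit limits.
  The default elementary rates are generic documented constants chosen
  to give a saturating monotone curve with capacity $\approx 20$ (middle
  of the physiological range); they are not measurements, so all
  full-model tests are property-based, and quantitative comparisons go
  through `effective_capacity()`, which recovers $(Cp^*, Ct^*)$ from any
  curve (asymptote + half-saturation moments, then least-squares
  refinement).
* **Coupled negative feedback.** Two mechanisms. *Transcriptional*:
  an independent repression site multiplies the promoter function by a
  repressive Hill factor — the product of regulatory factors is the
  standard composition for independently binding sites, and it makes the
  coupled gain the sum $LG_F + LG_N$ with $LG_N \le 0$. *Capacity
  inhibition*: the RR activates an inhibitor of its own phosphorylation;
  this is modeled as Hill inhibition of the capacity,
  $Cp^*_{eff} = Cp^*/(1 + (R_f^*/K_I^*)^{h_I})$ — a functional form
  chosen here (the mechanism is only specified as "reduces $Cp^*$ at
  steady state"), solved self-consistently inside the composed map. The
  repression parameters are left free rather than fixed, since no
  canonical values exist.
* **Gain at zero.** `lg_F(0)` and `lg_N(0)` are defined as 0 by
  continuous extension so grids containing 0 need no special casing.
* **Site metrics.** Individual information
  $R_i = \sum_l [2 - e(n) + \log_2 f(b_l, l)]$ uses the small-sample
  correction in its standard first-order form $e(n) = 3/(2 \ln 2\, n)$
  bits per position, and a pseudocount of 0.5 below $n = 50$ sites —
  the conventional choices; both are configurable and recorded in the
  PWM object, because published per-site values depend on the exact
  variant. ΔSNR uses base-10 logs and per-TF median centring; peak
  percentiles are mid-rank fractions (ties averaged). Sequences are
  taken as aligned and single-stranded; there is no motif discovery or
  genome scanning.

## What the synthetic generators emulate — and what they do not

`generate_pwm_sites()` draws aligned sites from an independent
per-position substitution model around a consensus, so the true
frequency matrix is known and information-content code can be checked
against ground truth. Real TFBS collections have position-dependent,
correlated variability and alignment uncertainty; a green test
establishes the arithmetic, not performance on curated sites.
`generate_peak_table()` draws lognormal ChIP intensities with the
autoregulated peak pinned at a stated quantile — it validates ranking
and centring logic, not peak calling. `generate_abundance_table()`
calibrates the fraction of TFs below a TF/TFBS ratio threshold; it makes
no claim about the real abundance distribution's shape.
`generate_param_grid()` provides log-spaced factorial or
Latin-hypercube parameter sets within the documented ranges. All
generators are pure functions of their arguments plus a seed, and
restore the caller's RNG state.

## Known limitations

* Deterministic, mean-field: TFs at tens of copies per cell are noisy,
  and stochastic switching near the saddle-nodes is outside scope.
* All decoys share one affinity and cooperativity; heterogeneous
  mixtures and competition by other DNA-binding proteins are not
  modeled.
* One universal dilution rate for free and DNA-bound protein.
* The bistable interval is detected by dense scanning, not numerical
  continuation; folds closer than the scan resolution to each other
  would require raising `n_scan`.
* Reproduction of published dose–response figures is qualitative (state
  counts, mono/bi classification): several of the underlying constants
  (`Ct*`, exact `Cp*` sweeps) are conventions rather than measurements,
  and they are recorded as assumptions in output metadata.
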