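#' Activation module A: phosphorylated RR from total RR
#'
#' Steady-state RR phosphorylation in a TCS with a bifunctional histidine
#' kinase, under the approximation that the RR is in large excess over the
#' HK. The implicit relation
#' \deqn{R_P^* = \frac{Cp^* (R_T^* - R_P^*)}{Ct^* + R_T^* - R_P^*}}
#' has the closed-form (smaller-root) solution
#' \deqn{R_P^* = \tfrac12\left(b - \sqrt{b^2 - 4 Cp^* R_T^*}\right),
#'   \quad b = Cp^* + Ct^* + R_T^*,}
#' evaluated here in the cancellation-free form
#' \eqn{2 Cp^* R_T^* / (b + \sqrt{b^2 - 4 Cp^* R_T^*})}. `Cp*` is the
#' phosphorylation capacity: the saturating phosphorylation level at high
#' total RR. `Ct*` sets how much total RR is needed to approach it.
#'
#' @param RT total RR level, normalized, `>= 0`. Vectorized.
#' @param Cp phosphorylation capacity, `>= 0`. `Inf` is allowed and gives
#'   `RP = RT` (no phosphatase limitation).
#' @param Ct half-saturation composite, `>= 0`.
#' @return Phosphorylated RR level(s), `0 <= RP <= min(RT, Cp)`.
#' @examples
#' rp_approx(2, Cp = 1, Ct = 1)  # 2 - sqrt(2)
#' @export
rp_approx <- function(RT, Cp, Ct) {
  if (any(RT < 0) || any(Cp < 0) || any(Ct < 0))
    stop("`RT`, `Cp` and `Ct` must be >= 0")
  if (is.infinite(Cp)) return(RT)
  b <- Cp + Ct + RT
  disc <- b^2 - 4 * Cp * RT
  disc[disc < 0] <- 0  # guard roundoff; analytically disc >= 0
  2 * Cp * RT / (b + sqrt(disc))
}

#' Logarithmic gain of the activation module
#'
#' \deqn{LG_A = 1 - \frac{R_T^* - R_P^*}
#'   {Ct^* + Cp^* - R_P^* + R_T^* - R_P^*} \in [0, 1].}
#' The gain is 1 when phosphorylation tracks total RR (far from capacity),
#' decays to 0 at saturation, equals exactly 1/2 at
#' `RT = Cp + Ct`, and is below 1/2 beyond that point. Because `LG_A <= 1`
#' the activation module never promotes bistability; it can only limit it.
#'
#' @inheritParams rp_approx
#' @return Gain value(s) in `[0, 1]`.
#' @export
lg_A <- function(RT, Cp, Ct) {
  if (any(RT <= 0)) stop("`RT` must be > 0")
  if (any(Cp <= 0)) stop("`Cp` must be > 0 for a defined gain")
  if (any(Ct < 0)) stop("`Ct` must be >= 0")
  if (is.infinite(Cp)) return(rep(1, length(RT)))
  RP <- rp_approx(RT, Cp, Ct)
  u <- RT - RP
  den <- Ct + Cp - RP + u
  out <- 1 - u / den
  # Ct = 0, RT = Cp: 0/0 corner between the LG=1 and LG=0 branches
  out[den == 0] <- NaN
  out
}

#' Rates of the full mass-action bifunctional-HK model
#'
#' Elementary reactions: HK autophosphorylation/auto-dephosphorylation as
#' pseudo first-order reversible steps (`k_k`, `k_unp`); phosphotransfer
#' via an explicit HKP.RR complex (`kon_t`, `koff_t`, `kcat_t`); and
#' phosphatase action of the unphosphorylated HK via an explicit HK.RRP
#' complex (`kon_p`, `koff_p`, `kcat_p`). Explicit complexes (rather than
#' Michaelis-Menten rate laws) are kept because complex sequestration is
#' what makes the approximation fail at RR/HK ratios near 1.
#'
#' The defaults are generic constants chosen to give saturating monotone
#' phosphorylation curves at desk scale; they are not measurements of any
#' particular system, so quantitative conclusions should come from the
#' capacity parameters extracted with [effective_capacity()], not from the
#' raw rate values.
#'
#' @param k_k,k_unp HK autophosphorylation / auto-dephosphorylation rates.
#' @param kon_t,koff_t,kcat_t phosphotransfer complex rates.
#' @param kon_p,koff_p,kcat_p phosphatase complex rates.
#' @return An object of class `tcs_full_rates`.
#' @export
full_tcs_rates <- function(k_k = 2, k_unp = 0.1,
                           kon_t = 5, koff_t = 1, kcat_t = 10,
                           kon_p = 0.2, koff_p = 1, kcat_p = 1) {
  r <- list(k_k = k_k, k_unp = k_unp,
            kon_t = kon_t, koff_t = koff_t, kcat_t = kcat_t,
            kon_p = kon_p, koff_p = koff_p, kcat_p = kcat_p)
  if (any(unlist(r) < 0)) stop("all rates must be >= 0")
  if (kon_t <= 0 || kon_p <= 0) stop("on-rates must be > 0")
  structure(r, class = "tcs_full_rates")
}

#' Steady state of the full mass-action TCS phosphorylation model
#'
#' Solves the six-species system (HK, HKP, RR, RRP, HKP.RR, HK.RRP) at
#' steady state, exactly: setting the complex and HKP time derivatives to
#' zero reduces every species to a function of free RR, and the RR-moiety
#' conservation law becomes a single monotone scalar equation solved by
#' bracketed root finding. Residuals of all rate equations and both
#' conservation laws are verified below `1e-8` (relative).
#'
#' @param RT total RR concentration (normalized), `> 0`. Vectorized.
#' @param rho RR/HK ratio; total HK is `RT / rho`.
#' @param rates a [full_tcs_rates()] object.
#' @return A data.frame with one row per `RT`: free species `HK`, `HKP`,
#'   `RR`, `RRP`, complexes `C_t` (HKP.RR), `C_p` (HK.RRP), and `RP`
#'   (free phosphorylated RR, the module output).
#' @export
full_model_steady <- function(RT, rho, rates = full_tcs_rates()) {
  stopifnot(inherits(rates, "tcs_full_rates"))
  if (any(RT <= 0)) stop("`RT` must be > 0")
  if (rho <= 0) stop("`rho` must be > 0")
  out <- lapply(RT, function(rt) .full_steady_one(rt, rt / rho, rates))
  do.call(rbind, out)
}

# one steady state: exact algebraic reduction to a 1-D root find in free RR
.full_steady_one <- function(RT, HKT, r) {
  if (r$kcat_p == 0 && r$k_k > 0 && r$kcat_t > 0) {
    # no dephosphorylation sink at steady state: phosphotransfer flux must
    # vanish, which forces free RR to zero and drives RR fully
    # phosphorylated (supported for k_unp = 0, where all HK is HKP and no
    # phosphatase complex forms)
    if (r$k_unp > 0)
      stop("kcat_p = 0 with k_unp > 0: degenerate rate set not supported")
    return(data.frame(RT = RT, HK = 0, HKP = HKT, RR = 0, RRP = RT,
                      C_t = 0, C_p = 0, RP = RT))
  }
  Km_t <- (r$koff_t + r$kcat_t) / r$kon_t
  Km_p <- (r$koff_p + r$kcat_p) / r$kon_p
  # at steady state (d/dt of complexes and HKP = 0), with u = [RR] free:
  #   HKP = HK * g(u),          g(u) = k_k / (k_unp + kcat_t * u / Km_t)
  #   C_t = HKP * u / Km_t
  #   RRP = v(u) independent of HK (phosphotransfer flux = phosphatase flux):
  #         kcat_t * HKP * u / Km_t = kcat_p * HK * RRP / Km_p
  #   C_p = HK * RRP / Km_p
  g <- function(u) r$k_k / (r$k_unp + r$kcat_t * u / Km_t)
  v <- function(u) (r$kcat_t * Km_p / (r$kcat_p * Km_t)) * u * g(u)
  hk_of <- function(u) {
    HKT / (1 + g(u) * (1 + u / Km_t) + v(u) / Km_p)
  }
  resid <- function(u) {
    hk <- hk_of(u)
    u + v(u) + hk * (g(u) * u / Km_t + v(u) / Km_p) - RT
  }
  if (r$k_k == 0 || r$kcat_t == 0) {
    # no phosphorylation flux: everything unphosphorylated
    u <- RT
  } else {
    u <- uniroot(resid, c(RT * 1e-12, RT), tol = 1e-14 * max(1, RT),
                 maxiter = 500)$root
  }
  hk <- hk_of(u); hkp <- hk * g(u)
  ct <- hkp * u / Km_t; rrp <- v(u); cp <- hk * rrp / Km_p
  st <- data.frame(RT = RT, HK = hk, HKP = hkp, RR = u, RRP = rrp,
                   C_t = ct, C_p = cp, RP = rrp)
  # conservation + rate-balance audit
  cons_rr <- abs(u + rrp + ct + cp - RT) / max(1, RT)
  cons_hk <- abs(hk + hkp + ct + cp - HKT) / max(1, HKT)
  flux <- abs(r$kcat_t * ct - r$kcat_p * cp) / max(1e-300, r$kcat_t * ct)
  if (max(cons_rr, cons_hk) > 1e-8 || (r$k_k > 0 && flux > 1e-6))
    stop(sprintf(
      "full-model steady state failed its audit at RT = %g (residuals %.2e/%.2e/%.2e)",
      RT, cons_rr, cons_hk, flux))
  st
}

#' Extract effective capacity parameters from a phosphorylation curve
#'
#' Inverts the approximation relation: `Cp*` is the saturation asymptote
#' of `RP(RT)` and `Ct*` equals `RT - Cp*/2` at the point where `RP`
#' crosses `Cp*/2`. Those moment estimates seed a least-squares refinement
#' against [rp_approx()] (disable with `refine = FALSE`). Used to compare
#' the full mass-action model with the approximation and to summarize it
#' by two numbers.
#'
#' @param RT,RP a monotone nondecreasing phosphorylation curve with at
#'   least 10 points spanning saturation.
#' @param refine logical; polish the estimates by nonlinear least squares.
#' @return A list with `Cp`, `Ct`, and `residual` (maximal relative
#'   deviation of `rp_approx(RT, Cp, Ct)` from the input `RP`). If the
#'   curve is not saturated (last two `RP` differ by more than 1%) a
#'   warning is issued and `saturated = FALSE` is set.
#' @export
effective_capacity <- function(RT, RP, refine = TRUE) {
  if (length(RT) < 10 || length(RP) != length(RT))
    stop("need >= 10 (RT, RP) pairs of equal length")
  o <- order(RT); RT <- RT[o]; RP <- RP[o]
  if (any(diff(RP) < -1e-9 * max(RP)))
    stop("`RP` must be monotone nondecreasing in `RT`")
  n <- length(RP)
  if (max(RP) == 0) {
    warning("constant-zero curve: capacity 0, Ct undefined")
    return(list(Cp = 0, Ct = NA_real_, residual = 0, saturated = TRUE))
  }
  saturated <- abs(RP[n] - RP[n - 1]) <= 0.01 * RP[n]
  if (!saturated)
    warning("curve does not appear saturated; extrapolating the asymptote")
  Cp0 <- RP[n]
  half <- Cp0 / 2
  RT_half <- approx(RP, RT, xout = half, ties = "ordered")$y
  if (is.na(RT_half)) RT_half <- RT[which.min(abs(RP - half))]
  Ct0 <- max(RT_half - half, 1e-9)
  Cp <- Cp0; Ct <- Ct0
  if (refine) {
    fit <- try(nls(RP ~ rp_approx(RT, Cp, Ct),
                   start = list(Cp = Cp0, Ct = Ct0),
                   lower = c(Cp = 1e-12, Ct = 0), algorithm = "port",
                   control = list(warnOnly = TRUE)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) {
      Cp <- coef(fit)[["Cp"]]; Ct <- coef(fit)[["Ct"]]
    }
  }
  pred <- rp_approx(RT, Cp, Ct)
  residual <- max(abs(pred - RP) / pmax(RP, 1e-12 * max(RP)))
  list(Cp = Cp, Ct = Ct, residual = residual, saturated = saturated)
}
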