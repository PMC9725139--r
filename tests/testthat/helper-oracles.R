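# Shared oracles, independent of the implementation paths they check.

# central-difference logarithmic slope d log(fun)/d log(x)
fd_log_gain <- function(fun, x, eps = 1e-6) {
  (log(fun(x * exp(eps))) - log(fun(x * exp(-eps)))) / (2 * eps)
}

# plain bisection root of g on [lo, hi] (g(lo), g(hi) opposite signs)
bisect_root <- function(g, lo, hi, tol = 1e-12, maxit = 200) {
  flo <- g(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# count fixed points of the composed map by a dense sign-change scan,
# independent of steady_states()
count_fixed_points <- function(params, Cp = NULL, n = 1e4) {
  if (!is.null(Cp)) params$Cp <- Cp
  rt <- exp(seq(log(0.5 * params$Rb), log(1.5 * params$f * params$Rb),
                length.out = n))
  g <- composite_map(rt, params)$production - rt
  sum(diff(sign(g)) != 0)
}

# reference parameter set: low fold change, strong decoy competition,
# basal level high enough to reach the bistable window
params_decoy_ref <- function(K = 0.5) {
  tcs_params(f = 5, h = 2, Rb = 2.5, D = 4, K = K, l = 2, Cp = 60, Ct = 3)
}

logspace <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# numeric overall-gain oracle: slope of the composed production map
lg3_at_oracle <- function(RT, params)
  fd_log_gain(function(x) composite_map(x, params)$production, RT)
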