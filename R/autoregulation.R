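#' Transcription module F: production level from free active TF
#'
#' Steady-state production level of the positively autoregulated promoter,
#' \deqn{F(R_f^*) = R_b^* \frac{1 + f {R_f^*}^h}{1 + {R_f^*}^h},}
#' a Hill-type activation ranging from the basal level \eqn{R_b^*} (no
#' active TF) to the fully induced level \eqn{f R_b^*}.
#'
#' @param Rf free active (phosphorylated) TF level, normalized, `>= 0`.
#'   Vectorized.
#' @param f fold change, `>= 1`.
#' @param h promoter binding cooperativity, `> 0`.
#' @param Rb normalized basal level, `> 0`.
#' @return Production level(s), same length as `Rf`.
#' @examples
#' production_F(c(0, 1, Inf), f = 5, h = 2, Rb = 1)
#' @export
production_F <- function(Rf, f, h = 2, Rb = 1) {
  if (any(Rf < 0)) stop("`Rf` must be >= 0")
  x <- Rf^h
  # x = Inf gives f*Rb by the limit
  out <- Rb * (1 + f * x) / (1 + x)
  out[is.infinite(x)] <- Rb * f
  out
}

#' Logarithmic gain of the transcription module
#'
#' \deqn{LG_F = \frac{R_f^*}{F}\frac{dF}{dR_f^*}
#'   = \frac{h (f-1) {R_f^*}^h}{(1 + f {R_f^*}^h)(1 + {R_f^*}^h)}.}
#' Nonnegative, vanishing at both extremes of `Rf`; `lg_F(0)` is defined
#' as 0 by continuous extension so grids that include 0 need no special
#' casing.
#'
#' @inheritParams production_F
#' @return Gain value(s) in `[0, h)`.
#' @seealso [max_lg_F()] for the closed-form maximum.
#' @export
lg_F <- function(Rf, f, h = 2) {
  if (any(Rf < 0)) stop("`Rf` must be >= 0")
  x <- Rf^h
  out <- h * (f - 1) * x / ((1 + f * x) * (1 + x))
  out[x == 0 | is.infinite(x)] <- 0
  out
}

#' Maximum of the transcription-module gain
#'
#' Closed form: \eqn{\max LG_F = h(\sqrt f - 1)/(\sqrt f + 1)}, attained at
#' \eqn{R_f^* = f^{-1/2h}}. With dimeric binding (`h = 2`) the maximum
#' reaches 1 exactly at `f = 9`: below that fold change the autoregulation
#' module alone can never drive bistability, and as `f` grows without
#' bound the maximum approaches 2.
#'
#' @inheritParams production_F
#' @return A list with `value` (the maximal gain) and `argmax` (the `Rf`
#'   where it is attained).
#' @examples
#' max_lg_F(9, 2)$value   # exactly 1
#' @export
max_lg_F <- function(f, h = 2) {
  if (any(f < 1)) stop("`f` must be >= 1")
  if (any(h <= 0)) stop("`h` must be > 0")
  s <- sqrt(f)
  list(value = h * (s - 1) / (s + 1), argmax = f^(-1 / (2 * h)))
}

#' Coupled-negative-feedback parameters
#'
#' Parameters of an additional repressive loop layered on the positive
#' autoregulation. Two mechanisms are supported: `"transcriptional"` (the
#' phosphorylated RR independently binds a repression site in its own
#' promoter, multiplying production by a repressive Hill factor with fold
#' change `f_N <= 1`) and `"capacity"` (the RR activates an inhibitor of
#' its own phosphorylation, reducing the effective phosphorylation
#' capacity Cp* at steady state; this mechanism acts inside the composed
#' map, see [dose_response()]).
#'
#' @param mode `"transcriptional"` or `"capacity"`.
#' @param f_N repression fold change, `0 < f_N <= 1` (transcriptional
#'   mode). `f_N = 1` disables repression.
#' @param K_N normalized repression-site affinity, `> 0`.
#' @param h_N repression-site cooperativity, default 2.
#' @param K_I,h_I Hill parameters of capacity inhibition
#'   (`Cp_eff = Cp / (1 + (Rf/K_I)^h_I)`), capacity mode only.
#' @return An object of class `tcs_nf`.
#' @export
nf_params <- function(mode = c("transcriptional", "capacity"),
                      f_N = 1, K_N = 1, h_N = 2, K_I = 1, h_I = 2) {
  mode <- match.arg(mode)
  if (f_N <= 0 || f_N > 1) stop("`f_N` must be in (0, 1]")
  if (K_N <= 0 || h_N <= 0) stop("`K_N` and `h_N` must be > 0")
  if (K_I <= 0 || h_I <= 0) stop("`K_I` and `h_I` must be > 0")
  structure(list(mode = mode, f_N = f_N, K_N = K_N, h_N = h_N,
                 K_I = K_I, h_I = h_I),
            class = "tcs_nf")
}

# repressive Hill factor of the transcriptional CNF promoter
nf_factor <- function(Rf, nf) {
  x <- (Rf / nf$K_N)^nf$h_N
  out <- (1 + nf$f_N * x) / (1 + x)
  out[is.infinite(x)] <- nf$f_N
  out
}

#' Gain of negative autoregulation and of the coupled promoter
#'
#' With independent activation and repression sites the promoter function
#' factorizes, so the coupled gain is the sum
#' \eqn{LG_C = LG_F + LG_N} with
#' \eqn{LG_N = h_N (f_N - 1) x / [(1 + f_N x)(1 + x)]},
#' \eqn{x = (R_f^*/K_N^*)^{h_N}}. `LG_N <= 0` always, so coupled negative
#' feedback can only lower the overall gain and shrink the bistability
#' range.
#'
#' @inheritParams production_F
#' @param params a [tcs_params()] object.
#' @param nf an [nf_params()] object in `"transcriptional"` mode.
#' @return Gain value(s).
#' @export
coupled_lg_C <- function(Rf, params, nf) {
  stopifnot(inherits(params, "tcs_params"), inherits(nf, "tcs_nf"))
  if (nf$mode != "transcriptional")
    stop("coupled_lg_C is defined for transcriptional-repression mode only; ",
         "capacity inhibition acts inside the composed map (see dose_response)")
  if (any(Rf < 0)) stop("`Rf` must be >= 0")
  lg_F(Rf, params$f, params$h) + lg_N(Rf, nf)
}

#' @rdname coupled_lg_C
#' @export
lg_N <- function(Rf, nf) {
  stopifnot(inherits(nf, "tcs_nf"))
  x <- (Rf / nf$K_N)^nf$h_N
  out <- nf$h_N * (nf$f_N - 1) * x / ((1 + nf$f_N * x) * (1 + x))
  out[x == 0 | is.infinite(x)] <- 0
  out
}
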