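#' Model parameters for an autoregulated TCS circuit
#'
#' Container for the dimensionless (K_auto-normalized) parameters of the
#' three-module model. All concentration-like fields are "starred"
#' quantities, i.e. concentrations divided by the affinity of the
#' autoregulated promoter \eqn{K_{auto}}. Dimensional inputs should be
#' converted once at the boundary with [normalize_params()].
#'
#' @param f transcriptional fold change of the autoregulated promoter
#'   (maximal/basal production ratio), `f >= 1`.
#' @param h binding cooperativity at the autoregulated promoter (Hill
#'   coefficient). Default 2: most bacterial response regulators bind as
#'   dimers.
#' @param Rb normalized basal expression level
#'   \eqn{R_b^* = \alpha/(k_{dil} K_{auto})}, `> 0`.
#' @param D normalized amount of competing (decoy) TFBSs, `>= 0`.
#' @param K relative decoy affinity \eqn{K^* = K/K_{auto}}, `> 0`.
#'   Values below 1 mean the decoys bind the TF more strongly than the
#'   autoregulated promoter does.
#' @param l binding cooperativity of the competing TFBSs (molecules bound
#'   per saturated site). Default 2 (dimer binding).
#' @param Cp normalized phosphorylation capacity \eqn{Cp^*}: the maximal
#'   attainable phosphorylated-RR level, the signal-dependent input.
#' @param Ct normalized half-saturation composite \eqn{Ct^*}. Default 3,
#'   the conventional choice for phase-diagram work at desk scale.
#' @param K_auto optional dimensional promoter affinity (e.g. in uM), kept
#'   for provenance only; the model never uses it after normalization.
#' @param k_dil,alpha optional dimensional dilution rate and lumped
#'   production rate constant, provenance only.
#'
#' @return An object of class `tcs_params` (a named list).
#' @examples
#' p <- tcs_params(f = 5, Rb = 2.5, D = 4, K = 0.5, Cp = 30)
#' p
#' @export
tcs_params <- function(f, h = 2, Rb, D = 0, K = 1, l = 2,
                       Cp = Inf, Ct = 3,
                       K_auto = NA_real_, k_dil = NA_real_,
                       alpha = NA_real_) {
  stopifnot(length(f) == 1, length(h) == 1, length(Rb) == 1,
            length(D) == 1, length(K) == 1, length(l) == 1,
            length(Cp) == 1, length(Ct) == 1)
  if (!is.finite(f) || f < 1)
    stop("`f` must be finite and >= 1 (positive autoregulation)")
  if (h <= 0) stop("`h` must be > 0")
  if (!is.finite(Rb) || Rb <= 0) stop("`Rb` must be finite and > 0")
  if (D < 0) stop("`D` must be >= 0")
  if (K <= 0) stop("`K` must be > 0")
  if (l <= 0) stop("`l` must be > 0")
  if (Cp < 0) stop("`Cp` must be >= 0")
  if (Ct < 0) stop("`Ct` must be >= 0")
  structure(
    list(f = f, h = h, Rb = Rb, D = D, K = K, l = l, Cp = Cp, Ct = Ct,
         K_auto = K_auto, k_dil = k_dil, alpha = alpha),
    class = "tcs_params")
}

#' @export
print.tcs_params <- function(x, ...) {
  cat("TCS model parameters (K_auto-normalized)\n")
  cat(sprintf("  autoregulation : f = %g, h = %g, Rb* = %g\n",
              x$f, x$h, x$Rb))
  cat(sprintf("  DNA binding    : D* = %g, K* = %g, l = %g\n",
              x$D, x$K, x$l))
  cat(sprintf("  phosphorylation: Cp* = %g, Ct* = %g\n", x$Cp, x$Ct))
  if (is.finite(x$K_auto))
    cat(sprintf("  dimensional    : K_auto = %g\n", x$K_auto))
  invisible(x)
}

#' Normalize dimensional parameters by the promoter affinity K_auto
#'
#' Divides every concentration-like entry of `raw` by `K_auto` and builds a
#' [tcs_params()] object. `Rb` is computed as `alpha / (k_dil * K_auto)`
#' when `alpha` and `k_dil` are supplied; otherwise a dimensional `Rb`
#' entry is normalized directly.
#'
#' @param raw named list of dimensional parameters. Concentration-like
#'   entries: `Cp`, `Ct`, `K`, `D`, `Rb` (all in the same units as
#'   `K_auto`). Dimensionless entries passed through: `f`, `h`, `l`.
#'   Rate entries: `alpha` (concentration/time), `k_dil` (1/time).
#' @param K_auto promoter affinity, same concentration units, `> 0`.
#' @return A `tcs_params` object with starred (normalized) fields.
#' @examples
#' normalize_params(list(f = 5, Cp = 4, Ct = 0.8, K = 0.1, Rb = 0.25),
#'                  K_auto = 0.1)
#' @export
normalize_params <- function(raw, K_auto) {
  if (!is.numeric(K_auto) || length(K_auto) != 1 || !is.finite(K_auto) ||
      K_auto <= 0)
    stop("`K_auto` must be a single positive number")
  if (!is.list(raw)) stop("`raw` must be a named list")
  req <- function(name) {
    if (is.null(raw[[name]]))
      stop(sprintf("configuration error: required field `%s` is missing",
                   name))
    raw[[name]]
  }
  conc <- function(name, default = NULL) {
    v <- raw[[name]]
    if (is.null(v)) return(default)
    if (v < 0) stop(sprintf("`%s` must be >= 0", name))
    v / K_auto
  }
  f <- req("f")
  Rb <- if (!is.null(raw$alpha) && !is.null(raw$k_dil)) {
    if (raw$k_dil <= 0) stop("`k_dil` must be > 0")
    raw$alpha / (raw$k_dil * K_auto)
  } else {
    r <- conc("Rb")
    if (is.null(r))
      stop("configuration error: required field `Rb` (or `alpha` + `k_dil`) is missing")
    r
  }
  tcs_params(
    f = f,
    h = if (is.null(raw$h)) 2 else raw$h,
    Rb = Rb,
    D = conc("D", 0),
    K = conc("K", 1),
    l = if (is.null(raw$l)) 2 else raw$l,
    Cp = conc("Cp", Inf),
    Ct = conc("Ct", 3),
    K_auto = K_auto,
    k_dil = if (is.null(raw$k_dil)) NA_real_ else raw$k_dil,
    alpha = if (is.null(raw$alpha)) NA_real_ else raw$alpha)
}

#' Convert between concentration and molecules per cell
#'
#' `molecules_from_concentration()` converts a concentration in micromolar
#' to an (expected, real-valued) molecule count in a cell of the given
#' volume; `concentration_from_molecules()` is the exact inverse. At the
#' default bacterial cell volume of 1e-15 L, 0.1 uM corresponds to about 60
#' molecules.
#'
#' @param conc_uM concentration in micromolar, `>= 0`.
#' @param n molecule count, `>= 0`.
#' @param volume_L cell volume in liters, `> 0`. Default `1e-15`.
#' @return A numeric vector (molecules, or uM for the inverse).
#' @examples
#' molecules_from_concentration(0.1)   # ~60
#' concentration_from_molecules(60.22) # ~0.1
#' @export
molecules_from_concentration <- function(conc_uM, volume_L = 1e-15) {
  if (any(conc_uM < 0)) stop("`conc_uM` must be >= 0")
  if (any(volume_L <= 0)) stop("`volume_L` must be > 0")
  conc_uM * 1e-6 * volume_L * .avogadro
}

#' @rdname molecules_from_concentration
#' @export
concentration_from_molecules <- function(n, volume_L = 1e-15) {
  if (any(n < 0)) stop("`n` must be >= 0")
  if (any(volume_L <= 0)) stop("`volume_L` must be > 0")
  n / (1e-6 * volume_L * .avogadro)
}

.avogadro <- 6.02214076e23
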