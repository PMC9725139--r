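#' @title Composed circuit map and overall gain
#' @name composition
#' @description Internal plumbing that chains the three modules:
#' activation `A` (total RR -> phosphorylated RR), binding `B`
#' (phosphorylated -> free) and transcription `F` (free -> production).
NULL

.logspace <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))

# set a named scalar field on a tcs_params object (phase-diagram axes)
set_param <- function(params, name, value) {
  ok <- c("f", "h", "Rb", "D", "K", "l", "Cp", "Ct")
  if (!name %in% ok)
    stop(sprintf("unknown parameter `%s`; must be one of %s",
                 name, paste(ok, collapse = ", ")))
  params[[name]] <- value
  params
}

#' Evaluate the composed map F(B(A(RT)))
#'
#' For each total RR level, computes the phosphorylated level `RP`, the
#' free level `Rf` and the production level of the autoregulated promoter.
#' With a capacity-inhibition negative feedback the effective capacity
#' depends on `Rf` itself, so a self-consistent inner fixed point is
#' solved: `Rf` such that `forward_RP(Rf) = rp_approx(RT, Cp_eff(Rf), Ct)`
#' (the left side is increasing and the right side nonincreasing in `Rf`,
#' so the root is unique).
#'
#' @param RT total RR level(s), `>= 0`.
#' @param params a [tcs_params()] object.
#' @param nf optional [nf_params()] object.
#' @param Cp optional override of `params$Cp` (signal sweeps).
#' @return A data.frame with columns `RT`, `RP`, `Rf`, `production`.
#' @export
composite_map <- function(RT, params, nf = NULL, Cp = NULL) {
  stopifnot(inherits(params, "tcs_params"))
  if (!is.null(Cp)) params$Cp <- Cp
  capacity_nf <- !is.null(nf) && nf$mode == "capacity"
  if (capacity_nf) {
    Rf <- vapply(RT, function(rt) .rf_capacity_nf(rt, params, nf),
                 numeric(1))
    RP <- forward_RP(Rf, params$D, params$K, params$l)
  } else {
    RP <- rp_approx(RT, params$Cp, params$Ct)
    Rf <- solve_Rf(RP, params$D, params$K, params$l)
  }
  production <- production_F(Rf, params$f, params$h, params$Rb)
  if (!is.null(nf) && nf$mode == "transcriptional")
    production <- production * nf_factor(Rf, nf)
  data.frame(RT = RT, RP = RP, Rf = Rf, production = production)
}

# inner fixed point for capacity-inhibition CNF
.rf_capacity_nf <- function(RT, params, nf) {
  if (RT == 0) return(0)
  psi <- function(rf) {
    cp_eff <- params$Cp / (1 + (rf / nf$K_I)^nf$h_I)
    forward_RP(rf, params$D, params$K, params$l) -
      rp_approx(RT, cp_eff, params$Ct)
  }
  # psi(0) <= 0 and psi(RT) >= 0; psi is increasing
  uniroot(psi, c(0, RT), tol = 1e-12 * max(1, RT), maxiter = 200)$root
}

# scalar overall gain at one RT (grid-free; used by profiles and phase
# diagrams). lg_A_one = TRUE drops the activation module (LG_A = 1,
# RP = RT), the combined autoregulation + binding analysis.
lg3_at <- function(RT, params, lg_A_one = FALSE, nf = NULL) {
  if (!is.null(nf) && nf$mode == "capacity")
    return(.lg3_numeric(RT, params, nf))
  RP <- if (lg_A_one) RT else rp_approx(RT, params$Cp, params$Ct)
  Rf <- solve_Rf(RP, params$D, params$K, params$l)
  la <- if (lg_A_one || is.infinite(params$Cp)) 1
        else lg_A(RT, params$Cp, params$Ct)
  lb <- as.numeric(lg_B(Rf, params$D, params$K, params$l))
  lf <- if (!is.null(nf)) coupled_lg_C(Rf, params, nf)
        else lg_F(Rf, params$f, params$h)
  la * lb * lf
}

# numeric overall gain: central difference of log production vs log RT
.lg3_numeric <- function(RT, params, nf, eps = 1e-6) {
  p <- function(rt) composite_map(rt, params, nf = nf)$production
  (log(p(RT * exp(eps))) - log(p(RT * exp(-eps)))) / (2 * eps)
}

#' Overall logarithmic-gain profile over a grid of total RR levels
#'
#' Per grid point: `RP` from the activation module, `Rf` from the binding
#' module, the three module gains and their product
#' `LG3 = LG_A * LG_B * LG_F`. The profile maximum is located on the grid
#' and refined by golden-section search between the neighboring grid
#' points.
#'
#' @param params a [tcs_params()] object.
#' @param RT_grid ascending positive grid of total RR levels. Default 200
#'   log-spaced points on `[0.1, 100]`, the physiological RR range.
#' @param lg_A_one drop the activation module (`LG_A = 1`, `RP = RT`);
#'   gives the combined autoregulation + binding gain.
#' @param nf optional transcriptional [nf_params()]; its gain contribution
#'   is folded into the `LG_F` column (coupled gain `LG_C`).
#' @return An object of class `tcs_lg_profile`: a data.frame with columns
#'   `RT`, `RP`, `Rf`, `LG_A`, `LG_B`, `LG_F`, `LG3`, plus attributes
#'   `max_LG3` and `argmax_RT`.
#' @examples
#' pr <- lg3_profile(tcs_params(f = 25, Rb = 1, D = 1, K = 1/3, Cp = 20))
#' attr(pr, "max_LG3")
#' @export
lg3_profile <- function(params, RT_grid = .logspace(0.1, 100, 200),
                        lg_A_one = FALSE, nf = NULL) {
  stopifnot(inherits(params, "tcs_params"))
  if (any(diff(RT_grid) <= 0) || any(RT_grid <= 0))
    stop("`RT_grid` must be ascending and positive")
  if (!is.null(nf) && nf$mode != "transcriptional")
    stop("lg3_profile supports transcriptional CNF only; use dose_response ",
         "for capacity inhibition")
  RP <- if (lg_A_one) RT_grid else rp_approx(RT_grid, params$Cp, params$Ct)
  Rf <- solve_Rf(RP, params$D, params$K, params$l)
  la <- if (lg_A_one || is.infinite(params$Cp)) rep(1, length(RT_grid))
        else lg_A(RT_grid, params$Cp, params$Ct)
  lb <- as.numeric(lg_B(pmax(Rf, .Machine$double.xmin), params$D,
                        params$K, params$l))
  lf <- if (!is.null(nf)) coupled_lg_C(Rf, params, nf)
        else lg_F(Rf, params$f, params$h)
  lg3 <- la * lb * lf
  out <- data.frame(RT = RT_grid, RP = RP, Rf = Rf,
                    LG_A = la, LG_B = lb, LG_F = lf, LG3 = lg3)
  i <- which.max(lg3)
  lo <- RT_grid[max(1, i - 1)]; hi <- RT_grid[min(length(RT_grid), i + 1)]
  opt <- optimize(function(lrt) lg3_at(exp(lrt), params, lg_A_one, nf),
                  c(log(lo), log(hi)), maximum = TRUE, tol = 1e-8)
  structure(out, class = c("tcs_lg_profile", "data.frame"),
            max_LG3 = max(opt$objective, lg3[i]),
            argmax_RT = if (opt$objective >= lg3[i]) exp(opt$maximum)
                        else RT_grid[i])
}

#' Steady states of the closed circuit
#'
#' Fixed points of the dimensionless dynamics
#' \eqn{dR_T^*/d\tau = F(B(A(R_T^*))) - R_T^*} (time in units of
#' \eqn{1/k_{dil}}). Roots of `G(RT) = production - RT` are located by a
#' dense sign-change scan over log-spaced points spanning the production
#' image `[Rb*, f Rb*]` (with margin) and refined by Brent's method. For a
#' one-dimensional flow a fixed point is stable iff `G'(RT) < 0`, which at
#' a fixed point is equivalent to `LG3 < 1`; near-zero derivatives
#' (`|G'| < 1e-8`) are labeled `"degenerate"`.
#'
#' @inheritParams composite_map
#' @param n_scan number of scan points (default 2000; doubled once
#'   automatically if an even number of crossings is found).
#' @param interval optional scan interval; default
#'   `[0.9 f_N Rb, 1.1 f Rb]`.
#' @return An object of class `tcs_steady_states`: a data.frame with one
#'   row per fixed point, columns `RT`, `RP`, `Rf`, `production`, `LG3`,
#'   `stability` (`"stable"`, `"unstable"` or `"degenerate"`), ordered by
#'   `RT`.
#' @examples
#' p <- tcs_params(f = 5, Rb = 2.5, D = 4, K = 0.5, Cp = 30, Ct = 3)
#' steady_states(p)
#' @export
steady_states <- function(params, Cp = NULL, nf = NULL,
                          n_scan = 2000, interval = NULL) {
  stopifnot(inherits(params, "tcs_params"))
  if (!is.null(Cp)) params$Cp <- Cp
  if (is.null(interval)) {
    f_lo <- if (!is.null(nf) && nf$mode == "transcriptional") nf$f_N else 1
    interval <- c(0.9 * params$Rb * f_lo, 1.1 * params$f * params$Rb)
  }
  G <- function(rt) composite_map(rt, params, nf = nf)$production - rt
  roots <- .scan_roots(G, interval, n_scan)
  if (length(roots) %% 2 == 0) {
    roots <- .scan_roots(G, interval, 4 * n_scan)
    if (length(roots) %% 2 == 0)
      warning("even number of fixed-point crossings after refinement; ",
              "roots may be merged at scan resolution")
  }
  st <- composite_map(roots, params, nf = nf)
  eps <- 1e-6
  gprime <- vapply(roots, function(r)
    (G(r * (1 + eps)) - G(r * (1 - eps))) / (2 * r * eps), numeric(1))
  stability <- ifelse(abs(gprime) < 1e-8, "degenerate",
                      ifelse(gprime < 0, "stable", "unstable"))
  lg3 <- vapply(roots, function(r) lg3_at(r, params, nf = nf), numeric(1))
  out <- data.frame(RT = st$RT, RP = st$RP, Rf = st$Rf,
                    production = st$production, LG3 = lg3,
                    stability = stability)
  structure(out[order(out$RT), , drop = FALSE],
            class = c("tcs_steady_states", "data.frame"),
            interval = interval)
}

# dense log-spaced sign-change scan + Brent refinement
.scan_roots <- function(G, interval, n) {
  x <- .logspace(interval[1], interval[2], n)
  gx <- vapply(x, G, numeric(1))
  roots <- x[gx == 0]
  idx <- which(gx[-1] * gx[-n] < 0)
  for (i in idx) {
    r <- uniroot(G, c(x[i], x[i + 1]), tol = 1e-12 * max(1, x[i]),
                 maxiter = 200)
    roots <- c(roots, r$root)
  }
  sort(unique(roots))
}

#' Forward time integration of the closed circuit
#'
#' Integrates \eqn{dR_T^*/d\tau = F(B(A(R_T^*))) - R_T^*} (dimensionless
#' time, units of \eqn{1/k_{dil}}) with classical RK4. Used to verify
#' stability labels dynamically and to illustrate hysteresis.
#'
#' @inheritParams composite_map
#' @param RT0 initial total RR level.
#' @param tau_end integration horizon, default 50 dilution times.
#' @param dt time step, default 0.01.
#' @return A data.frame with columns `tau` and `RT`.
#' @export
simulate_rt <- function(RT0, params, nf = NULL, tau_end = 50, dt = 0.01) {
  G <- function(rt) composite_map(rt, params, nf = nf)$production - rt
  n <- ceiling(tau_end / dt)
  rt <- numeric(n + 1); rt[1] <- RT0
  for (i in seq_len(n)) {
    y <- rt[i]
    k1 <- G(y); k2 <- G(max(y + dt * k1 / 2, 0))
    k3 <- G(max(y + dt * k2 / 2, 0)); k4 <- G(max(y + dt * k3, 0))
    rt[i + 1] <- max(y + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6, 0)
  }
  data.frame(tau = seq(0, by = dt, length.out = n + 1), RT = rt)
}

#' Dose-response over the phosphorylation capacity
#'
#' Sweeps the signal-dependent input `Cp*` and collects all steady states
#' per value, giving the signal-response (and bifurcation) diagram. The
#' bistable interval is the `Cp*` range carrying three fixed points (two
#' stable, one unstable); its saddle-node edges are refined by bisection
#' between neighboring grid values to `1e-4` relative. Transcriptional
#' response is reported as occupancy of a reporter promoter.
#'
#' @inheritParams steady_states
#' @param Cp_grid ascending grid of capacity values.
#' @param K_rep,h_rep reporter promoter affinity and cooperativity for the
#'   occupancy output, see [promoter_occupancy()].
#' @return An object of class `tcs_bifurcation`: list with `states` (a
#'   data.frame with columns `Cp`, `RT`, `RP`, `Rf`, `production`, `LG3`,
#'   `occupancy`, `stability`), `bistable_interval` (length-2 numeric or
#'   `NULL`), `saddle_nodes` (refined fold locations) and `params`.
#' @export
dose_response <- function(params, Cp_grid, nf = NULL,
                          K_rep = 1, h_rep = 2, n_scan = 2000) {
  stopifnot(inherits(params, "tcs_params"))
  if (any(diff(Cp_grid) <= 0)) stop("`Cp_grid` must be ascending")
  res <- lapply(Cp_grid, function(cp) {
    ss <- steady_states(params, Cp = cp, nf = nf, n_scan = n_scan)
    cbind(Cp = cp, as.data.frame(ss))
  })
  states <- do.call(rbind, res)
  states$occupancy <- promoter_occupancy(states$Rf, K_rep, h_rep)
  counts <- vapply(res, nrow, integer(1))
  bist <- which(counts >= 3)
  interval <- NULL; folds <- numeric(0)
  if (length(bist)) {
    count_at <- function(cp)
      nrow(steady_states(params, Cp = cp, nf = nf, n_scan = n_scan))
    lo <- Cp_grid[min(bist)]; hi <- Cp_grid[max(bist)]
    if (min(bist) > 1)
      lo <- .bisect_fold(count_at, Cp_grid[min(bist) - 1], lo)
    if (max(bist) < length(Cp_grid))
      hi <- .bisect_fold(count_at, Cp_grid[max(bist) + 1], hi)
    interval <- c(lo, hi)
    folds <- interval
  }
  structure(list(states = states, bistable_interval = interval,
                 saddle_nodes = folds, params = params, nf = nf),
            class = "tcs_bifurcation")
}

# bisect the Cp where the state count changes; `inside` has >= 3 states
.bisect_fold <- function(count_at, outside, inside, rel_tol = 1e-4) {
  while (abs(inside - outside) > rel_tol * max(abs(inside), 1)) {
    mid <- sqrt(inside * outside)
    if (count_at(mid) >= 3) inside <- mid else outside <- mid
  }
  inside
}

#' @export
print.tcs_bifurcation <- function(x, ...) {
  ncp <- length(unique(x$states$Cp))
  cat(sprintf("Dose-response sweep over %d Cp* values\n", ncp))
  if (is.null(x$bistable_interval)) {
    cat("  monostable throughout\n")
  } else {
    cat(sprintf("  bistable for Cp* in [%.4g, %.4g]\n",
                x$bistable_interval[1], x$bistable_interval[2]))
  }
  invisible(x)
}

#' Mono-/bistability phase diagram
#'
#' Evaluates the overall gain over a two-parameter grid. In `"max"` mode
#' each cell reports `max_RT LG3` (maximized over a log-spaced `RT` grid
#' with golden-section refinement around the grid argmax); cells with
#' value below 1 are certainly monostable (gain above 1 is only a
#' necessary condition for bistability). In `"pointwise"` mode one axis
#' must be named `"RT"` and the cell value is `LG3` at that `RT`. The
#' `value = 1` contour separating the regions is extracted with
#' [grDevices::contourLines()].
#'
#' @inheritParams lg3_profile
#' @param axis1,axis2 lists `list(name = , values = )`; `name` is a
#'   [tcs_params()] field (or `"RT"` in pointwise mode) and `values` an
#'   ascending grid.
#' @param mode `"max"` (maximize over `RT`) or `"pointwise"`.
#' @param RT_grid the inner maximization grid for `"max"` mode.
#' @return An object of class `tcs_phase_diagram`: list with `value` (a
#'   matrix, rows = axis1), `axis1`, `axis2`, `contour` (list of
#'   level-1 polylines with `x`, `y`), `ratio` (the TF/TFBS ratio `RT/D`
#'   matrix when both quantities are resolvable, else `NULL`), and `mode`.
#' @export
phase_diagram <- function(params, axis1, axis2,
                          mode = c("max", "pointwise"),
                          RT_grid = .logspace(0.1, 100, 60),
                          lg_A_one = FALSE, nf = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "tcs_params"))
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || is.null(ax$name) || is.null(ax$values))
      stop("configuration error: axes must be list(name =, values =)")
    if (length(ax$values) < 2 || any(diff(ax$values) <= 0) ||
        any(ax$values <= 0))
      stop("configuration error: axis grids must be ascending, positive, ",
           "length >= 2")
  }
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  value <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      p <- params
      rt_point <- NULL
      if (axis1$name == "RT") rt_point <- axis1$values[i]
      else p <- set_param(p, axis1$name, axis1$values[i])
      if (axis2$name == "RT") rt_point <- axis2$values[j]
      else p <- set_param(p, axis2$name, axis2$values[j])
      value[i, j] <- if (mode == "pointwise") {
        if (is.null(rt_point))
          stop("pointwise mode requires one axis named \"RT\"")
        lg3_at(rt_point, p, lg_A_one, nf)
      } else {
        .max_lg3(p, RT_grid, lg_A_one, nf)
      }
    }
  }
  contour <- contourLines(x = axis1$values, y = axis2$values, z = value,
                          levels = 1)
  ratio <- NULL
  if (mode == "pointwise" &&
      any(c(axis1$name, axis2$name) == "RT") &&
      any(c(axis1$name, axis2$name) == "D")) {
    rt_m <- if (axis1$name == "RT")
      matrix(axis1$values, n1, n2) else matrix(axis2$values, n1, n2, byrow = TRUE)
    d_m <- if (axis1$name == "D")
      matrix(axis1$values, n1, n2) else matrix(axis2$values, n1, n2, byrow = TRUE)
    ratio <- rt_m / d_m
  }
  structure(list(value = value, axis1 = axis1, axis2 = axis2,
                 contour = contour, ratio = ratio, mode = mode,
                 lg_A_one = lg_A_one),
            class = "tcs_phase_diagram")
}

# max of LG3 over an RT grid with local golden-section refinement
.max_lg3 <- function(params, RT_grid, lg_A_one = FALSE, nf = NULL) {
  v <- vapply(RT_grid, function(rt) lg3_at(rt, params, lg_A_one, nf),
              numeric(1))
  i <- which.max(v)
  lo <- RT_grid[max(1, i - 1)]; hi <- RT_grid[min(length(RT_grid), i + 1)]
  opt <- optimize(function(lrt) lg3_at(exp(lrt), params, lg_A_one, nf),
                  c(log(lo), log(hi)), maximum = TRUE, tol = 1e-8)
  max(v[i], opt$objective)
}

#' @export
print.tcs_phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram (%s mode): %s x %s, %d x %d cells\n",
              x$mode, x$axis1$name, x$axis2$name,
              nrow(x$value), ncol(x$value)))
  cat(sprintf("  value range [%.3g, %.3g]; %d contour segment(s) at 1\n",
              min(x$value), max(x$value), length(x$contour)))
  invisible(x)
}
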