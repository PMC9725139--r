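#' Deterministic synthetic binding-site generator
#'
#' Emits `n` aligned sites derived from a consensus by independent
#' per-position substitution: with probability `mutation_prob` a position
#' is replaced by one of the three other bases, uniformly. The true
#' per-position frequency model implied by this process
#' (`1 - mutation_prob` for the consensus base, `mutation_prob/3` for
#' each other base) is returned alongside so information-content code can
#' be checked against known ground truth. The generator is a pure
#' function of its arguments: the global RNG state is saved and restored.
#'
#' @param consensus ACGT string.
#' @param n number of sites, `>= 1`.
#' @param mutation_prob per-position substitution probability, in
#'   `[0, 0.75)` (0.75 is the uniform-random limit).
#' @param seed integer seed.
#' @return A list with `sites` (character vector, named `site_1`...),
#'   `true_freq` (4 x L matrix) and the generating arguments.
#' @export
generate_pwm_sites <- function(consensus, n, mutation_prob, seed) {
  consensus <- toupper(consensus)
  bases <- c("A", "C", "G", "T")
  cvec <- strsplit(consensus, "")[[1]]
  if (!length(cvec) || !all(cvec %in% bases))
    stop("`consensus` must be a nonempty ACGT string")
  if (mutation_prob < 0 || mutation_prob >= 0.75)
    stop("`mutation_prob` must be in [0, 0.75)")
  L <- length(cvec)
  sites <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- cvec
      mut <- runif(L) < mutation_prob
      if (any(mut))
        s[mut] <- vapply(s[mut], function(b)
          sample(setdiff(bases, b), 1), character(1))
      paste(s, collapse = "")
    }, character(1))
  })
  names(sites) <- paste0("site_", seq_len(n))
  true_freq <- vapply(cvec, function(b) {
    p <- rep(mutation_prob / 3, 4); p[match(b, bases)] <- 1 - mutation_prob
    p
  }, numeric(4))
  rownames(true_freq) <- bases
  list(sites = sites, true_freq = true_freq, consensus = consensus,
       n = n, mutation_prob = mutation_prob, seed = seed)
}

#' Synthetic ChIP peak table with a spiked autoregulated peak
#'
#' Draws `n_peaks` lognormal SNR values and forces the single
#' `"positive"`-role (autoregulated-promoter) peak to sit at the stated
#' quantile of the drawn distribution, so downstream ranking code can be
#' validated against known ground truth.
#'
#' @param n_peaks number of peaks, `>= 3`.
#' @param lognormal_mu,lognormal_sigma meanlog and sdlog of the SNR draw.
#' @param spike_quantile quantile in `[0, 1]` at which the autoregulated
#'   peak is placed.
#' @param seed integer seed.
#' @param tf TF name used in the table.
#' @return A data.frame (`tf`, `peak_id`, `snr`, `role`) with
#'   `attr(, "spike_quantile")` recording the ground truth.
#' @export
generate_peak_table <- function(n_peaks, lognormal_mu = 1,
                                lognormal_sigma = 1, spike_quantile = 0.9,
                                seed = 1, tf = "tfA") {
  if (n_peaks < 3) stop("`n_peaks` must be >= 3")
  if (spike_quantile < 0 || spike_quantile > 1)
    stop("`spike_quantile` must be in [0, 1]")
  snr <- with_seed(seed, rlnorm(n_peaks, lognormal_mu, lognormal_sigma))
  snr[1] <- quantile(snr[-1], spike_quantile, names = FALSE, type = 7)
  out <- data.frame(
    tf = tf,
    peak_id = sprintf("peak_%03d", seq_len(n_peaks)),
    snr = snr,
    role = c("positive", rep("none", n_peaks - 1)))
  attr(out, "spike_quantile") <- spike_quantile
  out
}

#' Synthetic TF abundance / TFBS count table
#'
#' Lognormal abundances and TFBS counts calibrated so that a target
#' fraction of TFs falls below a given TF/TFBS ratio threshold: a
#' `frac_low` share of rows is drawn with ratios below `ratio_threshold`
#' and the rest above it.
#'
#' @param n_tf number of TFs.
#' @param frac_low fraction of TFs with ratio below `ratio_threshold`.
#' @param ratio_threshold ratio cut separating the two groups. Default 2.
#' @param seed integer seed.
#' @return A data.frame (`tf`, `abundance`, `tfbs_count`).
#' @export
generate_abundance_table <- function(n_tf, frac_low = 0.2,
                                     ratio_threshold = 2, seed = 1) {
  if (n_tf < 1) stop("`n_tf` must be >= 1")
  if (frac_low < 0 || frac_low > 1) stop("`frac_low` must be in [0, 1]")
  with_seed(seed, {
    n_low <- round(frac_low * n_tf)
    ratio <- c(ratio_threshold * exp(-runif(n_low, 0.05, 2)),
               ratio_threshold * exp(runif(n_tf - n_low, 0.05, 3)))
    tfbs <- pmax(1, round(rlnorm(n_tf, log(20), 0.8)))
    data.frame(tf = sprintf("tf_%03d", seq_len(n_tf)),
               abundance = ratio * tfbs,
               tfbs_count = tfbs)
  })
}

#' Parameter-set grid generator
#'
#' Emits deterministic parameter sets spanning stated ranges, either as a
#' full factorial log-spaced grid or by Latin-hypercube sampling (one
#' stratified draw per dimension, permuted; log scale for positive
#' ranges). LHS rows are distinct by construction.
#'
#' @param ranges named list of length-2 numeric ranges (fields of
#'   [tcs_params()]); a length-1 entry pins the value.
#' @param n number of sets (LHS) or points per axis (grid).
#' @param method `"lhs"` or `"grid"`.
#' @param seed integer seed (LHS only).
#' @return A data.frame with one column per field and `n` (or `n^k`) rows.
#' @export
generate_param_grid <- function(ranges, n, method = c("lhs", "grid"),
                                seed = 1) {
  method <- match.arg(method)
  if (!length(ranges) || is.null(names(ranges)))
    stop("`ranges` must be a named list")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!length(r) %in% 1:2 || any(!is.finite(r)))
      stop(sprintf("configuration error: range `%s` must be 1 or 2 finite numbers", nm))
    if (length(r) == 2 && r[1] > r[2])
      stop(sprintf("configuration error: inverted range for `%s`", nm))
  }
  span <- function(r, u) {
    if (length(r) == 1 || r[1] == r[2]) return(rep(r[1], length(u)))
    if (r[1] > 0) exp(log(r[1]) + u * (log(r[2]) - log(r[1])))
    else r[1] + u * (r[2] - r[1])
  }
  if (method == "grid") {
    axes <- lapply(ranges, function(r)
      unique(span(r, seq(0, 1, length.out = n))))
    out <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  } else {
    us <- with_seed(seed, lapply(ranges, function(r)
      (sample(n) - runif(n)) / n))
    out <- as.data.frame(mapply(span, ranges, us, SIMPLIFY = FALSE))
  }
  out
}

# evaluate `expr` under a private RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
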