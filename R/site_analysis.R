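#' Build a position frequency matrix from aligned binding sites
#'
#' Counts bases per position over a set of pre-aligned, equal-length
#' sites (ACGT only; ambiguity codes are rejected), applies an optional
#' pseudocount, and computes the small-sample information correction
#' \eqn{e(n) \approx 3 / (2 \ln 2\, n)} bits per position (the standard
#' first-order correction for a 4-letter alphabet estimated from `n`
#' sequences). Sites are taken as given on a single strand — curated TFBS
#' sets are already oriented.
#'
#' @param sites character vector of aligned sequences, or a
#'   `Biostrings::DNAStringSet`. At least 2 sequences of equal length.
#' @param pseudocount added to every base count per position before
#'   normalization. Default: 0.5 when `n < 50`, else 0.
#' @param correction logical; apply the small-sample correction `e(n)` in
#'   information scores (default `TRUE`).
#' @return An object of class `tcs_pwm`: list with `freq` (4 x L matrix,
#'   rows ACGT), `counts`, `n`, `e_n`, `pseudocount`, `consensus`.
#' @examples
#' pwm <- build_pwm(c("ACGT", "ACGA", "ACGT"), pseudocount = 0)
#' pwm$consensus
#' @export
build_pwm <- function(sites, pseudocount = NULL, correction = TRUE) {
  sites <- as.character(sites)
  if (length(sites) < 2) stop("need at least 2 aligned sites")
  L <- unique(nchar(sites))
  if (length(L) != 1)
    stop("alignment error: sequences have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  if (!all(mat %in% c("A", "C", "G", "T")))
    stop("sequences must contain only A, C, G, T (no ambiguity codes)")
  n <- length(sites)
  if (is.null(pseudocount)) pseudocount <- if (n < 50) 0.5 else 0
  counts <- vapply(seq_len(L), function(l)
    tabulate(factor(mat[, l], levels = c("A", "C", "G", "T")), 4),
    numeric(4))
  rownames(counts) <- c("A", "C", "G", "T")
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  e_n <- if (correction) 3 / (2 * log(2) * n) else 0
  consensus <- paste(rownames(freq)[apply(freq, 2, which.max)],
                     collapse = "")
  structure(list(freq = freq, counts = counts, n = n, e_n = e_n,
                 pseudocount = pseudocount, consensus = consensus),
            class = "tcs_pwm")
}

#' @export
print.tcs_pwm <- function(x, ...) {
  cat(sprintf(
    "Position frequency matrix: %d sites x %d positions (pseudocount %g, e(n) = %.4f bits)\n",
    x$n, ncol(x$freq), x$pseudocount, x$e_n))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Individual information content of a binding site
#'
#' Per-site bit score against a frequency matrix:
#' \deqn{R_i = \sum_l \left[2 - e(n) + \log_2 f(b_l, l)\right],}
#' the sum over positions of the sequence's log-frequency surprisal
#' relative to a uniform background, with the small-sample correction
#' `e(n)` applied per position. Higher `R_i` means closer match to the
#' aligned-site model and (empirically) stronger binding. A zero
#' frequency under zero pseudocount yields `-Inf`, returned with a
#' warning and `attr(, "undefined") = TRUE` rather than being dropped.
#'
#' @param pwm a [build_pwm()] object.
#' @param site a single sequence (character) of the matrix's width.
#' @return `R_i` in bits (scalar).
#' @export
individual_information <- function(pwm, site) {
  stopifnot(inherits(pwm, "tcs_pwm"))
  site <- toupper(as.character(site))
  L <- ncol(pwm$freq)
  if (nchar(site) != L)
    stop(sprintf("site length %d does not match matrix width %d",
                 nchar(site), L))
  b <- strsplit(site, "")[[1]]
  if (!all(b %in% rownames(pwm$freq)))
    stop("site must contain only A, C, G, T")
  f <- pwm$freq[cbind(match(b, rownames(pwm$freq)), seq_len(L))]
  ri <- sum(2 - pwm$e_n + log2(f))
  if (is.infinite(ri)) {
    warning("site hits a zero-frequency base; R_i is -Inf")
    attr(ri, "undefined") <- TRUE
  }
  ri
}

#' @rdname individual_information
#' @param sites character vector of sequences.
#' @return `ri_all()`: named numeric vector of per-site scores.
#' @export
ri_all <- function(pwm, sites) {
  vapply(as.character(sites),
         function(s) as.numeric(individual_information(pwm, s)),
         numeric(1))
}

#' Relative ChIP peak strength (delta log10 SNR)
#'
#' Per TF, subtracts the median log10 peak intensity from each peak's
#' log10 intensity, so the median of the resulting `delta_log10_snr` is 0
#' by construction and peak strengths are comparable across TFs. Rows
#' with nonpositive SNR are rejected (with a message reporting the
#' count); TFs with fewer than 3 surviving peaks are flagged `low_n`. The
#' percentile of each peak within its TF is reported as the mid-rank
#' fraction (ties averaged).
#'
#' @param peaks a data.frame with columns `tf`, `peak_id`, `snr` and
#'   optionally `role` (one of `"positive"`, `"negative"`, `"unknown"`,
#'   `"none"`; the autoregulated-promoter peak carries a non-`"none"`
#'   role).
#' @return The input with added columns `delta_log10_snr`, `percentile`,
#'   `low_n`; rejected rows are dropped and counted in
#'   `attr(, "n_rejected")`.
#' @examples
#' pk <- data.frame(tf = "tfA", peak_id = 1:3, snr = c(10, 100, 1000))
#' delta_log_snr(pk)$delta_log10_snr  # -1, 0, 1
#' @export
delta_log_snr <- function(peaks) {
  need <- c("tf", "peak_id", "snr")
  if (!all(need %in% names(peaks)))
    stop("`peaks` must have columns tf, peak_id, snr")
  bad <- !is.finite(peaks$snr) | peaks$snr <= 0
  if (any(bad))
    message(sum(bad), " peak(s) rejected: nonpositive or missing SNR")
  peaks <- peaks[!bad, , drop = FALSE]
  if (!nrow(peaks)) stop("no peaks with positive SNR")
  out <- do.call(rbind, lapply(split(peaks, peaks$tf), function(d) {
    lg <- log10(d$snr)
    d$delta_log10_snr <- lg - median(lg)
    n <- nrow(d)
    # mid-rank fraction: strictly-smaller count plus half the ties
    d$percentile <- vapply(d$delta_log10_snr, function(x)
      (sum(d$delta_log10_snr < x) + 0.5 * sum(d$delta_log10_snr == x)) / n,
      numeric(1))
    d$low_n <- n < 3
    d
  }))
  rownames(out) <- NULL
  structure(out, n_rejected = sum(bad))
}

#' TF abundance to TFBS count ratios
#'
#' Per TF, the ratio of protein abundance to the number of its binding
#' sites; a ratio below 2 means too few molecules to occupy every site
#' even at full induction (2:1 dimer binding), and a ratio below 4 is far
#' from great excess. Reports a histogram over log2-spaced bins, the
#' cumulative fraction of TFs below each bin edge, the median ratio and
#' the fractions below 2 and below 4.
#'
#' @param tab data.frame with columns `tf`, `abundance` (`>= 0`) and
#'   `tfbs_count` (`>= 1`; zero-count rows are rejected and counted).
#' @param breaks histogram bin edges on the ratio scale; default
#'   log2-spaced covering the data.
#' @return A list with `ratios` (named vector), `breaks`, `counts`,
#'   `cumulative` (fraction of TFs with ratio below each right edge),
#'   `median`, `frac_below_2`, `frac_below_4`, `n_rejected`.
#' @export
tf_tfbs_ratios <- function(tab, breaks = NULL) {
  need <- c("tf", "abundance", "tfbs_count")
  if (!all(need %in% names(tab)))
    stop("`tab` must have columns tf, abundance, tfbs_count")
  if (any(tab$abundance < 0)) stop("`abundance` must be >= 0")
  bad <- tab$tfbs_count < 1 | !is.finite(tab$tfbs_count)
  if (any(bad))
    message(sum(bad), " row(s) rejected: zero or missing TFBS count")
  tab <- tab[!bad, , drop = FALSE]
  ratios <- setNames(tab$abundance / tab$tfbs_count, tab$tf)
  if (is.null(breaks)) {
    lo <- floor(log2(max(min(ratios), 2^-10)))
    hi <- ceiling(log2(max(ratios, 1)))
    breaks <- 2^seq(lo, hi + 1)
  }
  counts <- as.numeric(table(cut(ratios, breaks, include.lowest = TRUE,
                                 right = FALSE)))
  cumulative <- vapply(breaks[-1], function(b) mean(ratios < b), numeric(1))
  list(ratios = ratios, breaks = breaks, counts = counts,
       cumulative = cumulative, median = median(ratios),
       frac_below_2 = mean(ratios < 2), frac_below_4 = mean(ratios < 4),
       n_rejected = sum(bad))
}

#' Decoy binding-site count from plasmid copy-number arithmetic
#'
#' Decoy TFBSs introduced on a multicopy plasmid: the effective copy
#' number is a relative signal (e.g. relative reporter fluorescence or
#' DNA amount) times the reference copy number, rounded to the nearest
#' integer; the decoy count multiplies it by the sites carried per
#' plasmid.
#'
#' @param relative_signal fraction in `(0, 1]`; values above 1 trigger a
#'   warning and are clipped only when `clip = TRUE`.
#' @param base_copy_number reference plasmid copy number, `>= 0`.
#' @param sites_per_plasmid binding sites per plasmid, `>= 0`.
#' @param clip clip `relative_signal` at 1 (default `FALSE`).
#' @return A list with `copy_number` (integer) and `decoy_count`.
#' @examples
#' decoy_site_count(0.62, 96, 1)  # copy number 60
#' @export
decoy_site_count <- function(relative_signal, base_copy_number,
                             sites_per_plasmid, clip = FALSE) {
  if (relative_signal <= 0) stop("`relative_signal` must be > 0")
  if (base_copy_number < 0 || sites_per_plasmid < 0)
    stop("counts must be >= 0")
  if (relative_signal > 1) {
    warning("relative_signal > 1",
            if (clip) "; clipped to 1" else " (not clipped)")
    if (clip) relative_signal <- 1
  }
  copy_number <- round(relative_signal * base_copy_number)
  list(copy_number = copy_number,
       decoy_count = copy_number * sites_per_plasmid)
}
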