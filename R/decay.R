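#' Constant-rate recombination model
#'
#' Converts physical to recombination distance assuming a uniform rate
#' obtained from a total linkage-map length and a genome size. The defaults
#' are the Heliconius erato map (1430 cM) and genome (400 Mb), giving
#' 3.575e-6 cM/bp -- i.e. 3.575 cM per Mb.
#'
#' @param map_length_cM total linkage map length in centimorgans.
#' @param genome_size_bp genome size in base pairs.
#' @return list of class `recombination_model` with `map_length_cM`,
#'   `genome_size_bp`, `rate_cM_per_bp`.
#' @export
recombination_model <- function(map_length_cM = 1430, genome_size_bp = 400e6) {
  stopifnot(map_length_cM > 0, genome_size_bp > 0)
  structure(list(map_length_cM = map_length_cM,
                 genome_size_bp = genome_size_bp,
                 rate_cM_per_bp = map_length_cM / genome_size_bp),
            class = "recombination_model")
}

#' Physical to recombination distance
#'
#' @param distance_bp non-negative distance(s) in bp.
#' @param model a [recombination_model()].
#' @return distance(s) in cM.
#' @export
bp_to_cM <- function(distance_bp, model = recombination_model()) {
  if (any(distance_bp < 0)) stop("distance must be non-negative")
  distance_bp * model$rate_cM_per_bp
}

#' Recombination distance from the causative locus
#'
#' The causative locus is taken as the centre of the functional interval
#' (midpoint rounded down to an integer bp); distances are unsigned, so
#' upstream and downstream sites at equal physical distance get equal
#' recombination distance.
#'
#' @param position site coordinate(s), 1-based.
#' @param region_start,region_end functional interval bounds, 1-based
#'   inclusive.
#' @param model a [recombination_model()].
#' @return distance(s) in cM.
#' @export
distance_to_locus <- function(position, region_start, region_end,
                              model = recombination_model()) {
  center <- floor((region_start + region_end) / 2)
  bp_to_cM(abs(position - center), model)
}

#' Bin per-site components by recombination distance
#'
#' Sites are assigned to half-open bins `[k*w, (k+1)*w)` of width `w` cM by
#' their distance from the causative locus; a site exactly at a bin edge
#' belongs to the upper bin. Per-bin theta-hat uses the ratio-of-sums rule;
#' bins without sites are emitted with `NA` theta so the bin sequence is
#' exhaustive from 0 to the farthest site.
#'
#' @param components `site_components` frame.
#' @param distances_cM one distance per site (same order).
#' @param bin_width_cM bin width (default 0.01 cM).
#' @return data.frame: `bin_index`, `cM_lo`, `cM_hi`, `cM_mid`, `theta`,
#'   `n_positions`, `sum_num`, `sum_den`.
#' @export
bin_decay <- function(components, distances_cM, bin_width_cM = 0.01) {
  stopifnot(nrow(components) == length(distances_cM))
  ok <- !is.na(components$a)
  a <- components$a[ok]
  den <- a + components$b[ok] + components$c[ok]
  d <- distances_cM[ok]
  bin <- floor(d / bin_width_cM)
  n_bins <- if (length(bin)) max(bin) + 1L else 0L
  idx <- factor(bin, levels = 0:(n_bins - 1L))
  sum_num <- as.numeric(tapply(a, idx, sum, default = 0))
  sum_den <- as.numeric(tapply(den, idx, sum, default = 0))
  n_pos <- as.integer(tapply(rep(1L, length(bin)), idx, sum, default = 0L))
  theta <- ifelse(sum_den != 0, sum_num / sum_den, NA_real_)
  theta[n_pos == 0L] <- NA_real_
  k <- seq_len(n_bins) - 1L
  data.frame(bin_index = k, cM_lo = k * bin_width_cM,
             cM_hi = (k + 1L) * bin_width_cM,
             cM_mid = (k + 0.5) * bin_width_cM,
             theta = theta, n_positions = n_pos,
             sum_num = sum_num, sum_den = sum_den)
}

#' Loess smoothing of a binned decay curve
#'
#' Presentation-only smoothing: locally weighted quadratic regression with
#' tricube weights, evaluated at the input abscissae. Smoothed values never
#' feed back into any estimate. With too few finite points for the span the
#' fit is refused with a hint to enlarge the span.
#'
#' @param x bin centres (cM).
#' @param y binned theta values (`NA` allowed; dropped).
#' @param span loess span (default 0.3).
#' @param degree local polynomial degree (default 2).
#' @return numeric vector, same length as `x`: smoothed values (`NA` where
#'   `y` was `NA`).
#' @export
loess_smooth <- function(x, y, span = 0.3, degree = 2) {
  ok <- is.finite(x) & is.finite(y)
  n_ok <- sum(ok)
  if (n_ok < max(4, ceiling(span * n_ok)) || floor(span * n_ok) < degree + 1)
    stop("too few finite points (", n_ok,
         ") for loess at span ", span, "; increase the span")
  df <- data.frame(xx = x[ok], yy = y[ok])
  fit <- stats::loess(yy ~ xx, data = df, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::predict(fit, data.frame(xx = x[ok]))
  out
}

#' Exponential-decay fit to a binned curve
#'
#' Fits `theta(d) = bg + amp * exp(-d / lambda)` to per-bin estimates by
#' nonlinear least squares, for recovering the decay scale of a divergence
#' peak. Used by the synthetic-data recovery checks.
#'
#' @param d bin centres (cM).
#' @param theta binned theta values.
#' @param weights optional per-bin weights (e.g. site counts).
#' @return list with `bg`, `amp`, `lambda_cM`.
#' @export
fit_decay_scale <- function(d, theta, weights = NULL) {
  ok <- is.finite(d) & is.finite(theta)
  if (!is.null(weights)) weights <- weights[ok]
  d <- d[ok]; theta <- theta[ok]
  if (length(d) < 4L) stop("too few bins for a decay fit")
  bg0 <- stats::median(theta[d >= stats::quantile(d, 0.8)])
  amp0 <- max(theta) - bg0
  lam0 <- max(diff(range(d)) / 4, 1e-3)
  fit <- stats::nls(theta ~ bg + amp * exp(-d / lambda),
                    start = list(bg = bg0, amp = max(amp0, 1e-3), lambda = lam0),
                    weights = weights,
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  cf <- stats::coef(fit)
  list(bg = unname(cf["bg"]), amp = unname(cf["amp"]),
       lambda_cM = unname(cf["lambda"]))
}
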