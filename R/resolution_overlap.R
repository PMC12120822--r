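# Conventions (forced jointly by the printed triples they reproduce):
#   FWHM = 2*sqrt(2*ln 2) * sigma
#   resolving power Rp = mean CCS / FWHM
#   resolution Rs = delta / (4 * sigma)        (base-width definition)
#   error = Phi(-delta / (2 * sigma))          (midpoint decision boundary,
#           equal-variance equal-abundance 1:1 two-Gaussian mixture)
.FWHM_K <- 2 * sqrt(2 * log(2))

.overlap_result <- function(delta_ccs, mean_ccs, sigma) {
  fwhm <- .FWHM_K * sigma
  err <- stats::pnorm(-delta_ccs / (2 * sigma))
  structure(list(delta_ccs = delta_ccs, mean_ccs = mean_ccs,
                 sigma = sigma, fwhm = fwhm,
                 resolution = delta_ccs / (4 * sigma),
                 resolving_power = mean_ccs / fwhm,
                 error_probability = err,
                 p_correct = 1 - err),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("<overlap_result> delta = %.3g A^2, mean CCS = %.4g A^2\n",
                     "  sigma %.4g, FWHM %.4g, resolution %.2f, ",
                     "resolving power %.0f\n",
                     "  error probability %.2g (p_correct %.4f)\n"),
              x$delta_ccs, x$mean_ccs, x$sigma, x$fwhm,
              x$resolution, x$resolving_power,
              x$error_probability, x$p_correct))
  invisible(x)
}

#' Two-peak Gaussian overlap at a given ion mobility resolving power
#'
#' Models two isobaric species as equal-width Gaussians in CCS space,
#' separated by \code{delta_ccs}, with the peak width set by the
#' instrument's resolving power (CCS / FWHM). Annotating a 1:1 mixture by
#' assigning each observation to the nearer peak center misclassifies with
#' probability \code{Phi(-delta / (2 sigma))}.
#'
#' @param delta_ccs Peak-center separation, Angstrom^2.
#' @param mean_ccs Mean CCS of the pair, Angstrom^2.
#' @param resolving_power Ion mobility resolving power (CCS / FWHM).
#' @return An \code{overlap_result} with \code{sigma}, \code{fwhm},
#'   \code{resolution} (Rs = delta / 4 sigma), \code{resolving_power},
#'   \code{error_probability} and \code{p_correct}.
#' @examples
#' overlap_from_resolving_power(1.28, 268.4, 87)   # error ~ 0.31
#' @export
overlap_from_resolving_power <- function(delta_ccs, mean_ccs,
                                         resolving_power) {
  if (delta_ccs <= 0 || mean_ccs <= 0 || resolving_power <= 0) {
    stop("delta_ccs, mean_ccs and resolving_power must all be > 0")
  }
  sigma <- (mean_ccs / resolving_power) / .FWHM_K
  .overlap_result(delta_ccs, mean_ccs, sigma)
}

#' Resolving power required for a target annotation error probability
#'
#' Closed-form inversion of [overlap_from_resolving_power()]:
#' \code{sigma = delta / (2 * qnorm(1 - target))}, then
#' \code{Rp = mean_ccs / (FWHM from sigma)}.
#'
#' @inheritParams overlap_from_resolving_power
#' @param target_error Desired misclassification probability, in (0, 0.5).
#' @return An \code{overlap_result} at the required resolving power.
#' @examples
#' required_resolving_power(1.28, 268.4, 0.05)$resolving_power  # ~293
#' @export
required_resolving_power <- function(delta_ccs, mean_ccs, target_error) {
  if (delta_ccs <= 0 || mean_ccs <= 0) {
    stop("delta_ccs and mean_ccs must be > 0")
  }
  if (target_error <= 0 || target_error >= 0.5) {
    stop("target_error must lie strictly between 0 and 0.5")
  }
  sigma <- delta_ccs / (2 * stats::qnorm(1 - target_error))
  .overlap_result(delta_ccs, mean_ccs, sigma)
}

#' Resolving power at a target two-peak resolution
#'
#' @inheritParams overlap_from_resolving_power
#' @param target_resolution Desired resolution Rs = delta / (4 sigma);
#'   1.5 is baseline separation.
#' @return An \code{overlap_result} at the corresponding resolving power.
#' @examples
#' resolving_power_for_resolution(1.28, 268.4, 1.5)$resolving_power  # ~534
#' @export
resolving_power_for_resolution <- function(delta_ccs, mean_ccs,
                                           target_resolution) {
  if (delta_ccs <= 0 || mean_ccs <= 0 || target_resolution <= 0) {
    stop("delta_ccs, mean_ccs and target_resolution must all be > 0")
  }
  sigma <- delta_ccs / (4 * target_resolution)
  .overlap_result(delta_ccs, mean_ccs, sigma)
}

#' Frequency-weighted standard deviation
#'
#' Population-form weighted SD, \code{sqrt(sum(w * (x - xbar_w)^2) /
#' sum(w))} with \code{xbar_w} the weighted mean — the spread statistic
#' used to pool raw per-feature CCS scatter with intensity weights.
#'
#' @param values Numeric vector (length >= 2).
#' @param weights Non-negative weights, not all zero; recycled to
#'   \code{length(values)} if scalar.
#' @return The weighted standard deviation.
#' @export
weighted_sd <- function(values, weights = rep(1, length(values))) {
  if (length(values) < 2L) stop("need at least two values")
  if (length(weights) == 1L) weights <- rep(weights, length(values))
  if (length(weights) != length(values)) {
    stop("weights must match values in length")
  }
  if (any(weights < 0)) stop("weights must be >= 0")
  if (sum(weights) == 0) stop("weights must not all be zero")
  m <- sum(weights * values) / sum(weights)
  sqrt(sum(weights * (values - m)^2) / sum(weights))
}

#' Mean absolute CCS separation of alkenyl/alkyl isobar pairs
#'
#' Unweighted mean of absolute per-pair CCS differences for the
#' \code{alkenyl_vs_alkyl_isobar} transformation — the peak separation fed
#' into the overlap model together with the mean ether-lipid CCS.
#'
#' @param deltas A \code{pair_deltas} data.frame from [compute_deltas()].
#' @return Mean absolute CCS delta, Angstrom^2.
#' @export
mean_isobar_separation <- function(deltas) {
  iso <- deltas[deltas$transformation == "alkenyl_vs_alkyl_isobar", ,
                drop = FALSE]
  if (nrow(iso) == 0L) stop("no alkenyl_vs_alkyl_isobar pairs in input")
  mean(abs(iso$delta_ccs))
}

#' Annotation error probability over a resolving-power grid
#'
#' @inheritParams overlap_from_resolving_power
#' @param rp_grid Numeric vector of resolving powers.
#' @return data.frame with columns \code{resolving_power},
#'   \code{resolution}, \code{error_probability}, \code{p_correct}.
#' @export
error_curve <- function(delta_ccs, mean_ccs,
                        rp_grid = seq(25, 600, by = 5)) {
  rows <- lapply(rp_grid, function(rp) {
    o <- overlap_from_resolving_power(delta_ccs, mean_ccs, rp)
    data.frame(resolving_power = rp, resolution = o$resolution,
               error_probability = o$error_probability,
               p_correct = o$p_correct)
  })
  do.call(rbind, rows)
}
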