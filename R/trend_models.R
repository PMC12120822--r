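#' Fit the five-coefficient linear RT/CCS trend model
#'
#' Least squares of per-species mean response on \code{[1, CC, DB,
#' I(alkyl), I(alkenyl)]}: a deliberately simple model where cumulative
#' carbons, cumulative double bonds and the sn-1 linkage type are the only
#' predictors. Per-term explained sums of squares are computed by term
#' deletion (refit without the term; the RSS increase is the term's
#' contribution), which is order-independent.
#'
#' Retention times follow a multiplicative structure on reversed-phase
#' columns, so \code{transform = "log"} fits the model on \code{log(RT)}
#' (coefficients are then log-scale effects); CCS is additive and uses the
#' identity transform.
#'
#' @param features Feature data.frame (calibrated / aligned); species-level
#'   means are taken internally across samples.
#' @param response \code{"ccs"} or \code{"rt"}.
#' @param transform \code{"identity"} (default) or \code{"log"}.
#' @param interactions If \code{TRUE}, adds the bilinear CC:DB,
#'   CC:linkage and DB:linkage interaction columns (extended model; off by
#'   default).
#' @return Object of class \code{trend_model}: \code{response},
#'   \code{transform}, \code{coefficients} (named: intercept, cc, db,
#'   alkyl, alkenyl, ...), \code{se}, \code{rss}, \code{ss_deleted}
#'   (deletion SS per non-intercept term), \code{n_species},
#'   \code{species_means}.
#' @export
fit_trend <- function(features, response = c("ccs", "rt"),
                      transform = c("identity", "log"),
                      interactions = FALSE) {
  response <- match.arg(response)
  transform <- match.arg(transform)
  stopifnot(all(c("species", response) %in% names(features)))
  y_raw <- features[[response]]
  if (any(!is.finite(y_raw))) stop("non-finite ", response, " values")
  means <- tapply(y_raw, features$species, mean)
  sp <- names(means)
  info <- species_info(sp)
  if (length(sp) < 6L || length(unique(info$cc)) < 2L ||
      length(unique(info$linkage)) < 2L) {
    stop("need >= 6 species spanning >= 2 CC values and >= 2 linkage types")
  }
  y <- as.numeric(means)
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires positive responses")
    y <- log(y)
  }
  alkyl <- as.numeric(info$linkage == "alkyl")
  alkenyl <- as.numeric(info$linkage == "alkenyl")
  X <- cbind(intercept = 1, cc = info$cc, db = info$db,
             alkyl = alkyl, alkenyl = alkenyl)
  if (interactions) {
    X <- cbind(X, `cc:db` = info$cc * info$db,
               `cc:alkyl` = info$cc * alkyl, `cc:alkenyl` = info$cc * alkenyl,
               `db:alkyl` = info$db * alkyl, `db:alkenyl` = info$db * alkenyl)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: species set does not span the model terms")
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y); p <- ncol(X)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  terms <- setdiff(colnames(X), "intercept")
  ss_del <- vapply(terms, function(tm) {
    sub <- X[, setdiff(colnames(X), tm), drop = FALSE]
    sum(stats::lm.fit(sub, y)$residuals^2) - rss
  }, numeric(1))
  structure(list(response = response, transform = transform,
                 coefficients = stats::setNames(fit$coefficients, colnames(X)),
                 se = se, rss = rss, ss_deleted = ss_del,
                 n_species = n,
                 species_means = data.frame(info, value = as.numeric(means),
                                            stringsAsFactors = FALSE)),
            class = "trend_model")
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("<trend_model> %s (%s), %d species, RSS = %.4g\n",
              x$response, x$transform, x$n_species, x$rss))
  print(round(rbind(coefficient = x$coefficients, se = x$se), 5))
  invisible(x)
}

#' Predict RT or CCS for a species from a fitted trend model
#'
#' Linear evaluation at (CC, DB, linkage indicators); log-transform models
#' are back-transformed so predictions are on the original response scale
#' (minutes or Angstrom^2).
#'
#' @param object A \code{trend_model}.
#' @param species Character vector of shorthand names (any level) or a
#'   single \code{lipid_species}.
#' @param ... Unused.
#' @return Numeric predictions, one per species.
#' @export
predict.trend_model <- function(object, species, ...) {
  if (inherits(species, "lipid_species")) {
    species <- render_shorthand(species)
  }
  info <- species_info(species)
  alkyl <- as.numeric(info$linkage == "alkyl")
  alkenyl <- as.numeric(info$linkage == "alkenyl")
  X <- cbind(intercept = 1, cc = info$cc, db = info$db,
             alkyl = alkyl, alkenyl = alkenyl)
  if ("cc:db" %in% names(object$coefficients)) {
    X <- cbind(X, `cc:db` = info$cc * info$db,
               `cc:alkyl` = info$cc * alkyl, `cc:alkenyl` = info$cc * alkenyl,
               `db:alkyl` = info$db * alkyl, `db:alkenyl` = info$db * alkenyl)
  }
  eta <- drop(X[, names(object$coefficients), drop = FALSE] %*%
                object$coefficients)
  if (object$transform == "log") exp(eta) else eta
}

#' Compare measured species-level CCS with database predictions
#'
#' Per sn-1 subclass, fits the zero-intercept regression of measured on
#' predicted CCS: a slope of 1 then means perfect proportional agreement,
#' and the slope directly reads out any multiplicative database bias.
#' Predicted tables given at molecular species level are first averaged to
#' species level. Model quality is summarized by the standard
#' \code{AIC = n * ln(RSS / n) + 2k} with \code{k = 1} for the slope-only
#' model (note: lower is better under this standard convention).
#'
#' @param measured data.frame with columns \code{species}, \code{ccs}:
#'   species-level measured means.
#' @param predicted data.frame with columns \code{species},
#'   \code{ccs_pred_a2} (molecular or species level names).
#' @param intercept If \code{TRUE}, fit a free intercept as well
#'   (\code{k = 2}); default \code{FALSE}.
#' @param min_n Minimum matched species per subclass; subclasses below it
#'   are skipped with a warning.
#' @return data.frame with one row per subclass: \code{subclass},
#'   \code{slope}, \code{slope_sd}, \code{n}, \code{aic}.
#' @export
compare_to_predictions <- function(measured, predicted, intercept = FALSE,
                                   min_n = 3L) {
  stopifnot(all(c("species", "ccs") %in% names(measured)),
            all(c("species", "ccs_pred_a2") %in% names(predicted)))
  pred_sp <- to_species_level(predicted$species)
  pred <- tapply(predicted$ccs_pred_a2, pred_sp, mean)
  meas_sp <- to_species_level(measured$species)
  meas <- tapply(measured$ccs, meas_sp, mean)
  shared <- intersect(names(pred), names(meas))
  info <- species_info(shared)
  rows <- list()
  for (sub in c("acyl", "alkyl", "alkenyl")) {
    sp <- shared[info$linkage == sub]
    if (length(sp) < min_n) {
      warning("subclass-skipped: ", sub, " has ", length(sp),
              " matched species (< ", min_n, ")", call. = FALSE)
      next
    }
    x <- as.numeric(pred[sp]); y <- as.numeric(meas[sp])
    X <- if (intercept) cbind(1, x) else cbind(x)
    fit <- stats::lm.fit(X, y)
    k <- ncol(X)
    n <- length(y)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / max(n - k, 1L)
    XtXinv <- chol2inv(chol(crossprod(X)))
    slope_idx <- k  # slope is the last column
    rows[[sub]] <- data.frame(
      subclass = sub,
      slope = unname(fit$coefficients[slope_idx]),
      slope_sd = sqrt(XtXinv[slope_idx, slope_idx] * sigma2),
      n = n,
      aic = n * log(rss / n) + 2 * k,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
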