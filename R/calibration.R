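#' Fit a per-sample linear CCS calibration
#'
#' Ordinary least squares of reference CCS on raw mobility over 1-acyl PE
#' anchor species only; ether species are never used as anchors. The
#' fitted affine map converts a sample's uncalibrated mobility values to
#' calibrated CCS comparable across samples.
#'
#' @param features Feature data.frame for a single sample (columns
#'   \code{species}, \code{sample_id}, \code{raw_mobility}).
#' @param reference data.frame with columns \code{species}, \code{ccs_a2}:
#'   curated 1-acyl reference CCS values.
#' @param sample_id Optional sample id to select from \code{features}.
#' @return Object of class \code{ccs_calibration}: \code{sample_id},
#'   \code{slope}, \code{intercept} (Angstrom^2), \code{n_anchors},
#'   \code{residual_sd}.
#' @export
fit_ccs_calibration <- function(features, reference, sample_id = NULL) {
  stopifnot(is.data.frame(features), is.data.frame(reference),
            all(c("species", "ccs_a2") %in% names(reference)))
  if (!is.null(sample_id)) {
    features <- features[features$sample_id == sample_id, , drop = FALSE]
  }
  sid <- unique(features$sample_id)
  if (length(sid) != 1L) {
    stop("fit_ccs_calibration expects features from exactly one sample; ",
         "got ", length(sid))
  }
  info <- species_info(features$species)
  anchors <- features[info$linkage == "acyl" &
                        features$species %in% reference$species, , drop = FALSE]
  anchors <- anchors[!duplicated(anchors$species), , drop = FALSE]
  if (nrow(anchors) < 2L) {
    stop("calibration error: need >= 2 distinct 1-acyl anchor species, ",
         "found ", nrow(anchors), " in sample ", sid)
  }
  x <- anchors$raw_mobility
  y <- reference$ccs_a2[match(anchors$species, reference$species)]
  if (stats::sd(x) == 0) {
    stop("degenerate fit: zero variance in raw mobility for sample ", sid)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  n <- nrow(anchors)
  rsd <- if (n > 2L) sqrt(sum(res^2) / (n - 2L)) else 0
  sxx <- sum((x - mean(x))^2)
  structure(list(sample_id = sid,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_anchors = n,
                 residual_sd = rsd,
                 slope_se = rsd / sqrt(sxx),
                 intercept_se = rsd * sqrt(1 / n + mean(x)^2 / sxx)),
            class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat(sprintf("<ccs_calibration> %s: ccs = %.4f * raw + %.3f (n = %d, residual sd = %.3f)\n",
              x$sample_id, x$slope, x$intercept, x$n_anchors, x$residual_sd))
  invisible(x)
}

#' Apply a CCS calibration to a sample's features
#'
#' @param features Feature data.frame for the model's sample.
#' @param model A \code{ccs_calibration}.
#' @return \code{features} with the \code{ccs} column filled as
#'   \code{slope * raw_mobility + intercept} for all subclasses.
#' @export
apply_calibration <- function(features, model) {
  stopifnot(inherits(model, "ccs_calibration"))
  sid <- unique(features$sample_id)
  if (!identical(sid, model$sample_id)) {
    stop("sample mismatch: model is for ", model$sample_id,
         ", features are from ", paste(sid, collapse = ", "))
  }
  features$ccs <- model$slope * features$raw_mobility + model$intercept
  features
}

#' Calibrate CCS for every sample of a feature table
#'
#' @param features Multi-sample feature data.frame.
#' @param reference Reference CCS table (see [fit_ccs_calibration()]).
#' @return list with \code{features} (calibrated) and \code{models}
#'   (named list of \code{ccs_calibration} per sample).
#' @export
calibrate_cohort <- function(features, reference) {
  sids <- unique(features$sample_id)
  models <- lapply(sids, function(s) {
    fit_ccs_calibration(features, reference, sample_id = s)
  })
  names(models) <- sids
  out <- lapply(sids, function(s) {
    apply_calibration(features[features$sample_id == s, , drop = FALSE],
                      models[[s]])
  })
  features <- do.call(rbind, out)
  rownames(features) <- NULL
  list(features = features, models = models)
}

#' Linear retention-time alignment across samples
#'
#' Aligns every sample's retention times to a reference sample by ordinary
#' least squares of the reference RT on the sample RT over species shared
#' between the two. By default the reference is the sample with the most
#' annotated species (maximizing anchors).
#'
#' @param features Multi-sample feature data.frame (columns \code{species},
#'   \code{sample_id}, \code{rt}).
#' @param reference_sample Optional reference sample id.
#' @return list with \code{features} (column \code{rt} replaced by aligned
#'   values; original kept as \code{rt_raw}) and \code{alignments}
#'   (data.frame: sample_id, slope, intercept, n_anchors).
#' @export
align_rt <- function(features, reference_sample = NULL) {
  stopifnot(all(c("species", "sample_id", "rt") %in% names(features)))
  sids <- unique(features$sample_id)
  if (is.null(reference_sample)) {
    counts <- tapply(features$species, features$sample_id,
                     function(s) length(unique(s)))
    reference_sample <- names(counts)[which.max(counts)]
  }
  if (!reference_sample %in% sids) {
    stop("reference sample ", reference_sample, " not in feature table")
  }
  ref <- features[features$sample_id == reference_sample, , drop = FALSE]
  ref <- ref[!duplicated(ref$species), , drop = FALSE]
  features$rt_raw <- features$rt
  aligns <- vector("list", length(sids))
  for (i in seq_along(sids)) {
    s <- sids[i]
    fs <- features[features$sample_id == s, , drop = FALSE]
    shared <- intersect(fs$species, ref$species)
    if (length(shared) < 2L) {
      stop("RT alignment error: sample ", s, " shares only ",
           length(shared), " species with reference ", reference_sample)
    }
    x <- fs$rt_raw[match(shared, fs$species)]
    y <- ref$rt[match(shared, ref$species)]
    fit <- stats::lm.fit(cbind(1, x), y)
    b <- unname(fit$coefficients)
    if (is.na(b[2]) || b[2] <= 0) {
      stop("RT alignment error: non-positive slope for sample ", s)
    }
    idx <- features$sample_id == s
    features$rt[idx] <- b[1] + b[2] * features$rt_raw[idx]
    aligns[[i]] <- data.frame(sample_id = s, slope = b[2], intercept = b[1],
                              n_anchors = length(shared),
                              stringsAsFactors = FALSE)
  }
  list(features = features, alignments = do.call(rbind, aligns),
       reference_sample = reference_sample)
}
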