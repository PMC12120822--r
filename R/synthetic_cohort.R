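#' Cohort design for the synthetic lipidomics experiment
#'
#' Describes the study layout the generator emulates: three mouse tissues,
#' wild-type vs Peds1-deficient genotypes with three replicates each, and a
#' PE species grid over cumulative carbons and double bonds. Wild-type
#' samples carry 1-O-alkenyl (plasmalogen) ether species, Peds1-deficient
#' samples carry 1-O-alkyl species, and 1-acyl species are present in all
#' samples.
#'
#' @param tissues Tissue labels.
#' @param genotypes Genotype labels; the first is treated as wild type
#'   (alkenyl-carrying), the second as desaturase-deficient (alkyl-carrying).
#' @param replicates Biological replicates per tissue x genotype group.
#' @param cc_grid Cumulative side-chain carbon numbers.
#' @param db_grid Cumulative double bond numbers.
#' @param seed Integer seed controlling every random draw downstream.
#' @return A \code{cohort_design} list.
#' @export
cohort_design <- function(tissues = c("heart", "cerebellum", "cerebrum"),
                          genotypes = c("WT", "dPeds1"),
                          replicates = 3L,
                          cc_grid = c(34L, 36L, 38L, 40L),
                          db_grid = 0:7,
                          seed = 1L) {
  stopifnot(length(tissues) >= 1, length(genotypes) == 2,
            replicates >= 1, length(cc_grid) >= 1, length(db_grid) >= 1)
  structure(list(tissues = tissues, genotypes = genotypes,
                 replicates = as.integer(replicates),
                 cc_grid = as.integer(cc_grid), db_grid = as.integer(db_grid),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Generative RT/CCS model for synthetic PE features
#'
#' Retention-time effects are multiplicative (log-linear), so structural
#' transformations produce scale-free relative differences: adding one
#' downstream radyl double bond multiplies RT by 1 - 0.117, the Delta-1
#' vinyl ether double bond by 1 - 0.020. CCS effects are additive in
#' Angstrom^2: +2.7 per side-chain carbon (i.e. +5.4 per 2 CH2), -1.0 per
#' downstream double bond and +0.3 for the vinyl ether bond, with an
#' ether-linkage offset shared by alkyl and alkenyl species. Defaults are
#' chosen so the average ether-lipid CCS over the default species grid sits
#' at 268.4 Angstrom^2.
#'
#' Besides per-observation measurement noise, each species receives a
#' seeded mean-zero deviation (CCS sd \code{species_sd_ccs}, log-RT sd
#' \code{species_sd_log_rt}) representing composition effects the cumulative
#' shorthand cannot encode. Molecular species containing a chain with >= 4
#' double bonds additionally receive a fixed \code{highdb_offset_ccs},
#' emulating the bimodal CCS deviations seen for polyunsaturated chains;
#' at species level (the default cohort) this offset is inert.
#'
#' Each sample distorts CCS by an affine map drawn from
#' \code{cal_slope_range} / \code{cal_intercept_range} (what the
#' calibration stage must undo) and RT by a mild affine map from
#' \code{rt_slope_range} / \code{rt_intercept_range} (what RT alignment
#' must undo).
#'
#' @param rt_intercept_log Log-minutes intercept.
#' @param rt_per_carbon_log Log-RT increment per side-chain carbon.
#' @param rt_per_db_log Log-RT increment per downstream double bond.
#' @param rt_delta1_log Log-RT increment for the Delta-1 vinyl ether bond.
#' @param rt_ether_log Log-RT offset for ether (alkyl or alkenyl) linkage.
#' @param ccs_intercept,ccs_per_carbon,ccs_per_db,ccs_delta1,ccs_ether CCS
#'   model coefficients, Angstrom^2.
#' @param species_sd_ccs,species_sd_log_rt Per-species deviation scales.
#' @param highdb_offset_ccs CCS offset for molecular chains with >= 4 DB.
#' @param noise_sd_ccs Per-observation CCS noise sd, Angstrom^2.
#' @param noise_sd_log_rt Per-observation log-RT noise sd.
#' @param noise_ppm_mz Per-observation m/z noise, ppm.
#' @param cal_slope_range,cal_intercept_range Per-sample CCS distortion:
#'   raw mobility = (CCS - intercept)/slope.
#' @param rt_slope_range,rt_intercept_range Per-sample RT distortion
#'   (observed = slope * true + intercept), minutes.
#' @param resolving_power Ion mobility resolving power (CCS / FWHM) used
#'   when rendering mobilograms.
#' @return A \code{generative_model} list.
#' @export
generative_model <- function(rt_intercept_log = -0.794,
                             rt_per_carbon_log = log(1.25) / 2,
                             rt_per_db_log = log(1 - 0.117),
                             rt_delta1_log = log(1 - 0.020),
                             rt_ether_log = log(1.08),
                             ccs_intercept = 172.85,
                             ccs_per_carbon = 2.7,
                             ccs_per_db = -1.0,
                             ccs_delta1 = 0.3,
                             ccs_ether = -1.0,
                             species_sd_ccs = 0.4,
                             species_sd_log_rt = 0.01,
                             highdb_offset_ccs = 1.5,
                             noise_sd_ccs = 0.5,
                             noise_sd_log_rt = 0.002,
                             noise_ppm_mz = 2,
                             cal_slope_range = c(0.97, 1.03),
                             cal_intercept_range = c(-5, 5),
                             rt_slope_range = c(0.98, 1.02),
                             rt_intercept_range = c(-0.05, 0.05),
                             resolving_power = 87) {
  m <- list(rt_intercept_log = rt_intercept_log,
            rt_per_carbon_log = rt_per_carbon_log,
            rt_per_db_log = rt_per_db_log,
            rt_delta1_log = rt_delta1_log,
            rt_ether_log = rt_ether_log,
            ccs_intercept = ccs_intercept,
            ccs_per_carbon = ccs_per_carbon,
            ccs_per_db = ccs_per_db,
            ccs_delta1 = ccs_delta1,
            ccs_ether = ccs_ether,
            species_sd_ccs = species_sd_ccs,
            species_sd_log_rt = species_sd_log_rt,
            highdb_offset_ccs = highdb_offset_ccs,
            noise_sd_ccs = noise_sd_ccs,
            noise_sd_log_rt = noise_sd_log_rt,
            noise_ppm_mz = noise_ppm_mz,
            cal_slope_range = cal_slope_range,
            cal_intercept_range = cal_intercept_range,
            rt_slope_range = rt_slope_range,
            rt_intercept_range = rt_intercept_range,
            resolving_power = resolving_power)
  num <- unlist(m)
  if (any(!is.finite(num))) stop("non-finite generative model coefficient")
  sds <- c(species_sd_ccs, species_sd_log_rt, noise_sd_ccs,
           noise_sd_log_rt, noise_ppm_mz)
  if (any(sds < 0)) stop("noise and deviation scales must be >= 0")
  if (resolving_power <= 0) stop("resolving_power must be > 0")
  structure(m, class = "generative_model")
}

#' A zero-noise, identity-distortion variant of a generative model
#'
#' Convenience for tests and worked examples: switches off per-species
#' deviations, measurement noise and per-sample distortions so generated
#' values equal the structural model exactly.
#'
#' @param model A \code{generative_model}.
#' @return A \code{generative_model} with all stochastic scales zeroed.
#' @export
noiseless <- function(model = generative_model()) {
  model$species_sd_ccs <- 0
  model$species_sd_log_rt <- 0
  model$noise_sd_ccs <- 0
  model$noise_sd_log_rt <- 0
  model$noise_ppm_mz <- 0
  model$cal_slope_range <- c(1, 1)
  model$cal_intercept_range <- c(0, 0)
  model$rt_slope_range <- c(1, 1)
  model$rt_intercept_range <- c(0, 0)
  model
}

# Structural (noise-free, deviation-free) true values for parsed species.
structural_values <- function(info, model) {
  ether <- info$linkage %in% c("alkyl", "alkenyl")
  vinyl <- info$linkage == "alkenyl"
  log_rt <- model$rt_intercept_log +
    model$rt_per_carbon_log * info$cc +
    model$rt_per_db_log * info$db +
    model$rt_delta1_log * vinyl +
    model$rt_ether_log * ether
  ccs <- model$ccs_intercept +
    model$ccs_per_carbon * info$cc +
    model$ccs_per_db * info$db +
    model$ccs_delta1 * vinyl +
    model$ccs_ether * ether
  data.frame(info, true_log_rt = log_rt, true_ccs = ccs,
             stringsAsFactors = FALSE)
}

# Deterministic tissue abundance weights: tissues differ in their
# double-bond profile (heart enriched in low-DB, cerebrum in high-DB).
.tissue_weight <- function(tissue, tissues, db) {
  peak <- c(2, 4, 5)[(match(tissue, tissues) - 1) %% 3 + 1]
  exp(-(db - peak)^2 / 8)
}

#' Generate a synthetic 4D lipidomics cohort
#'
#' Builds one feature row per (species, sample) according to the occupancy
#' rules of the Peds1 knockout design: 1-acyl species in every sample,
#' 1-O-alkenyl only in wild-type samples, 1-O-alkyl only in
#' Peds1-deficient samples (mutual exclusivity). True RT/CCS values come
#' from the structural model plus seeded per-species deviations; each
#' observation adds measurement noise, a per-sample affine CCS distortion
#' (stored raw mobility is uncalibrated) and a per-sample affine RT
#' distortion. m/z values come from the shorthand mass engine with ppm
#' noise.
#'
#' @param design A [cohort_design()].
#' @param model A [generative_model()].
#' @param molecular Logical; if \code{TRUE}, ether species are emitted as
#'   molecular-level names with an sn-1 16:0 ether chain and the remaining
#'   carbons/double bonds on sn-2, activating the high-DB CCS offset for
#'   sn-2 chains with >= 4 double bonds. Default \code{FALSE} (species
#'   level).
#' @return An object of class \code{ether_cohort}: list with
#'   \code{features} (data.frame: species, sample_id, tissue, genotype,
#'   rt, mz, raw_mobility, ccs (NA until calibrated), intensity),
#'   \code{species} (per-species truth incl. deviations), \code{samples}
#'   (per-sample truth incl. the CCS/RT distortion parameters),
#'   \code{design} and \code{model}.
#' @examples
#' cohort <- generate_cohort(cohort_design(seed = 7))
#' nrow(cohort$samples)  # 18 samples
#' @export
generate_cohort <- function(design = cohort_design(),
                            model = generative_model(),
                            molecular = FALSE) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(model, "generative_model"))
  set.seed(design$seed)

  grid <- expand.grid(cc = design$cc_grid, db = design$db_grid,
                      linkage = c("acyl", "alkyl", "alkenyl"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pfx <- .LINKAGE_PREFIX[grid$linkage]
  if (molecular) {
    ether <- grid$linkage != "acyl"
    name <- ifelse(ether,
                   sprintf("PE %s16:0_%d:%d", pfx, grid$cc - 16L, grid$db),
                   sprintf("PE %d:%d", grid$cc, grid$db))
    sn2_highdb <- ether & grid$db >= 4L
  } else {
    name <- sprintf("PE %s%d:%d", pfx, grid$cc, grid$db)
    sn2_highdb <- rep(FALSE, nrow(grid))
  }
  info <- data.frame(species = name, linkage = grid$linkage,
                     cc = grid$cc, db = grid$db, stringsAsFactors = FALSE)
  truth <- structural_values(info, model)
  n_sp <- nrow(truth)
  truth$dev_ccs <- stats::rnorm(n_sp, 0, model$species_sd_ccs) +
    ifelse(sn2_highdb, model$highdb_offset_ccs, 0)
  truth$dev_log_rt <- stats::rnorm(n_sp, 0, model$species_sd_log_rt)
  truth$true_ccs <- truth$true_ccs + truth$dev_ccs
  truth$true_log_rt <- truth$true_log_rt + truth$dev_log_rt
  truth$mz <- mz_deprotonated(truth$species)

  samples <- expand.grid(tissue = design$tissues, genotype = design$genotypes,
                         replicate = seq_len(design$replicates),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_%d", samples$tissue,
                               samples$genotype, samples$replicate)
  n_s <- nrow(samples)
  samples$cal_slope <- stats::runif(n_s, model$cal_slope_range[1],
                                    model$cal_slope_range[2])
  samples$cal_intercept <- stats::runif(n_s, model$cal_intercept_range[1],
                                        model$cal_intercept_range[2])
  samples$rt_slope <- stats::runif(n_s, model$rt_slope_range[1],
                                   model$rt_slope_range[2])
  samples$rt_intercept <- stats::runif(n_s, model$rt_intercept_range[1],
                                       model$rt_intercept_range[2])

  wt <- design$genotypes[1]
  rows <- vector("list", n_s)
  for (i in seq_len(n_s)) {
    s <- samples[i, ]
    keep <- truth$linkage == "acyl" |
      (truth$linkage == "alkenyl" & s$genotype == wt) |
      (truth$linkage == "alkyl" & s$genotype != wt)
    sp <- truth[keep, , drop = FALSE]
    n <- nrow(sp)
    rt_true <- exp(sp$true_log_rt + stats::rnorm(n, 0, model$noise_sd_log_rt))
    rt_obs <- s$rt_slope * rt_true + s$rt_intercept
    ccs_obs <- sp$true_ccs + stats::rnorm(n, 0, model$noise_sd_ccs)
    raw <- (ccs_obs - s$cal_intercept) / s$cal_slope
    mz <- sp$mz * (1 + stats::rnorm(n, 0, model$noise_ppm_mz * 1e-6))
    w <- .tissue_weight(s$tissue, design$tissues, sp$db)
    intensity <- 1e5 * w * stats::rlnorm(n, 0, 0.8)
    rows[[i]] <- data.frame(species = sp$species, sample_id = s$sample_id,
                            tissue = s$tissue, genotype = s$genotype,
                            rt = rt_obs, mz = mz, raw_mobility = raw,
                            ccs = NA_real_, intensity = intensity,
                            stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  structure(list(features = features, species = truth,
                 samples = samples[, c("sample_id", "tissue", "genotype",
                                       "replicate", "cal_slope",
                                       "cal_intercept", "rt_slope",
                                       "rt_intercept")],
                 design = design, model = model),
            class = "ether_cohort")
}

#' @export
print.ether_cohort <- function(x, ...) {
  cat("<ether_cohort>", nrow(x$features), "features,",
      nrow(x$species), "species,", nrow(x$samples), "samples\n")
  invisible(x)
}

#' Reference CCS table for calibration (synthetic CCSbase stand-in)
#'
#' Extracts the true (deviation-inclusive, noise-free) CCS values of the
#' 1-acyl PE species from a synthetic cohort, emulating the externally
#' curated 1-acyl reference table used to calibrate ether-lipid CCS values.
#'
#' @param cohort An \code{ether_cohort}.
#' @return data.frame with columns \code{species}, \code{ccs_a2}.
#' @export
reference_ccs_table <- function(cohort) {
  stopifnot(inherits(cohort, "ether_cohort"))
  acyl <- cohort$species[cohort$species$linkage == "acyl", ]
  data.frame(species = acyl$species, ccs_a2 = acyl$true_ccs,
             stringsAsFactors = FALSE)
}

#' Synthetic predicted-CCS table with known subclass bias
#'
#' Builds a database-prediction stand-in from a cohort's true CCS values,
#' dividing each subclass by a known proportional bias. Regressing measured
#' on predicted then recovers exactly those bias factors as slopes, which
#' is how the measured-vs-database comparison is exercised without the
#' external database.
#'
#' @param cohort An \code{ether_cohort}.
#' @param bias Named numeric: division factor per subclass
#'   (\code{acyl}, \code{alkyl}, \code{alkenyl}).
#' @return data.frame with columns \code{species}, \code{ccs_pred_a2}.
#' @export
synthetic_predicted_table <- function(cohort,
                                      bias = c(acyl = 1.01, alkyl = 1.09,
                                               alkenyl = 1.17)) {
  stopifnot(inherits(cohort, "ether_cohort"))
  sp <- cohort$species
  data.frame(species = sp$species,
             ccs_pred_a2 = sp$true_ccs / bias[sp$linkage],
             stringsAsFactors = FALSE)
}

#' Render a summed ion mobilogram in CCS space
#'
#' Each feature contributes a Gaussian centered at its CCS value with
#' FWHM = CCS / resolving power and area equal to its intensity; the trace
#' is the pointwise sum.
#'
#' @param features data.frame with columns \code{ccs} and \code{intensity}
#'   (features sharing one m/z window).
#' @param resolving_power Ion mobility resolving power (CCS / FWHM).
#' @param grid_step CCS grid step, Angstrom^2.
#' @param pad Half-width of grid padding in multiples of the widest sigma.
#' @return data.frame with columns \code{ccs}, \code{intensity}.
#' @export
render_mobilogram <- function(features, resolving_power = 87,
                              grid_step = 0.02, pad = 5) {
  stopifnot(is.data.frame(features), nrow(features) >= 1,
            all(c("ccs", "intensity") %in% names(features)))
  if (resolving_power <= 0) stop("resolving_power must be > 0")
  if (grid_step <= 0) stop("grid_step must be > 0")
  fwhm <- features$ccs / resolving_power
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  lo <- min(features$ccs - pad * max(sigma))
  hi <- max(features$ccs + pad * max(sigma))
  grid <- seq(lo, hi, by = grid_step)
  y <- rep(0, length(grid))
  for (i in seq_len(nrow(features))) {
    y <- y + features$intensity[i] * stats::dnorm(grid, features$ccs[i],
                                                  sigma[i])
  }
  data.frame(ccs = grid, intensity = y)
}
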