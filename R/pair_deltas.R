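.TRANSFORMATIONS <- c("plus2CH2", "plusDB_downstream", "plusDB_delta1",
                      "alkenyl_vs_alkyl_isobar")

#' Enumerate matched species pairs for a structural transformation
#'
#' Matching rules (pairs are ordered reference -> transformed):
#' \describe{
#'   \item{plus2CH2}{same class, linkage and DB; CC increases by 2
#'     (radyl chain elongation).}
#'   \item{plusDB_downstream}{same class, linkage and CC; DB increases by 1
#'     (an additional double bond within the radyl chains).}
#'   \item{plusDB_delta1}{\code{PE O-n:d} vs \code{PE P-n:d}: adds only the
#'     Delta-1 vinyl ether double bond (transformed species is 2 H lighter).}
#'   \item{alkenyl_vs_alkyl_isobar}{\code{PE O-n:(d+1)} vs \code{PE P-n:d}:
#'     identical elemental formula, indistinguishable by m/z alone.}
#' }
#'
#' @param species Character vector of species-level shorthand names.
#' @param transformation One of \code{"plus2CH2"}, \code{"plusDB_downstream"},
#'   \code{"plusDB_delta1"}, \code{"alkenyl_vs_alkyl_isobar"}.
#' @return data.frame with columns \code{species_a} (reference),
#'   \code{species_b} (transformed), \code{transformation}. May be empty.
#' @export
enumerate_pairs <- function(species, transformation) {
  transformation <- match.arg(transformation, .TRANSFORMATIONS)
  species <- unique(species)
  info <- species_info(species)
  a <- character(0); b <- character(0)
  add <- function(ia, ib) {
    a <<- c(a, info$species[ia]); b <<- c(b, info$species[ib])
  }
  key <- function(linkage, cc, db) paste(linkage, cc, db, sep = "|")
  have <- key(info$linkage, info$cc, info$db)
  lookup <- function(linkage, cc, db) match(key(linkage, cc, db), have)
  for (i in seq_len(nrow(info))) {
    j <- switch(transformation,
      plus2CH2 = lookup(info$linkage[i], info$cc[i] + 2L, info$db[i]),
      plusDB_downstream = lookup(info$linkage[i], info$cc[i], info$db[i] + 1L),
      plusDB_delta1 = if (info$linkage[i] == "alkyl")
        lookup("alkenyl", info$cc[i], info$db[i]) else NA_integer_,
      alkenyl_vs_alkyl_isobar = if (info$linkage[i] == "alkyl" &&
                                    info$db[i] >= 1L)
        lookup("alkenyl", info$cc[i], info$db[i] - 1L) else NA_integer_
    )
    if (!is.na(j)) add(i, j)
  }
  data.frame(species_a = a, species_b = b,
             transformation = rep(transformation, length(a)),
             stringsAsFactors = FALSE)
}

# Per-pair deltas. Pairs whose species co-occur in samples are paired
# within sample (cancelling sample effects) and averaged across samples.
# Pairs that never co-occur (O-/P- pairs span the two genotypes by the
# knockout occupancy) are bridged: per-tissue species means are taken
# within each genotype and differenced within tissue.
.pair_delta_one <- function(features, sa, sb) {
  fa <- features[features$species == sa, , drop = FALSE]
  fb <- features[features$species == sb, , drop = FALSE]
  if (nrow(fa) == 0L || nrow(fb) == 0L) return(NULL)
  common <- intersect(fa$sample_id, fb$sample_id)
  if (length(common) >= 1L) {
    ia <- match(common, fa$sample_id); ib <- match(common, fb$sample_id)
    drt <- 100 * (fb$rt[ib] - fa$rt[ia]) / fa$rt[ia]
    dcc <- fb$ccs[ib] - fa$ccs[ia]
    n <- length(common)
  } else {
    tiss <- intersect(unique(fa$tissue), unique(fb$tissue))
    if (length(tiss) == 0L) return(NULL)
    drt <- dcc <- numeric(0)
    for (tt in tiss) {
      rta <- mean(fa$rt[fa$tissue == tt]); rtb <- mean(fb$rt[fb$tissue == tt])
      cca <- mean(fa$ccs[fa$tissue == tt]); ccb <- mean(fb$ccs[fb$tissue == tt])
      drt <- c(drt, 100 * (rtb - rta) / rta)
      dcc <- c(dcc, ccb - cca)
    }
    n <- length(tiss)
  }
  data.frame(delta_rt_pct = mean(drt), delta_ccs = mean(dcc),
             n_samples_used = n)
}

#' Compute RT and CCS deltas for matched species pairs
#'
#' For each pair, relative RT differences (\code{100 * (RT_b - RT_a) /
#' RT_a}, percent) and absolute CCS differences (\code{CCS_b - CCS_a},
#' Angstrom^2) are computed per common sample and averaged; pairs with no
#' common sample are bridged through per-tissue genotype means (required
#' for alkyl/alkenyl pairs, which never share a sample under the knockout
#' design). Pairs observable in neither way are dropped with a warning.
#'
#' @param features Calibrated, RT-aligned feature data.frame (columns
#'   \code{species}, \code{sample_id}, \code{tissue}, \code{rt},
#'   \code{ccs}).
#' @param pairs data.frame from [enumerate_pairs()] (one or several
#'   transformations row-bound).
#' @return data.frame of class \code{pair_deltas}: one row per retained
#'   pair with \code{species_a}, \code{species_b}, \code{transformation},
#'   \code{delta_rt_pct}, \code{delta_ccs}, \code{n_samples_used}.
#' @export
compute_deltas <- function(features, pairs) {
  stopifnot(all(c("species", "sample_id", "tissue", "rt", "ccs") %in%
                  names(features)),
            all(c("species_a", "species_b", "transformation") %in%
                  names(pairs)))
  if (any(!is.finite(features$ccs))) {
    stop("features must be calibrated before computing deltas (ccs has NA)")
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    d <- .pair_delta_one(features, pairs$species_a[i], pairs$species_b[i])
    if (is.null(d)) {
      warning("pair-dropped: no common sample or tissue for ",
              pairs$species_a[i], " / ", pairs$species_b[i], call. = FALSE)
      next
    }
    out[[i]] <- cbind(pairs[i, , drop = FALSE], d)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(species_a = character(0), species_b = character(0),
                      transformation = character(0),
                      delta_rt_pct = numeric(0), delta_ccs = numeric(0),
                      n_samples_used = integer(0))
  }
  rownames(res) <- NULL
  class(res) <- c("pair_deltas", "data.frame")
  res
}

#' Summarize pair deltas per transformation
#'
#' Unweighted mean and SD across pairs, per transformation and dimension,
#' mirroring the "mean +/- SD over 10-32 species pairs" presentation.
#'
#' @param deltas A \code{pair_deltas} data.frame from [compute_deltas()].
#' @return data.frame with columns \code{transformation}, \code{dimension}
#'   (\code{"rt_pct"} or \code{"ccs"}), \code{mean}, \code{sd},
#'   \code{n_pairs}.
#' @export
summarize_deltas <- function(deltas) {
  stopifnot(inherits(deltas, "pair_deltas") || is.data.frame(deltas))
  groups <- split(deltas, deltas$transformation)
  rows <- lapply(groups, function(g) {
    data.frame(
      transformation = g$transformation[1],
      dimension = c("rt_pct", "ccs"),
      mean = c(mean(g$delta_rt_pct), mean(g$delta_ccs)),
      sd = c(stats::sd(g$delta_rt_pct), stats::sd(g$delta_ccs)),
      n_pairs = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
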