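# Monoisotopic atomic masses (NIST/CODATA), Da. Proton = H atom - electron.
.ATOMIC_MASS <- c(
  C = 12.000000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151
)
.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS <- .ATOMIC_MASS[["H"]] - .ELECTRON_MASS

.LINKAGE_PREFIX <- c(acyl = "", alkyl = "O-", alkenyl = "P-")

#' Parse a lipid shorthand name
#'
#' Parses LIPID MAPS style shorthand for glycerophosphoethanolamines at
#' species level (\code{"PE 34:1"}, \code{"PE O-38:5"}, \code{"PE P-38:5"})
#' or molecular species level (\code{"PE O-18:0_20:4"}). The \code{O-}
#' prefix denotes a 1-O-alkyl (ether) sn-1 linkage and \code{P-} a
#' 1-O-alkenyl (plasmalogen, vinyl ether) linkage. For \code{P-} species
#' the Delta-1 vinyl ether double bond is by convention \emph{not} counted
#' in the shorthand double bond number, so \code{PE P-n:d} has the same
#' elemental formula as \code{PE O-n:(d+1)}.
#'
#' @param name A single lipid shorthand string.
#' @return An object of class \code{lipid_species}: a list with elements
#'   \code{lipid_class}, \code{linkage} (\code{"acyl"}, \code{"alkyl"} or
#'   \code{"alkenyl"}), \code{cc} (cumulative side-chain carbons),
#'   \code{db} (cumulative double bonds as written) and \code{chains}
#'   (a two-column matrix of per-chain carbons and double bonds, or
#'   \code{NULL} for species-level names).
#' @examples
#' parse_shorthand("PE P-38:5")
#' parse_shorthand("PE O-18:0_20:4")
#' @seealso [render_shorthand()], [elemental_formula()], [mz_deprotonated()]
#' @export
parse_shorthand <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name)) {
    stop("'name' must be a single character string")
  }
  x <- trimws(name)
  m <- regexec("^([A-Za-z]+)\\s+(O-|P-)?([0-9]+:[0-9]+(?:_[0-9]+:[0-9]+)*)$", x)
  parts <- regmatches(x, m)[[1]]
  if (length(parts) == 0L) {
    stop("malformed lipid shorthand: '", name, "'")
  }
  cls <- parts[2]
  if (cls != "PE") {
    stop("unknown lipid class token '", cls, "' in '", name, "'")
  }
  linkage <- switch(parts[3], "O-" = "alkyl", "P-" = "alkenyl", "acyl")
  chain_tokens <- strsplit(parts[4], "_", fixed = TRUE)[[1]]
  chain_num <- lapply(chain_tokens, function(tok) {
    cd <- as.numeric(strsplit(tok, ":", fixed = TRUE)[[1]])
    if (any(!is.finite(cd)) || any(cd != floor(cd)) || any(cd < 0)) {
      stop("invalid chain fragment '", tok, "' in '", name, "'")
    }
    cd
  })
  chains <- do.call(rbind, chain_num)
  colnames(chains) <- c("carbons", "double_bonds")
  cc <- sum(chains[, "carbons"])
  db <- sum(chains[, "double_bonds"])
  if (cc < 2) stop("cumulative carbon count ", cc, " too small in '", name, "'")
  structure(
    list(
      lipid_class = cls,
      linkage = linkage,
      cc = as.integer(cc),
      db = as.integer(db),
      chains = if (nrow(chains) > 1L) chains else NULL
    ),
    class = "lipid_species"
  )
}

#' Render a lipid species back to canonical shorthand
#'
#' @param species A \code{lipid_species} object.
#' @param level \code{"species"} (default) renders the cumulative
#'   \code{cc:db} form; \code{"molecular"} renders per-chain form when
#'   chain information is available.
#' @return A character scalar.
#' @export
render_shorthand <- function(species, level = c("species", "molecular")) {
  stopifnot(inherits(species, "lipid_species"))
  level <- match.arg(level)
  pfx <- .LINKAGE_PREFIX[[species$linkage]]
  if (level == "molecular" && !is.null(species$chains)) {
    body <- paste(sprintf("%d:%d", species$chains[, 1], species$chains[, 2]),
                  collapse = "_")
  } else {
    body <- sprintf("%d:%d", species$cc, species$db)
  }
  paste0(species$lipid_class, " ", pfx, body)
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species>", render_shorthand(x),
      sprintf("[%s, CC=%d, DB=%d]\n", x$linkage, x$cc, x$db))
  invisible(x)
}

#' Elemental formula of a PE species
#'
#' Computes element counts for phosphatidylethanolamine species from the
#' cumulative carbon and double-bond numbers. Diacyl \code{PE cc:db} is
#' C(cc+5) H(2cc-2db+10) N O8 P; replacing one ester by an ether bond
#' (1-O-alkyl) removes one oxygen and adds two hydrogens; the 1-O-alkenyl
#' (vinyl ether) form additionally removes two hydrogens, making
#' \code{PE P-n:d} isobaric with \code{PE O-n:(d+1)}.
#'
#' @param species A \code{lipid_species} object or a shorthand string.
#' @return Named integer vector with elements C, H, N, O, P, of class
#'   \code{elemental_formula}.
#' @export
elemental_formula <- function(species) {
  if (is.character(species)) species <- parse_shorthand(species)
  stopifnot(inherits(species, "lipid_species"))
  cc <- species$cc
  db <- species$db
  counts <- switch(species$linkage,
    acyl    = c(C = cc + 5L, H = 2L * cc - 2L * db + 10L, N = 1L, O = 8L, P = 1L),
    alkyl   = c(C = cc + 5L, H = 2L * cc - 2L * db + 12L, N = 1L, O = 7L, P = 1L),
    # P-n:d == O-n:(d+1): the Delta-1 vinyl DB is not written in db
    alkenyl = c(C = cc + 5L, H = 2L * cc - 2L * db + 10L, N = 1L, O = 7L, P = 1L)
  )
  if (any(counts < 0L)) {
    stop("cc=", cc, " cannot host db=", db, " double bonds")
  }
  structure(as.integer(counts), names = names(counts),
            class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x)[x > 0], ifelse(x[x > 0] > 1, x[x > 0], ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Monoisotopic neutral mass of a formula
#'
#' @param formula An \code{elemental_formula} (or anything accepted by
#'   [elemental_formula()]).
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (!inherits(formula, "elemental_formula")) {
    formula <- elemental_formula(formula)
  }
  sum(.ATOMIC_MASS[names(formula)] * as.numeric(formula))
}

#' m/z of the deprotonated ([M-H]-) ion
#'
#' Monoisotopic neutral mass minus the proton mass (hydrogen atom minus
#' electron), single charge. Negative ESI mode is the only adduct in scope.
#'
#' @param species A \code{lipid_species}, a shorthand string, or a
#'   character vector of shorthand strings (vectorized).
#' @return Numeric m/z value(s) in Da.
#' @examples
#' mz_deprotonated("PE 34:1")   # 716.5236
#' @export
mz_deprotonated <- function(species) {
  if (is.character(species) && length(species) > 1L) {
    return(vapply(species, mz_deprotonated, numeric(1), USE.NAMES = FALSE))
  }
  monoisotopic_mass(elemental_formula(species)) - .PROTON_MASS
}

# Vectorized species metadata for pipeline tables; errors on any bad name.
species_info <- function(names) {
  uniq <- unique(names)
  parsed <- lapply(uniq, parse_shorthand)
  info <- data.frame(
    species = uniq,
    linkage = vapply(parsed, `[[`, character(1), "linkage"),
    cc = vapply(parsed, `[[`, integer(1), "cc"),
    db = vapply(parsed, `[[`, integer(1), "db"),
    stringsAsFactors = FALSE
  )
  info[match(names, info$species), , drop = FALSE]
}

# Species-level canonical name for a possibly molecular-level name.
to_species_level <- function(names) {
  vapply(names, function(n) render_shorthand(parse_shorthand(n), "species"),
         character(1), USE.NAMES = FALSE)
}
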