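.FEATURE_COLUMNS <- c("species", "sample_id", "rt", "mz", "raw_mobility",
                      "intensity")

.delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

# Short provenance hash of an arbitrary config object (md5 of its JSON).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.meta_header <- function(config = NULL) {
  v <- as.character(utils::packageVersion("etherims"))
  h <- if (is.null(config)) "none" else config_hash(config)
  sprintf("# etherims %s config_hash=%s", v, h)
}

#' Write a feature table to CSV/TSV
#'
#' The delimiter follows the file extension (\code{.tsv}/\code{.txt} tab,
#' otherwise comma). A comment header line records the package version and
#' a hash of the provenance config. Numeric columns are written with
#' enough digits for a lossless round trip at 6 decimals.
#'
#' @param features Feature data.frame.
#' @param path Output path.
#' @param config Optional config object hashed into the header.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(features, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(config), con)
  utils::write.table(features, con, sep = .delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV/TSV
#'
#' Requires a header with at least the columns \code{species},
#' \code{sample_id}, \code{rt}, \code{mz}, \code{raw_mobility},
#' \code{intensity} (extra columns such as \code{tissue}, \code{genotype},
#' \code{ccs} are kept). Rows with unparseable species names or non-finite
#' mandatory numerics are rejected with a logged count.
#'
#' @param path Input path; delimiter by extension as in
#'   [write_feature_table()].
#' @return Feature data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.FEATURE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- c("rt", "mz", "raw_mobility", "intensity")
  ok_num <- rowSums(!is.finite(as.matrix(df[num_cols]))) == 0
  ok_sp <- vapply(df$species, function(s) {
    !inherits(try(parse_shorthand(s), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
  bad <- sum(!(ok_num & ok_sp))
  if (bad > 0L) {
    message("WARN rejected ", bad, " row(s) of ", nrow(df),
            " (unparseable species or non-finite numerics) in ", path)
  }
  out <- df[ok_num & ok_sp, , drop = FALSE]
  if (!"ccs" %in% names(out)) out$ccs <- NA_real_
  rownames(out) <- NULL
  out
}

#' Read a reference or predicted CCS table
#'
#' @param path CSV/TSV with columns \code{species} and one CCS column
#'   (\code{ccs_a2} or \code{ccs_pred_a2}).
#' @return data.frame.
#' @export
read_ccs_table <- function(path) {
  if (!file.exists(path)) stop("CCS table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!"species" %in% names(df) ||
      !any(c("ccs_a2", "ccs_pred_a2") %in% names(df))) {
    stop("CCS table ", path,
         " needs columns 'species' and 'ccs_a2' (or 'ccs_pred_a2')")
  }
  df
}

#' Write a generic table with the provenance header
#'
#' @inheritParams write_feature_table
#' @param x data.frame to write.
#' @export
write_table_with_meta <- function(x, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(config), con)
  utils::write.table(x, con, sep = .delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON report with provenance metadata
#'
#' @param x List to serialize.
#' @param path Output path.
#' @param config Optional config hashed into the \code{meta} block.
#' @export
write_json_report <- function(x, path, config = NULL) {
  x$meta <- list(package = "etherims",
                 version = as.character(utils::packageVersion("etherims")),
                 config_hash = if (is.null(config)) "none"
                               else config_hash(config))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
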