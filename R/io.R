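#' Read a plate-scan CSV
#'
#' Reads and validates a scan table with header
#' `well,excitation_nm,emission_nm,intensity`: every emission wavelength
#' must lie on the 5 nm grid, intensities must be non-negative, and
#' `(well, excitation, emission)` keys must be unique.
#'
#' @param path Path to a CSV file.
#' @return A validated scan `data.frame`.
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scan(tab)
}

#' Validate a scan table
#'
#' @param tab A data frame purporting to be a scan table.
#' @return The table, invisibly validated (errors otherwise).
#' @export
validate_scan <- function(tab) {
  required <- c("well", "excitation_nm", "emission_nm", "intensity")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("malformed header: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  off <- which(tab$emission_nm %% 5 != 0)
  if (length(off) > 0L)
    stop(sprintf(
      "off-grid wavelength: emission %g nm in row %d is not on the 5 nm grid",
      tab$emission_nm[off[1]], off[1]), call. = FALSE)
  neg <- which(tab$intensity < 0)
  if (length(neg) > 0L)
    stop(sprintf("negative intensity %g in row %d", tab$intensity[neg[1]],
                 neg[1]), call. = FALSE)
  key <- paste(tab$well, tab$excitation_nm, tab$emission_nm)
  if (anyDuplicated(key))
    stop("duplicate (well, excitation, emission) key: ",
         key[anyDuplicated(key)], call. = FALSE)
  tab[required]
}

#' Write a plate-scan CSV
#'
#' Writes the table deterministically: rows sorted by well, excitation and
#' emission, dot decimal separator, `%.10g` float formatting and `\n` line
#' endings regardless of locale, so identical tables produce identical
#' bytes.
#'
#' @param tab A scan table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(tab, path) {
  tab <- validate_scan(tab)
  ord <- order(tab$well, tab$excitation_nm, tab$emission_nm)
  tab <- tab[ord, , drop = FALSE]
  lines <- c("well,excitation_nm,emission_nm,intensity",
             sprintf("%s,%s,%s,%s", tab$well,
                     formatC(tab$excitation_nm, format = "g", digits = 10),
                     formatC(tab$emission_nm, format = "g", digits = 10),
                     formatC(tab$intensity, format = "g", digits = 10)))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a FLIM region-of-interest table
#'
#' CSV with columns `sample,fraction,tau_ns` and optionally `phase_rad`.
#'
#' @param path Path to a CSV file.
#' @return A data frame; `fraction` validated to `[0, 1]`.
#' @export
read_flim_rois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "fraction", "tau_ns")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("malformed header: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(tab$fraction < 0 | tab$fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(tab$tau_ns < 0)) stop("lifetimes must be >= 0", call. = FALSE)
  tab
}

#' Load a model configuration file
#'
#' Reads a YAML (or JSON) configuration block of model parameters, e.g.
#' `{F_a, R_a, K_MF, K_MR, P_TOT, regime}` for the kinetics module.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
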