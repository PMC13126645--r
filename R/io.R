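#' Read a plate-reader kinetics export
#'
#' Expects a comma-separated file with a header row, one time column and one
#' column per well. Times are converted to hours; a well-to-condition map
#' assigns chaperone concentrations.
#'
#' @param path File path.
#' @param time_unit One of `"h"`, `"min"`, `"s"`.
#' @param time_col Name of the time column (default first column).
#' @param well_map Optional named numeric vector or two-column data frame
#'   (`well_id`, `jb6_conc`) assigning chaperone concentrations (nM) to wells;
#'   unmapped wells get `NA`.
#' @return Long tibble with columns `t` (h), `signal`, `well_id`, `jb6_conc`.
#' @export
read_plate_csv <- function(path, time_unit = c("h", "min", "s"),
                           time_col = NULL, well_map = NULL) {
  time_unit <- match.arg(time_unit)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0L) {
    stop_oligochap(sprintf("'%s' contains no data rows.", path),
                   "oligochap_parse_error")
  }
  time_col <- time_col %||% names(df)[1]
  if (!time_col %in% names(df)) {
    stop_oligochap(sprintf("Missing time column '%s' in '%s'.", time_col, path),
                   "oligochap_parse_error")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop_oligochap(sprintf("Non-numeric column(s): %s.",
                           paste(bad, collapse = ", ")),
                   "oligochap_parse_error")
  }
  tt <- df[[time_col]]
  if (is.unsorted(tt, strictly = TRUE)) {
    bad_row <- which(diff(tt) <= 0)[1] + 1L
    stop_oligochap(
      sprintf("Time column not strictly increasing at row %d (t = %g).",
              bad_row, tt[bad_row]),
      "oligochap_parse_error")
  }
  div <- c(h = 1, min = 60, s = 3600)[[time_unit]]
  out <- df |>
    tidyr::pivot_longer(-dplyr::all_of(time_col),
                        names_to = "well_id", values_to = "signal") |>
    dplyr::mutate(t = .data[[time_col]] / div, .keep = "unused") |>
    dplyr::select("t", "signal", "well_id")
  if (!is.null(well_map)) {
    if (is.data.frame(well_map)) {
      well_map <- setNames(well_map$jb6_conc, well_map$well_id)
    }
    out$jb6_conc <- unname(well_map[out$well_id])
  } else {
    out$jb6_conc <- NA_real_
  }
  out
}

#' Read a diffusional-sizing export
#'
#' Accepts either raw two-chamber intensities (`intensity_inlet`,
#' `intensity_diffused`) or a ready `diffused_fraction` column, plus
#' `replicate_id` and optional `size_range` / grouping columns which are
#' carried through. Intensity pairs are converted to the diffused fraction
#' I_d / (I_d + I_i); fractions above 0.5 are clipped with a QC warning.
#'
#' @param path File path.
#' @return Tibble with at least `replicate_id` and `diffused_fraction`.
#' @export
read_mds_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"diffused_fraction" %in% names(df)) {
    if (!all(c("intensity_inlet", "intensity_diffused") %in% names(df))) {
      stop_oligochap(
        "Need diffused_fraction or intensity_inlet + intensity_diffused columns.",
        "oligochap_parse_error")
    }
    if (any(df$intensity_inlet < 0 | df$intensity_diffused < 0)) {
      stop_oligochap("Negative intensities are not physical.",
                     "oligochap_parse_error")
    }
    df$diffused_fraction <-
      df$intensity_diffused / (df$intensity_inlet + df$intensity_diffused)
  }
  over <- df$diffused_fraction > 0.5
  if (any(over)) {
    warn(sprintf("%d diffused fraction(s) > 0.5 clipped to 0.4999 (QC).",
                 sum(over)))
    df$diffused_fraction[over] <- 0.4999
  }
  as_tibble(df)
}

#' Read a supernatant-titration table
#'
#' @param path CSV with columns `X` (volume fraction; values given in percent
#'   may be flagged with `percent = TRUE`), `f` (or intensity pair as in
#'   [read_mds_csv()]), optional `replicate_id`.
#' @param percent If TRUE, `X` is divided by 100.
#' @return Tibble with columns `X`, `f`, `replicate_id`.
#' @export
read_titration_csv <- function(path, percent = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"f" %in% names(df)) {
    if (all(c("intensity_inlet", "intensity_diffused") %in% names(df))) {
      df$f <- df$intensity_diffused / (df$intensity_inlet + df$intensity_diffused)
    } else {
      stop_oligochap("Need column `f` or an intensity pair.",
                     "oligochap_parse_error")
    }
  }
  if (!"X" %in% names(df)) {
    stop_oligochap("Need column `X` (supernatant volume fraction).",
                   "oligochap_parse_error")
  }
  if (percent) df$X <- df$X / 100
  if (any(df$X < 0 | df$X > 1)) {
    stop_oligochap("`X` must lie in [0, 1] (use percent = TRUE for % input).",
                   "oligochap_parse_error")
  }
  if (!"replicate_id" %in% names(df)) df$replicate_id <- seq_len(nrow(df))
  as_tibble(df[, c("X", "f", "replicate_id")])
}

#' Read an oligomer-dissociation decay table
#'
#' @param path CSV with columns `t` (hours unless `time_unit` says otherwise),
#'   `r_h` (nm), optional `sd`, `condition`, `temperature_label`,
#'   `replicate_id`.
#' @param time_unit One of `"h"`, `"min"`.
#' @return Tibble sorted by condition and time.
#' @export
read_decay_csv <- function(path, time_unit = c("h", "min")) {
  time_unit <- match.arg(time_unit)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t", "r_h") %in% names(df))) {
    stop_oligochap("Need columns `t` and `r_h`.", "oligochap_parse_error")
  }
  if (time_unit == "min") df$t <- df$t / 60
  if (any(df$t < 0) || any(df$r_h <= 0)) {
    stop_oligochap("Times must be >= 0 and radii > 0.",
                   "oligochap_parse_error")
  }
  df <- as_tibble(df)
  if ("condition" %in% names(df)) {
    dplyr::arrange(df, .data$condition, .data$t)
  } else {
    dplyr::arrange(df, .data$t)
  }
}

#' Read a 3-column ASCII small-angle scattering file
#'
#' Whitespace-delimited `q I sigma` rows; lines starting with `#` are
#' comments. `sigma` is optional (third column absent = unweighted).
#'
#' @param path File path.
#' @return Tibble with columns `q`, `I` and (if present) `sigma`.
#' @export
read_saxs_dat <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    stop_oligochap(sprintf("'%s' has no data lines.", path),
                   "oligochap_parse_error")
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% 2:3) {
    stop_oligochap("Expect 2 or 3 whitespace-separated columns (q I [sigma]).",
                   "oligochap_parse_error")
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE))
  if (anyNA(m)) {
    stop_oligochap("Non-numeric value in scattering file.",
                   "oligochap_parse_error")
  }
  out <- tibble(q = m[, 1], I = m[, 2])
  if (ncols == 3L) out$sigma <- m[, 3]
  if (is.unsorted(out$q, strictly = TRUE)) {
    stop_oligochap("q must be strictly increasing.", "oligochap_parse_error")
  }
  out
}

#' Write a scattering curve as 3-column ASCII
#'
#' @param curve Tibble with `q`, `I` and optionally `sigma`.
#' @param path Output path.
#' @param comment Optional header comment (written as `# ...` lines).
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  has_sigma <- "sigma" %in% names(curve)
  writeLines(paste("#", if (has_sigma) "q I sigma" else "q I"), con)
  body <- if (has_sigma) {
    sprintf("%.8e %.8e %.8e", curve$q, curve$I, curve$sigma)
  } else {
    sprintf("%.8e %.8e", curve$q, curve$I)
  }
  writeLines(body, con)
  invisible(path)
}

#' Write an analysis result with reproducibility metadata
#'
#' Serialises a fitted object (any of the package's fit classes or a plain
#' list) to JSON together with the metadata needed to regenerate it: the
#' recorded seed, the generating/config parameters and the package version.
#'
#' @param result Object to serialise (lists and fit objects supported).
#' @param path Output path ('.json').
#' @param seed Seed used for any randomness.
#' @param config Optional configuration list echoed into the file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, seed = NULL, config = NULL) {
  payload <- list(
    result = unclass(result),
    metadata = list(
      seed = seed,
      config = config,
      package = "oligochap",
      version = as.character(utils::packageVersion("oligochap")),
      written = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
  )
  # drop embedded data frames that would bloat the artifact
  payload$result$series <- NULL
  payload$result$boot <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write kinetic traces in the plate-reader export layout
#'
#' Inverse of [read_plate_csv()]: wide CSV with a `time_h` column and one
#' column per well.
#'
#' @param traces Long tibble with `t`, `signal`, `well_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(traces, path) {
  wide <- traces |>
    dplyr::select("t", "well_id", "signal") |>
    tidyr::pivot_wider(names_from = "well_id", values_from = "signal") |>
    dplyr::rename(time_h = "t")
  readr::write_csv(wide, path)
  invisible(path)
}
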