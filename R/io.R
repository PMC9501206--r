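#' Read a bucket table
#'
#' A bucket table is a delimited text file (tab primary, comma accepted)
#' holding a samples-by-positions intensity matrix at fine equidistant
#' resolution, with one numeric header line of ppm values and sample labels
#' on the other margin. This is the exchange format produced by equidistant
#' binning of raw spectra at (typically) 0.001 ppm.
#'
#' @param path Path to the delimited file.
#' @param orientation One of `"auto"`, `"samples_in_rows"`,
#'   `"samples_in_columns"`. With `"auto"`, the margin whose labels parse as
#'   strictly monotone numbers is taken to be the ppm axis.
#' @return A [spectrum_set()] with all positions included and a descending
#'   ppm axis.
#' @export
read_bucket_table <- function(path,
                              orientation = c("auto", "samples_in_rows",
                                              "samples_in_columns")) {
  orientation <- match.arg(orientation)
  delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE,
                          name_repair = "minimal")
  if (ncol(df) < 2 || nrow(df) < 1) stop("bucket table too small", call. = FALSE)
  header <- names(df)[-1]
  header_num <- suppressWarnings(as.numeric(header))
  first_col_num <- suppressWarnings(as.numeric(df[[1]]))
  rows_mode <- !anyNA(header_num)
  cols_mode <- !anyNA(first_col_num)
  if (orientation == "samples_in_rows" || (orientation == "auto" && rows_mode)) {
    if (!rows_mode) stop("bucket table header is not numeric ppm values", call. = FALSE)
    ppm <- header_num
    ids <- df[[1]]
    vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
    vals <- matrix(vals, nrow = nrow(df))
  } else {
    if (!cols_mode) {
      stop("bucket table has no numeric ppm margin (format error)", call. = FALSE)
    }
    ppm <- first_col_num
    ids <- names(df)[-1]
    vals <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
    vals <- t(matrix(vals, nrow = nrow(df)))
  }
  if (anyNA(vals)) {
    stop("bucket table contains non-numeric or missing cells (ragged rows?)",
         call. = FALSE)
  }
  if (anyDuplicated(ppm)) stop("duplicated ppm values in bucket table", call. = FALSE)
  spectrum_set(vals, ppm = ppm, sample_ids = ids)
}

#' Write a bucket table
#'
#' Writes tab-delimited text with a ppm header line and sample ids in the
#' first column, at full double precision so that
#' `read_bucket_table(write_bucket_table(s))` round-trips bit for bit.
#'
#' @param s A [spectrum_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  df <- tibble::as_tibble(s$intensities, .name_repair = "minimal")
  names(df) <- format_full(s$ppm)
  df <- tibble::add_column(df, sample_id = s$sample_ids, .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

# shortest decimal strings that round-trip doubles exactly
format_full <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Read an analysis config
#'
#' JSON or YAML (by extension) with any of the keys `exclusions`
#' (list of `[ppm_hi, ppm_lo]` pairs), `lambda`, `rho`, `max_iter`, `tol`,
#' `min_region_bins`, `bin_width_ppm`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list; `exclusions`, if present, is an [exclusion_config()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$exclusions)) {
    ex <- cfg$exclusions
    if (is.data.frame(ex)) ex <- as.matrix(ex)
    cfg$exclusions <- exclusion_config(ex)
  }
  cfg
}

#' Write a feature table to delimited text
#'
#' The file has two tab-delimited blocks separated by a blank line: a
#' region-metadata block (`region_id`, `start`, `end`, `ppm_hi`, `ppm_lo`,
#' `kind`, `segment_id`) and a samples-by-regions value block. Values are
#' written at full precision; [read_feature_table()] round-trips exactly.
#'
#' @param ft A `feature_table` (see [summarize_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  meta <- ft$regions
  con <- file(path, open = "wt")
  on.exit(close(con))
  cols <- c("region_id", "start", "end", "ppm_hi", "ppm_lo", "kind", "segment_id")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(meta) == 0) {
    warning("feature table has zero retained regions; writing header only",
            call. = FALSE)
    return(invisible(path))
  }
  for (k in seq_len(nrow(meta))) {
    writeLines(paste(c(
      meta$region_id[k], meta$start[k], meta$end[k],
      format_full(meta$ppm_hi[k]), format_full(meta$ppm_lo[k]),
      as.character(meta$kind[k]), meta$segment_id[k]
    ), collapse = "\t"), con)
  }
  writeLines("", con)
  writeLines(paste(c("sample_id", meta$region_id), collapse = "\t"), con)
  for (i in seq_len(nrow(ft$values))) {
    writeLines(paste(c(rownames(ft$values)[i], format_full(ft$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the file.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "")[1]
  if (is.na(sep)) {
    if (length(lines) == 1L) {
      return(feature_table(matrix(numeric(0), nrow = 0, ncol = 0),
                           empty_region_tibble()))
    }
    stop("malformed feature table: missing block separator", call. = FALSE)
  }
  meta_raw <- utils::read.delim(text = lines[1:(sep - 1)], stringsAsFactors = FALSE)
  meta <- tibble::tibble(
    region_id = as.character(meta_raw$region_id),
    start = as.integer(meta_raw$start),
    end = as.integer(meta_raw$end),
    ppm_hi = as.numeric(meta_raw$ppm_hi),
    ppm_lo = as.numeric(meta_raw$ppm_lo),
    kind = as.character(meta_raw$kind),
    segment_id = as.integer(meta_raw$segment_id),
    width_bins = as.integer(meta_raw$end) - as.integer(meta_raw$start) + 1L
  )
  body <- utils::read.delim(text = lines[(sep + 1):length(lines)],
                            check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(body[, -1, drop = FALSE])
  rownames(vals) <- body[[1]]
  colnames(vals) <- meta$region_id
  feature_table(vals, meta)
}

#' Serialize a region set to JSON
#'
#' A region set learned on one cohort can be stored and later applied to new
#' spectra on the same axis with [apply_regions()] (train/apply workflows).
#'
#' @param rs A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  payload <- list(
    bin_width_ppm = rs$bin_width_ppm,
    min_region_bins = rs$min_region_bins,
    lambda = rs$lambda,
    regions = as.data.frame(rs$regions),
    dropped = as.data.frame(rs$dropped)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region set written by [write_region_set()]
#'
#' @param path Path to the JSON file.
#' @return A `region_set`.
#' @export
read_region_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_region_tbl <- function(df) {
    if (is.null(df) || length(df) == 0 || nrow(as.data.frame(df)) == 0) {
      return(empty_region_tibble())
    }
    df <- tibble::as_tibble(df)
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    df$segment_id <- as.integer(df$segment_id)
    df$width_bins <- as.integer(df$width_bins)
    df
  }
  region_set(
    regions = as_region_tbl(payload$regions),
    dropped = as_region_tbl(payload$dropped),
    bin_width_ppm = payload$bin_width_ppm,
    min_region_bins = payload$min_region_bins,
    lambda = payload$lambda
  )
}
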