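# Plain-text artifact formats: CSV payloads with full-precision doubles
# (shortest round-trip representation) and JSON for configuration and
# result summaries. Write-then-read is the identity on all payload fields.
# Writers go through readr (shortest round-trip doubles); numeric payloads
# are read back with base read.csv, whose double parser is exactly rounded
# (vroom's fast path can be one ulp off).

subject_table_cols <- c("subject_id", "group", "severity", "symptoms",
                        "days_since_injury")

# Schema check with field-level messages.
check_subject_table <- function(subjects) {
  missing <- setdiff(c("subject_id", "group"), names(subjects))
  if (length(missing)) {
    plv_abort(sprintf("subject table is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              class = "plvnet_schema_error")
  }
  bad <- setdiff(unique(subjects$group), c("patient", "control"))
  if (length(bad)) {
    plv_abort(sprintf("group labels must be 'patient'/'control'; found: %s",
                      paste(bad, collapse = ", ")),
              class = "plvnet_schema_error")
  }
  invisible(subjects)
}

#' Write / read a subject metadata table
#'
#' CSV with header `subject_id,group,severity,symptoms,days_since_injury`;
#' days since injury is present for patients and empty for controls.
#'
#' @param subjects Subject tibble.
#' @param path File path.
#' @return `read_subject_table()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  check_subject_table(subjects)
  keep <- intersect(subject_table_cols, names(subjects))
  readr::write_csv(subjects[keep], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  if ("subject_id" %in% names(out)) out$subject_id <- as.character(out$subject_id)
  check_subject_table(out)
  if (any(out$group == "patient" & is.na(out$days_since_injury)) ||
      any(out$group == "control" & !is.na(out$days_since_injury))) {
    plv_abort("days_since_injury must be present iff group = patient",
              class = "plvnet_schema_error")
  }
  out
}

#' Write / read a connectivity tensor
#'
#' Long-format CSV, one row per (subject, frequency, pair), carrying the
#' grid frequency, the pair's region indices and names, and the PLV.
#' Doubles are written in shortest round-trip representation, so a
#' write-read cycle is bit-identical.
#'
#' @param tensor A `plv_tensor`.
#' @param path File path.
#' @return `read_plv_tensor()` returns the `plv_tensor`; the writer
#'   returns `path` invisibly.
#' @export
write_plv_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "plv_tensor"))
  readr::write_csv(tidy.plv_tensor(tensor), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_plv_tensor
#' @export
read_plv_tensor <- function(path) {
  long <- utils::read.csv(path, colClasses = c(subject_id = "character"))
  need <- c("subject_id", "freq_index", "frequency_hz", "pair", "region_i",
            "region_j", "plv")
  missing <- setdiff(need, names(long))
  if (length(missing)) {
    plv_abort(sprintf("tensor file is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              class = "plvnet_schema_error")
  }
  ids <- unique(long$subject_id)
  freqs <- sort(unique(long$freq_index))
  pairs <- sort(unique(long$pair))
  n_pairs <- length(pairs)
  n_regions <- round((1 + sqrt(1 + 8 * n_pairs)) / 2)
  grid_f <- vapply(freqs, function(f) {
    long$frequency_hz[match(f, long$freq_index)]
  }, numeric(1))
  grid <- tibble::tibble(freq_index = freqs, frequency_hz = grid_f,
                         band = band_of(grid_f))
  class(grid) <- c("plv_grid", class(grid))
  pu <- all_pairs(n_regions)
  region_names <- character(n_regions)
  first_rows <- match(pairs, long$pair)
  region_names[pu$i[pairs]] <- long$region_i[first_rows]
  region_names[pu$j[pairs]] <- long$region_j[first_rows]
  arr <- array(NA_real_,
               c(length(ids), length(freqs), n_pairs))
  arr[cbind(match(long$subject_id, ids),
            match(long$freq_index, freqs),
            match(long$pair, pairs))] <- long$plv
  new_plv_tensor(arr, grid, n_regions, ids, region_names)
}

#' Write / read an epoched source time-series set
#'
#' Directory container: `meta.json` (sampling rate, region names, epoch
#' and sample counts) plus `timeseries.csv` in long format
#' (`subject_id,epoch,region,sample,value`).
#'
#' @param tsset A `plv_timeseries` set.
#' @param dir Directory path (created if needed).
#' @return `read_timeseries()` returns the `plv_timeseries`; the writer
#'   returns `dir` invisibly.
#' @export
write_timeseries <- function(tsset, dir) {
  stopifnot(inherits(tsset, "plv_timeseries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(tsset$subjects[[1]])
  meta <- list(sampling_rate_hz = tsset$sampling_rate_hz,
               region_names = tsset$region_names,
               subject_ids = names(tsset$subjects),
               n_epochs = d[1], n_regions = d[2], n_samples = d[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  long <- purrr::map_dfr(names(tsset$subjects), function(id) {
    arr <- tsset$subjects[[id]]
    tibble::tibble(
      subject_id = id,
      epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
      region = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      sample = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.vector(arr)
    )
  })
  readr::write_csv(long, file.path(dir, "timeseries.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, "timeseries.csv"),
                          colClasses = c(subject_id = "character"))
  subjects <- lapply(meta$subject_ids, function(id) {
    rows <- long[long$subject_id == id, ]
    arr <- array(NA_real_, c(meta$n_epochs, meta$n_regions, meta$n_samples))
    arr[cbind(rows$epoch, rows$region, rows$sample)] <- rows$value
    arr
  })
  names(subjects) <- meta$subject_ids
  structure(list(subjects = subjects,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 region_names = meta$region_names),
            class = "plv_timeseries")
}

#' Export one frequency's connectivity matrix as CSV
#'
#' @param tensor A `plv_tensor`.
#' @param freq_index Grid frequency index.
#' @param path File path.
#' @param subject Optional subject; default averages subjects.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(tensor, freq_index, path,
                                      subject = NULL) {
  m <- connectivity_matrix(tensor, freq_index, subject)
  df <- as.data.frame(m)
  df <- cbind(region = rownames(m), df)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
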