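#' Read and write force curves in the plain-text exchange format
#'
#' One file per approach/retract cycle: comment header lines of the form
#' `# key=value` (`curve_id`, `velocity_nm_s`, `dwell_s`,
#' `spring_constant_pN_nm`, `sensitivity_nm_V`), a column-name line, then
#' three tab-separated columns `z_nm`, `f_approach_pN`, `f_retract_pN`.
#'
#' @param curve Tibble for one curve (`z_nm`, `f_approach_pN`,
#'   `f_retract_pN`; `curve_id` optional).
#' @param path File path.
#' @param metadata Named list merged over the curve's attributes for the
#'   header.
#' @return `write_force_curve()` returns `path` invisibly;
#'   `read_force_curve()` returns the curve tibble with header fields as
#'   attributes.
#' @export
write_force_curve <- function(curve, path, metadata = list()) {
  meta <- list(
    curve_id = if ("curve_id" %in% names(curve)) curve$curve_id[[1]] else 1L,
    velocity_nm_s = attr(curve, "velocity_nm_s"),
    dwell_s = attr(curve, "dwell_s"),
    spring_constant_pN_nm = attr(curve, "spring_constant_pN_nm"),
    sensitivity_nm_V = attr(curve, "sensitivity_nm_V")
  )
  meta[names(metadata)] <- metadata
  meta <- meta[!vapply(meta, is.null, logical(1))]
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, format, character(1), digits = 15))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("z_nm\tf_approach_pN\tf_retract_pN", con)
  writeLines(sprintf("%.6g\t%.6g\t%.6g", curve$z_nm, curve$f_approach_pN,
                     curve$f_retract_pN), con)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  dat <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  out <- tibble::as_tibble(dat)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  for (i in seq_along(keys)) {
    v <- suppressWarnings(as.numeric(vals[[i]]))
    attr(out, keys[[i]]) <- if (is.na(v)) vals[[i]] else v
  }
  if (!"curve_id" %in% names(out)) {
    id <- attr(out, "curve_id")
    out <- tibble::add_column(out,
                              curve_id = as.integer(if (is.null(id)) 1 else id),
                              .before = 1)
  }
  out
}

#' Write a simulated experiment to a directory
#'
#' One exchange-format file per curve plus a `ground_truth.tsv` sidecar
#' (`curve_id`, `n_events`, `true_forces_pN`, `true_Lc_nm`; multiple events
#' comma-separated).
#'
#' @param experiment An `"afs_experiment"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(experiment$curves$curve_id)
  for (id in ids) {
    cv <- experiment$curves[experiment$curves$curve_id == id, ]
    attr(cv, "velocity_nm_s") <- experiment$config$retract_velocity
    attr(cv, "dwell_s") <- 0.5
    attr(cv, "spring_constant_pN_nm") <- experiment$config$spring_constant
    write_force_curve(cv, file.path(dir, sprintf("curve_%04d.tsv", id)))
  }
  truth <- experiment$events |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      true_forces_pN = paste(sprintf("%.4f", .data$force_pN), collapse = ","),
      true_Lc_nm = paste(sprintf("%.4f", .data$Lc_nm), collapse = ",")
    )
  all_ids <- tibble::tibble(curve_id = ids)
  truth <- dplyr::left_join(all_ids, truth, by = "curve_id")
  truth$n_events[is.na(truth$n_events)] <- 0L
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' @rdname write_force_curve
#' @param dir Directory of curve files.
#' @export
read_force_curves <- function(dir) {
  files <- sort(list.files(dir, pattern = "^curve_.*\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) {
    abort(sprintf("no curve files found in '%s'.", dir),
          class = "smforce_error")
  }
  dplyr::bind_rows(lapply(files, read_force_curve))
}

#' Read and write topographs as plain-text grids
#'
#' Format: one header line `# rows cols pixel_size_nm`, then the height
#' matrix (nm), one image row per line, space-separated.
#'
#' @param topo A `"topograph"` matrix.
#' @param path File path.
#' @return `write_topograph()` returns `path` invisibly; `read_topograph()`
#'   a `"topograph"`.
#' @export
write_topograph <- function(topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %g", nrow(topo), ncol(topo),
                     attr(topo, "pixel_size_nm")), con)
  utils::write.table(format(unclass(topo), digits = 7, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_topograph
#' @export
read_topograph <- function(path) {
  hdr <- scan(path, what = character(), n = 4, comment.char = "",
              quiet = TRUE)
  dims <- as.numeric(hdr[2:4])
  m <- matrix(scan(path, skip = 1, quiet = TRUE), nrow = dims[[1]],
              byrow = TRUE)
  structure(m, class = c("topograph", "matrix", "array"),
            pixel_size_nm = dims[[3]])
}

#' Store and load a calibration as a key/value text file
#'
#' @param cal An [calibration()] object.
#' @param path File path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` an `"afs_calibration"`.
#' @export
write_calibration <- function(cal, path) {
  writeLines(c(
    sprintf("sensitivity_nm_V=%.10g", cal$sensitivity),
    sprintf("spring_constant_pN_nm=%.10g", cal$spring_constant),
    sprintf("temperature_K=%.10g", cal$temperature)
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- readLines(path)
  vals <- as.numeric(sub("^[^=]*=", "", kv))
  names(vals) <- sub("=.*$", "", kv)
  calibration(sensitivity = vals[["sensitivity_nm_V"]],
              spring_constant = vals[["spring_constant_pN_nm"]],
              temperature = vals[["temperature_K"]])
}
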