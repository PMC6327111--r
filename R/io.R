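#' Read and write density time series
#'
#' CSV with mandatory header `time_days,density` and an optional `sem`
#' column.  Times must be non-negative, strictly increasing and free of
#' duplicates; parse problems are reported with the offending line number
#' (header = line 1).
#'
#' @param path File path.
#' @return Tibble with `time_days`, `density` and, when present, `sem`.
#' @export
read_density_series <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("time_days", "density")
  miss <- setdiff(need, names(raw))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  cols <- intersect(c("time_days", "density", "sem"), names(raw))
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad)) {
      abort(sprintf("non-numeric value in column '%s' at line %d", cl, bad[1] + 1))
    }
    raw[[cl]] <- v
  }
  t <- raw$time_days
  dup <- which(duplicated(t))
  if (length(dup)) abort(sprintf("duplicated time at line %d", dup[1] + 1))
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) abort(sprintf("times not increasing at line %d", nonmono[1] + 2))
  if (any(t < 0)) abort("times must be non-negative")
  if (any(raw$density < 0)) abort("densities must be non-negative")
  tibble::as_tibble(raw[cols])
}

#' @rdname read_density_series
#' @param series Data frame with `time_days`, `density`, optional `sem`.
#' @export
write_density_series <- function(series, path) {
  cols <- intersect(c("time_days", "density", "sem"), names(series))
  utils::write.csv(series[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write kinetic parameters (JSON or YAML)
#'
#' A flat mapping of the symbol names `mu`, `k`, `kprime`, `c0`, `lam`,
#' `beta` (extended-model keys `kprime_d`, `gamma`, `omega`, `delta` are
#' accepted and produce an [extended_params()]).  Format chosen by file
#' extension.
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return A `kinetic_params` or `extended_params` object.
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base_keys <- c("mu", "k", "kprime", "c0", "lam", "beta")
  ext_keys <- c("kprime_d", "gamma", "omega", "delta")
  unknown <- setdiff(names(lst), c(base_keys, ext_keys))
  if (length(unknown)) {
    abort(paste0("unknown parameter key(s): ", paste(unknown, collapse = ", ")))
  }
  base <- do.call(kinetic_params, lst[intersect(base_keys, names(lst))])
  if (any(ext_keys %in% names(lst))) {
    do.call(extended_params, c(list(base = base), lst[intersect(ext_keys, names(lst))]))
  } else {
    base
  }
}

#' @rdname read_params
#' @param params A `kinetic_params` or `extended_params` object.
#' @export
write_params <- function(params, path) {
  flat <- if (inherits(params, "extended_params")) {
    c(params$base[c("mu", "k", "kprime", "c0", "lam", "beta")],
      params[c("kprime_d", "gamma", "omega", "delta")])
  } else {
    params[c("mu", "k", "kprime", "c0", "lam", "beta")]
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

#' Read and write trajectories
#'
#' CSV with header `time_days,stem_density_per_mm,fgf_concentration_c0_units`
#' and, for two-compartment trajectories, `progenitor_density_per_mm`.
#'
#' @param traj A `mito_trajectory` (columns `time`, `s`, `c`, optional `d`).
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  out <- data.frame(time_days = traj$time, stem_density_per_mm = traj$s)
  if ("d" %in% names(traj)) out$progenitor_density_per_mm <- traj$d
  out$fgf_concentration_c0_units <- traj$c
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  raw <- utils::read.csv(path)
  out <- tibble::tibble(time = raw$time_days, s = raw$stem_density_per_mm)
  if ("progenitor_density_per_mm" %in% names(raw)) {
    out$d <- raw$progenitor_density_per_mm
  }
  out$c <- raw$fgf_concentration_c0_units
  out
}

#' Read and write per-bin counts
#'
#' CSV with header `bin_start_mm,count`.
#' @param counts A `binned_counts` tibble.
#' @param path File path.
#' @export
write_bin_counts <- function(counts, path) {
  utils::write.csv(counts[c("bin_start_mm", "count")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @export
read_bin_counts <- function(path) {
  raw <- utils::read.csv(path)
  if (!all(c("bin_start_mm", "count") %in% names(raw))) {
    abort("bin counts CSV needs columns bin_start_mm,count")
  }
  w <- if (nrow(raw) > 1) diff(raw$bin_start_mm)[1] else 1
  structure(tibble::as_tibble(raw[c("bin_start_mm", "count")]),
            class = c("binned_counts", class(tibble::tibble())),
            bin_width = w)
}

#' Read and write positional category tables
#'
#' CSV with header `category,length_fraction,observed,boundary_observed`
#' (the boundary column optional on read).
#' @param table A category table.
#' @param path File path.
#' @export
write_category_table <- function(table, path) {
  cols <- intersect(c("category", "length_fraction", "observed", "boundary_observed"),
                    names(table))
  utils::write.csv(table[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_category_table
#' @export
read_category_table <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_category_table(raw)
  raw
}
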