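# File formats: measurement CSV, processed-prickle CSV, density-grid CSV,
# model-parameter JSON, fit-result JSON. Degrees in all files; radians
# only internally.

#' Read a measurement CSV into stem records
#'
#' One row per organ with columns `stem_id`, `kind` (`leaf`|`prickle`),
#' `theta_deg`, `H_mm` and optionally `prickle_height_mm` (blank for
#' leaves). Prickles smaller than `maturity_min_mm` are dropped at entry
#' with a logged count — only mature prickles carry pattern information
#' at measurement resolution.
#'
#' @param path CSV file path (UTF-8, header required, decimal point).
#' @param maturity_min_mm Maturity threshold in mm (default 5); rows with
#'   a non-missing `prickle_height_mm` below it are dropped.
#' @return Named list of [stem_record()] objects, one per `stem_id`.
#' @export
read_measurements <- function(path, maturity_min_mm = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("stem_id", "kind", "theta_deg", "H_mm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("measurement CSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("measurement CSV has no data rows")
  if ("prickle_height_mm" %in% names(df)) {
    imm <- df$kind == "prickle" & !is.na(df$prickle_height_mm) &
      df$prickle_height_mm < maturity_min_mm
    if (any(imm)) {
      message(sprintf("read_measurements: dropped %d immature prickle(s) (< %g mm)",
                      sum(imm), maturity_min_mm))
      df <- df[!imm, , drop = FALSE]
    }
  }
  ids <- unique(df$stem_id)
  stems <- lapply(ids, function(id) {
    d <- df[df$stem_id == id, , drop = FALSE]
    stem_record(id, d$kind, d$theta_deg, d$H_mm)
  })
  names(stems) <- ids
  stems
}

#' Write stem records to a measurement CSV
#'
#' @param stems A `stem_record` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(stems, path) {
  if (inherits(stems, "stem_record")) stems <- list(stems)
  rows <- do.call(rbind, lapply(stems, function(s)
    cbind(stem_id = s$stem_id, s$organs)))
  rows$prickle_height_mm <- ifelse(rows$kind == "prickle", NA_real_, NA_real_)
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a density grid to CSV
#'
#' Matrix layout: first column `phi_deg`, remaining columns one per t
#' value (header `t_<value>`). Degrees in the file; radians internally.
#'
#' @param grid A `density_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  df <- data.frame(phi_deg = grid$phi_axis * 180 / pi, grid$values)
  names(df)[-1] <- sprintf("t_%.17g", grid$t_axis)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a density grid from CSV
#'
#' @param path CSV written by [write_density_grid()].
#' @param meaning `"model_density"` or `"kde_density"`.
#' @return A `density_grid`.
#' @export
read_density_grid <- function(path, meaning = "model_density") {
  df <- utils::read.csv(path, check.names = FALSE)
  t_axis <- as.numeric(sub("^t_", "", names(df)[-1]))
  density_grid(as.matrix(df[, -1, drop = FALSE]),
               df$phi_deg * pi / 180, t_axis, meaning = meaning)
}

params_to_list <- function(p) {
  list(alpha = p$alpha, beta = p$beta, T_a = p$T_a, T_b = p$T_b,
       T_c = p$T_c, T = p$T, Phi = p$Phi)
}

#' Write model parameters to JSON
#' @param params A `model_params`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(params, path) {
  jsonlite::write_json(params_to_list(params), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#' @param path JSON path with fields `alpha`, `beta`, `T_a`, `T_b`, `T_c`
#'   and optionally `T`, `Phi`.
#' @return A `model_params`.
#' @export
read_model_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(alpha = x$alpha, beta = x$beta, T_a = x$T_a, T_b = x$T_b,
               T_c = x$T_c,
               T = if (!is.null(x$T)) x$T else 1,
               Phi = if (!is.null(x$Phi)) x$Phi else golden_angle())
}

#' Write a fit result to JSON
#'
#' @param result A `fit_result` from [optimize_params()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(result, path) {
  out <- list(
    params = params_to_list(result$params),
    correlation = result$correlation,
    n_converged = result$n_converged,
    basins = lapply(result$all_optima, function(b)
      list(params = params_to_list(b$params), correlation = b$correlation)),
    config_echo = unclass(result$config),
    seed = result$seed
  )
  out$config_echo$params <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fit result from JSON
#' @param path JSON written by [write_fit_result()].
#' @return A list with `params` (a `model_params`), `correlation`,
#'   `n_converged`, `basins` and `seed`.
#' @export
read_fit_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_params <- function(p) model_params(
    alpha = p$alpha, beta = p$beta, T_a = p$T_a, T_b = p$T_b, T_c = p$T_c,
    T = if (!is.null(p$T)) p$T else 1,
    Phi = if (!is.null(p$Phi)) p$Phi else golden_angle())
  list(
    params = as_params(x$params),
    correlation = x$correlation,
    n_converged = x$n_converged,
    basins = lapply(x$basins, function(b)
      list(params = as_params(b$params), correlation = b$correlation)),
    seed = x$seed
  )
}
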