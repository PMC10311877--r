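# CSV/JSON round-tripping for the command-line workflow. Dialect: comma
# separated, header row, '.' decimal, no index column; 15 significant
# digits so write -> read is lossless for doubles in practice.

#' Write / read an allocation pool
#'
#' One row per accepted allocation: `alloc_id`, `D`, then `T_1..T_N`
#' columns in the original unit order of the data the pool was built
#' from.
#'
#' @param pool A `qrer_pool`.
#' @param data The [qrer_data] the pool was drawn for (supplies the
#'   stored permutation).
#' @param path Output CSV path.
#' @return `path`, invisibly (`read_allocation_pool` returns a tibble).
#' @export
write_allocation_pool <- function(pool, data, path) {
  stopifnot(inherits(pool, "qrer_pool"), inherits(data, "qrer_data"))
  inv <- order(data$perm)
  Tm <- pool$T[, inv, drop = FALSE]
  colnames(Tm) <- paste0("T_", seq_len(ncol(Tm)))
  df <- dplyr::bind_cols(
    tibble::tibble(alloc_id = seq_along(pool$D), D = pool$D),
    tibble::as_tibble(as.data.frame(Tm))
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_allocation_pool
#' @export
read_allocation_pool <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write per-unit weights as CSV
#'
#' Columns `unit_id`, `treated`, `weight` (within-arm simplex scale), in
#' the original unit order.
#'
#' @param data A [qrer_data].
#' @param weights Weight vector or matrix (canonical order; a matrix is
#'   averaged).
#' @param path Output CSV path.
#' @export
write_weights_csv <- function(data, weights, path) {
  readr::write_csv(weights_tibble(data, weights), path)
  invisible(path)
}

# echo the effective configuration of a run next to its outputs
write_run_config <- function(config, path, extra = list()) {
  cfg <- c(unclass(config), extra,
           list(package_version = as.character(utils::packageVersion("qrer"))))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
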