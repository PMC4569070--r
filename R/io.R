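# Plain-text serialization for the exchangeable objects: alpha histograms
# (CSV), P_ij tables and fit results (JSON), LMI matrices (CSV).

#' Write / read an alpha histogram as CSV
#'
#' Columns `lower`, `upper`, `count`, one row per bin.
#'
#' @param hist an [alpha_histogram()].
#' @param path file path.
#' @return `read_alpha_histogram` returns an [alpha_histogram()].
#' @export
write_alpha_histogram <- function(hist, path) {
  utils::write.csv(data.frame(lower = hist$edges[-length(hist$edges)],
                              upper = hist$edges[-1],
                              count = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alpha_histogram
#' @export
read_alpha_histogram <- function(path) {
  df <- utils::read.csv(path)
  alpha_histogram(c(df$lower, df$upper[nrow(df)]), df$count)
}

#' Write / read a P_ij table as JSON
#'
#' @param pij a `pij_table`.
#' @param path file path.
#' @return `read_pij` returns a `pij_table`.
#' @export
write_pij <- function(pij, path) {
  obj <- list(gamma_edges = pij$grid$gamma_edges,
              phi_edges = pij$grid$phi_edges,
              alpha_edges = pij$alpha_edges,
              counts = pij$counts,
              mask = pij$mask,
              hist = pij$hist)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_pij
#' @export
read_pij <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- bin_grid(obj$gamma_edges, obj$phi_edges)
  nb <- grid$n_bins
  na <- length(obj$alpha_edges) - 1L
  structure(list(hist = array(obj$hist, dim = c(nb, nb, na)),
                 counts = matrix(obj$counts, nb, nb),
                 mask = matrix(as.logical(obj$mask), nb, nb),
                 alpha_edges = obj$alpha_edges,
                 alpha_mids = (obj$alpha_edges[-1] + obj$alpha_edges[-(na + 1)]) / 2,
                 grid = grid),
            class = "pij_table")
}

#' Write a fit result as JSON
#'
#' Serializes weights, multipliers, achieved chi-squared, entropy and
#' convergence diagnostics.
#'
#' @param fit a `fib_fit`.
#' @param path file path.
#' @export
write_fit <- function(fit, path) {
  obj <- unclass(fit)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(path)
}

#' Write / read an LMI matrix as CSV (residue labels as header)
#'
#' @param lmi an [lmi_matrix()] (or bare matrix for writing).
#' @param path file path.
#' @return `read_lmi_matrix` returns the labelled numeric matrix.
#' @export
write_lmi_matrix <- function(lmi, path) {
  m <- if (inherits(lmi, "lmi_matrix")) lmi$lmi else as.matrix(lmi)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lmi_matrix
#' @export
read_lmi_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  m
}
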