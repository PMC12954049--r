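# Serialization of result artifacts: delimited tables for flat results,
# JSON for nested ones. Numbers are written at full double precision so a
# round trip reproduces the artifact to within print precision (<= 1e-12
# relative error).

#' Write a result artifact to file
#'
#' Dispatches on the artifact class: `ou_fit` and `model_comparison` as
#' one-row delimited tables, `profile_surface` as a long-format
#' (theta, sigma, delta_nll) table, `ou_bootstrap` draws as a table,
#' `separation_result` as structured JSON. Lineage networks are
#' deliberately not handled here - use [export_network()].
#'
#' @param artifact A result object produced by this package.
#' @param path Output path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_results <- function(artifact, path, ...) UseMethod("write_results")

full_precision_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.ou_fit <- function(artifact, path, ...) {
  full_precision_csv(
    data.frame(dataset_id = artifact$dataset_id,
               mu = artifact$params$mu, theta = artifact$params$theta,
               sigma = artifact$params$sigma, nll = artifact$nll,
               k = artifact$k, converged = artifact$converged,
               n_restarts_used = artifact$n_restarts_used),
    path)
}

#' @export
write_results.model_comparison <- function(artifact, path, ...) {
  full_precision_csv(as.data.frame(unclass(artifact)), path)
}

#' @export
write_results.profile_surface <- function(artifact, path, ...) {
  g <- expand.grid(theta = artifact$theta_grid, sigma = artifact$sigma_grid)
  g$delta_nll <- as.vector(artifact$delta_nll)
  g$mu_fixed <- artifact$mu_fixed
  full_precision_csv(g, path)
}

#' @export
write_results.ou_bootstrap <- function(artifact, path, ...) {
  full_precision_csv(artifact$draws, path)
}

#' @export
write_results.separation_result <- function(artifact, path, ...) {
  q <- as.data.frame(artifact$quantiles)
  q <- cbind(metric = rownames(artifact$quantiles), q)
  jsonlite::write_json(
    list(pair = artifact$pair, t_grid = artifact$t_grid,
         convention = artifact$convention, quantiles = q),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE,
    dataframe = "columns")
  invisible(path)
}

#' @export
write_results.therapy_ensemble <- function(artifact, path, ...) {
  full_precision_csv(artifact$summary, path)
}

#' @export
write_results.cure_map <- function(artifact, path, ...) {
  g <- expand.grid(theta = artifact$theta_grid, sigma = artifact$sigma_grid)
  g$p_cure <- as.vector(artifact$p_cure)
  full_precision_csv(g, path)
}

#' @export
write_results.lineage_network <- function(artifact, path, ...) {
  stop("networks are exported by export_network(), not write_results()",
       call. = FALSE)
}

#' @export
write_results.default <- function(artifact, path, ...) {
  stop("no write_results() method for class ",
       paste(class(artifact), collapse = "/"), call. = FALSE)
}

#' Read back a tabular result artifact
#'
#' Counterpart of the table-producing [write_results()] methods; JSON
#' artifacts are read with `jsonlite::read_json`.
#'
#' @param path File written by [write_results()].
#' @return A data frame (delimited tables) or list (JSON).
#' @export
read_results <- function(path) {
  if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else utils::read.csv(path, stringsAsFactors = FALSE)
}
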