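# Trajectory table I/O and detection-floor preprocessing.
#
# Raw observations are non-negative frequencies x_{r,t} in long format
# (lineage, replicate, time, value). Zeros cannot be log-transformed, so a
# lineage-specific detection floor epsilon = 0.5 * min{x > 0} replaces them
# before taking log10. Flooring never decreases a value and is idempotent.

#' Read a long-format trajectory table
#'
#' Reads a delimited text file with one row per observation. The delimiter
#' is auto-detected from the extension (`.csv` comma, otherwise tab) unless
#' given. Rows with a missing value are dropped with a message; negative
#' values and duplicate (lineage, replicate, time) rows are errors.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical names
#'   `lineage`, `replicate`, `time`, `value` to the file's column names.
#' @param sep Field separator; `NULL` to auto-detect from the extension.
#' @return A `data.frame` with columns lineage, replicate, time, value.
#' @export
read_trajectories <- function(path,
                              column_map = c(lineage = "lineage",
                                             replicate = "replicate",
                                             time = "time",
                                             value = "value"),
                              sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("lineage", "replicate", "time", "value")
  cm <- column_map[need]
  if (anyNA(cm))
    stop("`column_map` must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(unname(cm), names(raw))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tab <- data.frame(lineage = as.character(raw[[cm[["lineage"]]]]),
                    replicate = as.character(raw[[cm[["replicate"]]]]),
                    time = as.numeric(raw[[cm[["time"]]]]),
                    value = as.numeric(raw[[cm[["value"]]]]),
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("empty trajectory table: ", path, call. = FALSE)
    return(tab)
  }
  drop <- is.na(tab$value)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing value dropped")
    tab <- tab[!drop, , drop = FALSE]
  }
  validate_trajectories(tab)
  tab
}

validate_trajectories <- function(tab) {
  if (any(!is.finite(tab$time)))
    stop("validation error: non-finite time values", call. = FALSE)
  neg <- which(tab$value < 0)
  if (length(neg))
    stop("validation error: negative value in row ", neg[1L],
         " (frequencies must be >= 0)", call. = FALSE)
  key <- paste(tab$lineage, tab$replicate, tab$time, sep = "\r")
  if (anyDuplicated(key))
    stop("validation error: duplicate (lineage, replicate, time) rows; ",
         "aggregate or deduplicate upstream", call. = FALSE)
  invisible(tab)
}

#' Detection floor for zero replacement
#'
#' Half the smallest strictly positive observation:
#' `epsilon = 0.5 * min(x > 0)`. Computed per lineage, never pooled.
#'
#' @param values Numeric vector of non-negative observations.
#' @return The detection floor, a single positive number.
#' @export
detection_floor <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("values must be non-negative", call. = FALSE)
  pos <- values[is.finite(values) & values > 0]
  if (!length(pos))
    stop("no positive observations; floor undefined", call. = FALSE)
  0.5 * min(pos)
}

#' Floor zeros and transform one lineage to log10
#'
#' Extracts one lineage from a raw trajectory table, computes its detection
#' floor over that lineage's values only, replaces observations below the
#' floor by the floor (`x* = max(x, epsilon)`), and returns the replicate
#' trajectories `y = log10(x*)`.
#'
#' @param table Long-format `data.frame` as from [read_trajectories()], or
#'   an already log10-scaled `lineage_dataset` (returned unchanged, making
#'   the operation idempotent).
#' @param lineage Lineage label to extract.
#' @return A `lineage_dataset`: list with `lineage`, `replicates` (each a
#'   list with strictly increasing `times` and `y`), `epsilon`, `scale`.
#' @export
floor_and_log <- function(table, lineage) {
  if (inherits(table, "lineage_dataset")) {
    if (identical(table$scale, "log10")) return(table)
    stop("`table` is a lineage_dataset on an unexpected scale", call. = FALSE)
  }
  stopifnot(is.data.frame(table))
  validate_trajectories(table)
  sub <- table[table$lineage == lineage, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("lineage not present in table: ", lineage, call. = FALSE)
  eps <- detection_floor(sub$value)
  reps <- lapply(split(sub, sub$replicate), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    list(times = d$time, y = log10(pmax(d$value, eps)))
  })
  lineage_dataset(lineage, reps, eps)
}

#' Construct a lineage dataset
#'
#' Low-level constructor for replicate-grouped log10 trajectories; most
#' users reach this via [floor_and_log()].
#'
#' @param lineage Lineage label.
#' @param replicates Named list; each element a list with `times` (strictly
#'   increasing) and `y` (same length, finite).
#' @param epsilon Detection floor used in preprocessing.
#' @param scale Either `"log10"` or `"raw"`.
#' @export
lineage_dataset <- function(lineage, replicates, epsilon, scale = "log10") {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  for (r in replicates) {
    stopifnot(length(r$times) == length(r$y))
    if (length(r$times) > 1L && any(diff(r$times) <= 0))
      stop("replicate times must be strictly increasing", call. = FALSE)
    if (any(!is.finite(r$y)))
      stop("non-finite y in replicate trajectory", call. = FALSE)
  }
  stop_if_not_scalar(epsilon, "epsilon", positive = TRUE)
  scale <- match.arg(scale, c("log10", "raw"))
  structure(list(lineage = lineage, replicates = replicates,
                 epsilon = epsilon, scale = scale),
            class = "lineage_dataset")
}

#' @export
print.lineage_dataset <- function(x, ...) {
  np <- vapply(x$replicates, function(r) length(r$times), integer(1))
  cat(sprintf("Lineage dataset '%s' (%s scale): %d replicate(s), %d points, epsilon = %.4g\n",
              x$lineage, x$scale, length(x$replicates), sum(np), x$epsilon))
  invisible(x)
}

# Mean of replicate first observations: the default conditioning value y0
# for lineage-level predictive trajectories.
dataset_y0 <- function(data) {
  mean(vapply(data$replicates, function(r) r$y[1L], numeric(1)))
}
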