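# Internal helpers shared across modules.

# Ordered factor of time labels; times are stored numerically (hours).
time_levels <- function(times) sort(unique(as.numeric(times)))

#' Check that a longitudinal table is balanced
#'
#' A design is balanced when every animal is observed exactly once at every
#' time point. The multilevel split and the paired contrasts both assume
#' this.
#'
#' @param data A data frame with at least `animal` and `time` columns.
#' @return Invisibly, the input. Errors if the design is unbalanced.
#' @keywords internal
check_balanced <- function(data) {
  tab <- table(data$animal, data$time)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
    abort(sprintf(
      "Design is not balanced: animal(s) %s are not observed exactly once per time point.",
      paste(utils::head(bad, 5L), collapse = ", ")
    ), class = "acth_design_error")
  }
  invisible(data)
}

#' Convert between long tables and observation matrices
#'
#' `long_to_matrix()` pivots a long (`animal`, `time`, extras, `variable`,
#' `value`) table to a numeric matrix with one row per animal x time and one
#' column per variable, plus a row-annotation tibble. `matrix_to_long()` is
#' its inverse.
#'
#' @param data Long tibble with `animal`, `time`, the feature column and
#'   `value`.
#' @param feature_col Name of the feature column (default `"variable"`).
#' @param values Numeric matrix (rows aligned with `rows`).
#' @param rows Row-annotation tibble as returned by `long_to_matrix()`.
#' @return `long_to_matrix()`: a list with `values` (matrix) and `rows`
#'   (tibble). `matrix_to_long()`: a long tibble.
#' @export
long_to_matrix <- function(data, feature_col = "variable") {
  stopifnot(all(c("animal", "time", feature_col, "value") %in% names(data)))
  anno_cols <- setdiff(names(data), c(feature_col, "value"))
  wide <- tidyr::pivot_wider(
    data,
    names_from = all_of(feature_col),
    values_from = "value"
  ) %>%
    arrange(.data$animal, .data$time)
  feats <- setdiff(names(wide), anno_cols)
  values <- as.matrix(wide[feats])
  rownames(values) <- paste(wide$animal, wide$time, sep = "_")
  list(values = values, rows = wide[anno_cols])
}

#' @rdname long_to_matrix
#' @export
matrix_to_long <- function(values, rows, feature_col = "variable") {
  out <- as_tibble(rows)
  out <- dplyr::bind_cols(out, as_tibble(values, .name_repair = "minimal"))
  tidyr::pivot_longer(
    out,
    cols = -dplyr::all_of(names(rows)),
    names_to = feature_col,
    values_to = "value"
  )
}

#' Deterministic per-stage random seed
#'
#' Derives a reproducible substream seed from a global seed and a stage name,
#' so every pipeline stage draws from its own stream while everything remains
#' a pure function of the single global seed. Values stay inside the 32-bit
#' integer range.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any non-empty string).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  if (!length(chars)) abort("Empty stage name.", class = "acth_param_error")
  off <- sum(chars * seq_along(chars))
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

# Largest-|x| entry made positive; used as the deterministic sign convention
# for every loading vector.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Mean silhouette width of a labelling
#'
#' Measures how well a set of labels (e.g. times of measurement) separates
#' points in a score space: for each point, `(b - a) / max(a, b)` where `a`
#' is the mean distance to its own label's other points and `b` the smallest
#' mean distance to another label. Used to compare multilevel and raw PCA
#' score spaces.
#'
#' @param x Numeric matrix or data frame of coordinates (rows = points).
#' @param labels Label vector, one per row.
#' @return The mean silhouette width (in `[-1, 1]`).
#' @export
mean_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  dm <- as.matrix(dist(x))
  labels <- as.character(labels)
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]
    a <- mean(dm[i, own & seq_len(nrow(x)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(dm[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

stop_if_not_numeric <- function(x, what) {
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", what))
  invisible(x)
}
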