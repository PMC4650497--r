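# Split of a repeated-measures observation matrix into offset, between-animal
# and within-animal components. The within-animal part carries the
# time-related variation free of stable inter-individual differences and is
# the input to multilevel PCA/PLS.

decompose_matrix <- function(x, animal) {
  stopifnot(is.matrix(x), length(animal) == nrow(x))
  grand <- colMeans(x)
  offset <- matrix(grand, nrow(x), ncol(x), byrow = TRUE,
                   dimnames = dimnames(x))
  # rowsum orders groups like table(): by sorted group label
  counts <- as.vector(table(animal))
  animal_means <- rowsum(x, animal) / counts
  per_row_mean <- animal_means[as.character(animal), , drop = FALSE]
  between <- per_row_mean - offset
  within <- x - per_row_mean
  dimnames(between) <- dimnames(x)
  dimnames(within) <- dimnames(x)
  list(offset = offset, between = between, within = within)
}

#' Multilevel split of a repeated-measures table
#'
#' Decomposes each variable's observation vector into three additive parts:
#' the grand-mean offset, the between-animal deviation (the animal's mean
#' over its time points minus the grand mean, constant within animal) and the
#' within-animal deviation (the observation minus the animal's mean). The
#' three parts reconstruct the data exactly; the within-animal component has
#' zero mean inside every animal, the between-animal component has zero
#' column means.
#'
#' @param data A long tibble with `animal`, `time`, `variable`, `value`
#'   (balanced design: every animal seen at every time), or an `expr_study`.
#' @param ... Passed to methods.
#' @return For a data frame: a tibble of class `multilevel_decomp` with the
#'   input columns plus `offset`, `between`, `within`. For an `expr_study`:
#'   the same object with `$values` replaced by the within-animal component
#'   and the other components stored in `$components`.
#' @examples
#' d <- tibble::tibble(
#'   animal = rep(c("a", "b"), each = 2), time = rep(c(0, 1), 2),
#'   variable = "x", value = c(1, 3, 5, 7)
#' )
#' multilevel_decompose(d)
#' @export
multilevel_decompose <- function(data, ...) UseMethod("multilevel_decompose")

#' @rdname multilevel_decompose
#' @export
multilevel_decompose.data.frame <- function(data, ...) {
  check_balanced(distinct(data, .data$animal, .data$time))
  cell_counts <- dplyr::count(data, .data$animal, .data$time)
  if (length(unique(cell_counts$n)) != 1L) {
    abort("Unbalanced table: some animal x time cells miss variables.",
          class = "acth_design_error")
  }
  if (anyNA(data$value)) {
    abort("Missing values present; impute before decomposing.",
          class = "acth_design_error")
  }
  wide <- long_to_matrix(data)
  parts <- decompose_matrix(wide$values, wide$rows$animal)
  long_part <- function(m, nm) {
    matrix_to_long(m, wide$rows) %>% rename(!!nm := "value")
  }
  keys <- c(names(wide$rows), "variable")
  out <- matrix_to_long(wide$values, wide$rows) %>%
    left_join(long_part(parts$offset, "offset"), by = keys) %>%
    left_join(long_part(parts$between, "between"), by = keys) %>%
    left_join(long_part(parts$within, "within"), by = keys)
  class(out) <- c("multilevel_decomp", class(out))
  out
}

#' @rdname multilevel_decompose
#' @export
multilevel_decompose.expr_study <- function(data, ...) {
  check_balanced(data$samples)
  parts <- decompose_matrix(t(data$values), data$samples$animal)
  data$components <- list(offset = t(parts$offset), between = t(parts$between))
  data$values <- t(parts$within)
  note_provenance(data, "multilevel_decompose", list())
}

#' Matrix view of one component of a multilevel decomposition
#'
#' @param x A `multilevel_decomp` tibble.
#' @param component One of `"value"`, `"offset"`, `"between"`, `"within"`.
#' @return List with `values` (samples x variables matrix) and `rows`
#'   (annotation tibble).
#' @export
component_matrix <- function(x, component = "within") {
  stopifnot(component %in% c("value", "offset", "between", "within"))
  keep <- x %>%
    select(dplyr::any_of(c("animal", "time", "batch", "sex")),
           "variable", all_of(component)) %>%
    rename(value = all_of(component))
  long_to_matrix(keep)
}
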