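#' Build a balanced longitudinal study design
#'
#' Creates the sampling frame of an ACTH-challenge study: every animal is
#' observed at every time point (hours relative to the injection), belongs to
#' one rearing batch and has a sex label. The default time grid is the
#' 0, +1, +4, +24 hour kinetic used throughout the package.
#'
#' @param n_animals Number of animals.
#' @param times Numeric vector of time points in hours. Must include 0, the
#'   pre-injection baseline.
#' @param n_batches Number of batches; animals are assigned round-robin.
#' @param sexes Character vector recycled over animals (`"F"`, `"M"`). Use
#'   `"F"` for a single-sex design.
#' @return A tibble with one row per animal x time and columns `animal`,
#'   `time`, `batch`, `sex`.
#' @examples
#' design <- study_design(n_animals = 6, n_batches = 2)
#' table(design$batch, design$time)
#' @export
study_design <- function(n_animals,
                         times = c(0, 1, 4, 24),
                         n_batches = 1L,
                         sexes = c("F", "M")) {
  if (n_animals < 1L) abort("`n_animals` must be >= 1.", class = "acth_param_error")
  if (n_batches < 1L) abort("`n_batches` must be >= 1.", class = "acth_param_error")
  if (!0 %in% times) abort("`times` must include the baseline time 0.", class = "acth_param_error")
  times <- time_levels(times)
  animal <- sprintf("A%03d", seq_len(n_animals))
  batch <- sprintf("B%d", ((seq_len(n_animals) - 1L) %% n_batches) + 1L)
  sex <- rep_len(sexes, n_animals)
  tidyr::expand_grid(
    tibble(animal = animal, batch = batch, sex = sex),
    time = times
  ) %>%
    select("animal", "time", "batch", "sex") %>%
    arrange(.data$animal, .data$time)
}
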