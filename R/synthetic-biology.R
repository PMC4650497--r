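#' Default kinetics of the clinical-biology panel
#'
#' Reference kinetics for the 15 blood variables of a porcine ACTH challenge:
#' plasma cortisol peaking about 2.7-fold above baseline one hour after the
#' injection, free fatty acids rising about 3.2-fold at +1 h, a transient
#' glucose rise at +4 h, granulocytosis with a matching drop in lymphocyte and
#' monocyte proportions at +1/+4 h, a mild decrease of the red-cell
#' compartment, and platelet indices that do not respond. Baselines are on
#' the measurement scale; fold effects multiply the animal-specific baseline
#' at each post-injection time (the fold at t = 0 is 1 by definition).
#'
#' @param fold_cortisol_1h Fold change of cortisol at +1 h (default 2.7).
#' @param fold_ffa_1h Fold change of free fatty acids at +1 h (default 3.21).
#' @return A tibble with one row per variable: `variable`, `baseline`
#'   (measurement scale), `noise_sd` and `animal_sd` (residual and
#'   between-animal SDs, measurement scale), `transform` (the normalising
#'   transform the preprocessing profile applies), and `fold_1`, `fold_4`,
#'   `fold_24`.
#' @export
bio_kinetics <- function(fold_cortisol_1h = 2.7, fold_ffa_1h = 3.21) {
  k <- tibble::tribble(
    ~variable,      ~baseline, ~noise_cv, ~animal_cv, ~transform, ~fold_1, ~fold_4, ~fold_24,
    "cortisol",          35.5,      0.25,       0.20,    "log10",  fold_cortisol_1h, 0.45, 0.70,
    "ffa",               0.16,      0.30,       0.25,     "sqrt",  fold_ffa_1h,      1.10, 1.00,
    "glucose",           7.67,      0.05,       0.05, "identity",  1.00, 1.08, 1.00,
    "white_cells",       17.0,      0.10,       0.10,    "log10",  1.05, 1.05, 1.00,
    "lymphocytes",       56.6,      0.06,       0.08, "identity",  0.82, 0.85, 1.00,
    "monocytes",         7.82,      0.08,       0.10, "identity",  0.85, 0.90, 1.00,
    "granulocytes",      34.2,      0.10,       0.12, "identity",  1.35, 1.30, 1.00,
    "red_cells",         5.48,      0.04,       0.06, "identity",  0.97, 0.95, 0.95,
    "mcv",               53.7,      0.02,       0.05, "identity",  1.00, 1.00, 1.00,
    "hematocrit",        28.7,      0.03,       0.05, "identity",  0.97, 0.94, 0.95,
    "hemoglobin",        9.75,      0.03,       0.05, "identity",  0.97, 0.94, 0.95,
    "rdw",               32.6,      0.01,       0.02, "identity",  1.00, 1.00, 1.00,
    "platelets",        407.0,      0.10,       0.15,    "log10",  1.00, 1.00, 1.00,
    "mpv",              10.05,      0.03,       0.07, "identity",  1.00, 1.00, 1.00,
    "pdw",              10.76,      0.02,       0.03, "identity",  1.00, 1.00, 1.00
  )
  k %>%
    mutate(
      noise_sd = .data$noise_cv * .data$baseline,
      animal_sd = .data$animal_cv * .data$baseline
    ) %>%
    select("variable", "baseline", "noise_sd", "animal_sd", "transform",
           "fold_1", "fold_4", "fold_24")
}

#' Simulate the longitudinal clinical-biology panel
#'
#' Generates blood-variable trajectories for a balanced ACTH-challenge
#' design. Each value is built as
#' `(baseline + U_i) * fold(variable, time) + batch_shift + noise`,
#' i.e. an additive animal random intercept on the measurement scale, a
#' multiplicative kinetic effect (identity at t = 0), an additive per-batch
#' location shift and i.i.d. Gaussian residual noise. Missing values and
#' outliers are injected last.
#'
#' @param design A design tibble from [study_design()].
#' @param kinetics A kinetics tibble as returned by [bio_kinetics()]. A
#'   `fold_<t>` column must exist for every post-baseline time in `design`.
#' @param batch_sd SD of the per-batch additive shift, as a fraction of each
#'   variable's baseline.
#' @param missing_rate,outlier_rate Cell-wise probabilities of masking a
#'   value or replacing it by an outlier.
#' @param outlier_size Outlier magnitude in residual-SD units.
#' @param floor_frac Assay detection floor as a fraction of each variable's
#'   baseline: no recorded measurement falls below it, keeping
#'   positive-support variables (hormone and metabolite concentrations,
#'   counts) positive. Set to `-Inf` to disable.
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return A list of class `acth_bio_sim`:
#' \describe{
#'   \item{data}{long tibble `animal`, `time`, `batch`, `sex`, `variable`,
#'     `value` (contains `NA` where masked)}
#'   \item{truth}{list with the effect table (`variable`, `time`, `fold`),
#'     animal intercepts, batch shifts and the kinetics used}
#'   \item{mask}{tibble of altered cells (`animal`, `time`, `variable`,
#'     `type`)}
#' }
#' @examples
#' sim <- simulate_biology(study_design(8), seed = 1)
#' head(sim$data)
#' @export
simulate_biology <- function(design,
                             kinetics = bio_kinetics(),
                             batch_sd = 0.03,
                             missing_rate = 0.01,
                             outlier_rate = 0.005,
                             outlier_size = 5,
                             floor_frac = 0.02,
                             seed = NULL) {
  check_balanced(design)
  if (nrow(kinetics) == 0L) abort("`kinetics` has no variables.", class = "acth_param_error")
  if (any(kinetics$noise_sd < 0) || any(kinetics$animal_sd < 0) || batch_sd < 0) {
    abort("Standard deviations must be non-negative.", class = "acth_param_error")
  }
  if (!is.null(seed)) set.seed(seed)

  times <- time_levels(design$time)
  post <- setdiff(times, 0)
  fold_cols <- paste0("fold_", post)
  missing_cols <- setdiff(fold_cols, names(kinetics))
  if (length(missing_cols)) {
    abort(sprintf("`kinetics` lacks column(s) %s for the design's time points.",
                  paste(missing_cols, collapse = ", ")),
          class = "acth_param_error")
  }

  effects <- kinetics %>%
    select("variable", all_of(fold_cols)) %>%
    tidyr::pivot_longer(-"variable", names_to = "time", values_to = "fold") %>%
    mutate(time = as.numeric(sub("^fold_", "", .data$time))) %>%
    bind_rows(tibble(variable = kinetics$variable, time = 0, fold = 1)) %>%
    arrange(.data$variable, .data$time)

  animals <- distinct(design, .data$animal, .data$batch, .data$sex)
  intercepts <- tidyr::expand_grid(animal = animals$animal,
                                   variable = kinetics$variable) %>%
    left_join(select(kinetics, "variable", "animal_sd"), by = "variable") %>%
    mutate(intercept = rnorm(dplyr::n(), 0, .data$animal_sd)) %>%
    select("animal", "variable", "intercept")

  batches <- tidyr::expand_grid(batch = sort(unique(design$batch)),
                                variable = kinetics$variable) %>%
    left_join(select(kinetics, "variable", "baseline"), by = "variable") %>%
    mutate(shift = rnorm(dplyr::n(), 0, batch_sd * .data$baseline)) %>%
    select("batch", "variable", "shift")

  data <- tidyr::expand_grid(design, variable = kinetics$variable) %>%
    left_join(select(kinetics, "variable", "baseline", "noise_sd"), by = "variable") %>%
    left_join(effects, by = c("variable", "time")) %>%
    left_join(intercepts, by = c("animal", "variable")) %>%
    left_join(batches, by = c("batch", "variable")) %>%
    mutate(value = (.data$baseline + .data$intercept) * .data$fold +
             .data$shift + rnorm(dplyr::n(), 0, .data$noise_sd)) %>%
    select("animal", "time", "batch", "sex", "variable", "value")

  noisy <- inject_missing_outliers(
    data,
    missing_rate = missing_rate,
    outlier_rate = outlier_rate,
    outlier_size = outlier_size,
    sd_by = left_join(data, select(kinetics, "variable", "noise_sd"),
                      by = "variable")$noise_sd
  )
  # assay detection floor, applied to every recorded value (incl. outliers)
  floor_vals <- floor_frac *
    left_join(noisy$data, select(kinetics, "variable", "baseline"),
              by = "variable")$baseline
  noisy$data$value <- pmax(noisy$data$value, floor_vals)

  structure(
    list(
      data = noisy$data,
      truth = list(effects = effects, intercepts = intercepts,
                   batch_shifts = batches, kinetics = kinetics),
      mask = noisy$mask
    ),
    class = "acth_bio_sim"
  )
}

#' Inject missing values and outliers into a long table
#'
#' Masks cells at random and replaces others by gross outliers, recording
#' every alteration. This emulates the hands-on data cleaning real assay
#' tables require (outlying observations treated as missing after visual
#' inspection).
#'
#' @param data Long tibble with a `value` column.
#' @param missing_rate,outlier_rate Per-cell probabilities in `[0, 1]`.
#'   Masking takes precedence over outlier injection.
#' @param outlier_size Outlier offset in SD units (sign chosen at random).
#' @param sd_by Numeric vector (recycled) giving the SD scale per row; by
#'   default the overall SD of `value`.
#' @param seed Optional integer seed.
#' @return List with `data` (values altered) and `mask` (tibble of altered
#'   cells with a `type` column, `"missing"` or `"outlier"`).
#' @export
inject_missing_outliers <- function(data,
                                    missing_rate = 0,
                                    outlier_rate = 0,
                                    outlier_size = 5,
                                    sd_by = NULL,
                                    seed = NULL) {
  rates <- c(missing_rate, outlier_rate)
  if (any(rates < 0) || any(rates > 1)) {
    abort("Rates must lie in [0, 1].", class = "acth_param_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  if (is.null(sd_by)) sd_by <- stats::sd(data$value, na.rm = TRUE)
  sd_by <- rep_len(sd_by, n)

  u_miss <- runif(n) < missing_rate
  u_out <- !u_miss & (runif(n) < outlier_rate)

  out <- data
  out$value[u_out] <- out$value[u_out] +
    sample(c(-1, 1), sum(u_out), replace = TRUE) * outlier_size * sd_by[u_out]
  out$value[u_miss] <- NA_real_

  mask <- bind_rows(
    mutate(data[u_miss, setdiff(names(data), "value")], type = "missing"),
    mutate(data[u_out, setdiff(names(data), "value")], type = "outlier")
  )
  list(data = out, mask = as_tibble(mask))
}
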