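# Data-cleaning chain: k-NN imputation, normalising transforms, batch-median
# alignment, within-group quantile normalisation, probe filtering. Every
# operation appends a record to the table's provenance log.

#' Provenance log of a processed table
#'
#' Each preprocessing operation appends a record (operation name, parameters)
#' to the object's provenance attribute, so the exact cleaning chain applied
#' to any table can be recovered.
#'
#' @param x A processed tibble or `expr_study`.
#' @return A list of records, each with `op` and `params`.
#' @export
provenance <- function(x) {
  attr(x, "acth_provenance") %||% list()
}

note_provenance <- function(x, op, params = list(), prev = provenance(x)) {
  attr(x, "acth_provenance") <- c(prev, list(list(op = op, params = params)))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing values by k nearest neighbours
#'
#' Rows are the observation units (animal x time); distance between two rows
#' is the root mean squared difference over their shared observed columns,
#' after standardising every column to unit variance. A missing cell is
#' replaced by the (optionally inverse-distance weighted) mean of that column
#' in the `k` nearest rows where it is observed. Observed cells are never
#' altered.
#'
#' @param data Long tibble with `animal`, `time`, `variable`, `value`
#'   columns (extra annotation columns are preserved).
#' @param k Number of neighbours (default 5).
#' @param weighted If `TRUE`, neighbours are weighted by inverse distance;
#'   the default is a plain mean.
#' @return The completed long tibble (same row order), with a provenance
#'   record appended.
#' @examples
#' sim <- simulate_biology(study_design(10), missing_rate = 0.05, seed = 2)
#' filled <- impute_knn(sim$data, k = 5)
#' anyNA(filled$value)
#' @export
impute_knn <- function(data, k = 5L, weighted = FALSE) {
  wide <- long_to_matrix(data)
  x <- wide$values
  if (!anyNA(x)) {
    return(note_provenance(data, "impute_knn", list(k = k, imputed = 0L)))
  }
  all_missing <- colnames(x)[colSums(!is.na(x)) == 0L]
  if (length(all_missing)) {
    abort(sprintf("Column(s) entirely missing, cannot impute: %s.",
                  paste(all_missing, collapse = ", ")),
          class = "acth_impute_error")
  }
  if (any(rowSums(!is.na(x)) == 0L)) {
    abort("Some rows have no observed value at all.", class = "acth_impute_error")
  }

  mu <- colMeans(x, na.rm = TRUE)
  sdev <- apply(x, 2L, sd, na.rm = TRUE)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sdev, "/")

  filled <- x
  need <- which(is.na(x), arr.ind = TRUE)
  for (i in unique(need[, "row"])) {
    shared <- !is.na(z) & matrix(!is.na(z[i, ]), nrow(z), ncol(z), byrow = TRUE)
    diff2 <- sweep(z, 2L, z[i, ])^2
    diff2[!shared] <- NA
    n_shared <- rowSums(shared)
    d <- sqrt(rowMeans(diff2, na.rm = TRUE))
    d[i] <- Inf
    d[n_shared == 0L] <- Inf
    for (j in need[need[, "row"] == i, "col"]) {
      cand <- which(!is.na(x[, j]) & is.finite(d))
      if (!length(cand)) {
        abort(sprintf("No donor row available for column %s.", colnames(x)[j]),
              class = "acth_impute_error")
      }
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      if (weighted) {
        w <- 1 / pmax(d[nb], .Machine$double.eps)
        filled[i, j] <- sum(w * x[nb, j]) / sum(w)
      } else {
        filled[i, j] <- mean(x[nb, j])
      }
    }
  }

  out <- matrix_to_long(filled, wide$rows)
  out <- out[names(data)]
  out <- data %>%
    select(-"value") %>%
    left_join(out, by = setdiff(names(data), "value"))
  note_provenance(as_tibble(out), "impute_knn",
                  list(k = k, weighted = weighted, imputed = nrow(need)),
                  prev = provenance(data))
}

#' Default normalising-transform profile
#'
#' Maps each clinical variable to the transform that makes it approximately
#' Gaussian: log10 for cortisol, platelets and white-cell counts, square root
#' for free fatty acids, identity otherwise.
#'
#' @param variables Character vector of variable names to cover.
#' @return A tibble `variable`, `transform`.
#' @export
transform_profile <- function(variables = bio_kinetics()$variable) {
  tibble(variable = variables) %>%
    mutate(transform = case_when(
      .data$variable %in% c("cortisol", "platelets", "white_cells") ~ "log10",
      .data$variable == "ffa" ~ "sqrt",
      TRUE ~ "identity"
    ))
}

#' Apply per-variable normalising transforms
#'
#' @param data Long tibble with `variable` and `value` columns.
#' @param profile Tibble `variable`, `transform` with transform one of
#'   `"log10"`, `"sqrt"`, `"identity"`. Variables absent from the profile are
#'   left untouched.
#' @return The transformed tibble with a provenance record.
#' @export
apply_transforms <- function(data, profile = transform_profile(unique(data$variable))) {
  bad <- setdiff(profile$transform, c("log10", "sqrt", "identity"))
  if (length(bad)) {
    abort(sprintf("Unknown transform(s): %s.", paste(bad, collapse = ", ")),
          class = "acth_param_error")
  }
  out <- data %>%
    left_join(profile, by = "variable") %>%
    mutate(transform = dplyr::coalesce(.data$transform, "identity"))
  viol_log <- out$transform == "log10" & !is.na(out$value) & out$value <= 0
  viol_sqrt <- out$transform == "sqrt" & !is.na(out$value) & out$value < 0
  if (any(viol_log) || any(viol_sqrt)) {
    i <- which(viol_log | viol_sqrt)[1L]
    abort(sprintf(
      "Transform domain violation at animal %s, time %s, variable %s (value %.4g).",
      out$animal[i], out$time[i], out$variable[i], out$value[i]
    ), class = "acth_transform_error")
  }
  out <- out %>%
    mutate(value = dplyr::case_when(
      .data$transform == "log10" ~ log10(.data$value),
      .data$transform == "sqrt" ~ sqrt(.data$value),
      TRUE ~ .data$value
    )) %>%
    select(-"transform")
  note_provenance(out, "apply_transforms",
                  list(profile = setNames(profile$transform, profile$variable)),
                  prev = provenance(data))
}

#' Align within-batch medians
#'
#' Shifts every batch so that, variable by variable, its median equals the
#' pooled (pre-alignment) median of that variable. A pure location shift:
#' within-batch rank order is preserved and the global location of each
#' variable is unchanged.
#'
#' @param data Long tibble with `batch`, `variable`, `value`.
#' @return The aligned tibble with a provenance record.
#' @export
align_batch_medians <- function(data) {
  empty <- data %>%
    group_by(.data$batch, .data$variable) %>%
    summarise(n_obs = sum(!is.na(.data$value)), .groups = "drop") %>%
    filter(.data$n_obs == 0L)
  if (nrow(empty)) {
    abort(sprintf("Batch %s has no observed values for variable %s.",
                  empty$batch[1L], empty$variable[1L]),
          class = "acth_align_error")
  }
  out <- data %>%
    group_by(.data$variable) %>%
    mutate(.pooled = median(.data$value, na.rm = TRUE)) %>%
    group_by(.data$batch, .data$variable) %>%
    mutate(value = .data$value - median(.data$value, na.rm = TRUE) + .data$.pooled) %>%
    ungroup() %>%
    select(-".pooled")
  note_provenance(out, "align_batch_medians", list(), prev = provenance(data))
}

#' Quantile-normalise samples within groups
#'
#' Within each group of samples (typically the four arrays of one animal),
#' every sample's value vector is replaced so that all samples share the same
#' sorted vector: the per-rank mean across the group's samples. Average ranks
#' are used for ties. The `"median"` mode instead performs the degenerate
#' single-statistic alignment (each sample's median shifted to the group's
#' mean median), which is the within-array median alignment step.
#'
#' @param x An `expr_study` or a numeric matrix (features x samples).
#' @param group Vector assigning each sample (column) to a group; for an
#'   `expr_study` the default is the animal.
#' @param mode `"quantile"` (full normalisation) or `"median"`.
#' @return Object of the same type with normalised values.
#' @export
quantile_normalize_within <- function(x, group = NULL, mode = c("quantile", "median")) {
  mode <- match.arg(mode)
  if (inherits(x, "expr_study")) {
    grp <- group %||% x$samples$animal
    x$values <- quantile_normalize_within(x$values, grp, mode)
    return(note_provenance(x, "quantile_normalize_within", list(mode = mode)))
  }
  stopifnot(is.matrix(x), length(group) == ncol(x))
  out <- x
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 2L) {
      warn(sprintf("Group %s has a single sample; left unchanged.", g))
      next
    }
    sub <- x[, idx, drop = FALSE]
    if (mode == "median") {
      med <- apply(sub, 2L, median)
      out[, idx] <- sweep(sub, 2L, med - mean(med))
    } else {
      ref <- rowMeans(apply(sub, 2L, sort))
      for (j in seq_along(idx)) {
        r <- rank(sub[, j], ties.method = "average")
        lo <- ref[floor(r)]
        hi <- ref[ceiling(r)]
        out[, idx[j]] <- (lo + hi) / 2
      }
    }
  }
  out
}

#' Filter probes against the negative-control background
#'
#' Removes negative-control probes, then keeps a probe only if its signal
#' exceeds the control threshold (control mean + `n_sd` control SDs) in at
#' least `min_expressed_fraction` of samples. With `threshold = "none"` only
#' the control probes are dropped.
#'
#' @param x An `expr_study`.
#' @param min_expressed_fraction Minimum fraction of samples above threshold.
#' @param threshold `"control"` or `"none"`.
#' @param n_sd Control SD multiplier for the threshold.
#' @return The filtered `expr_study`; the removal counts are recorded in the
#'   provenance log and in `attr(, "filter_report")`.
#' @export
filter_probes <- function(x, min_expressed_fraction = 0.5,
                          threshold = c("control", "none"), n_sd = 2) {
  stopifnot(inherits(x, "expr_study"))
  threshold <- match.arg(threshold)
  ctrl <- x$probes$is_control
  n_ctrl_removed <- sum(ctrl)
  vals <- x$values[!ctrl, , drop = FALSE]
  probes <- x$probes[!ctrl, , drop = FALSE]

  n_low <- 0L
  if (threshold == "control") {
    if (!any(ctrl)) {
      abort("Control-based filtering requires flagged negative controls.",
            class = "acth_config_error")
    }
    ctrl_vals <- x$values[ctrl, , drop = FALSE]
    thr <- mean(ctrl_vals) + n_sd * sd(ctrl_vals)
    frac <- rowMeans(vals > thr)
    keep <- frac >= min_expressed_fraction
    n_low <- sum(!keep)
    vals <- vals[keep, , drop = FALSE]
    probes <- probes[keep, , drop = FALSE]
  }

  x$values <- vals
  x$probes <- probes
  report <- list(controls_removed = n_ctrl_removed,
                 below_threshold_removed = n_low,
                 kept = nrow(vals))
  attr(x, "filter_report") <- report
  note_provenance(x, "filter_probes",
                  c(list(min_expressed_fraction = min_expressed_fraction,
                         threshold = threshold, n_sd = n_sd), report))
}
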