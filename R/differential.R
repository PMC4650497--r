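# Time-course testing: repeated-measures ANOVA, sex two-way ANOVA, paired
# contrasts against baseline, multiple-testing control, duplicate-probe
# consolidation and within-subject correlation to the cortisol peak.

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up (FDR control) or Bonferroni (FWER control).
#' `NA` p-values (e.g. zero-variance features) are excluded from the family
#' size and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "BH")
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1].", class = "acth_param_error")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = if (method == "BH") "BH" else "bonferroni")
  out
}

#' Repeated-measures one-way ANOVA per variable
#'
#' Tests the global time effect for each variable with time as the
#' within-subject factor (the subject stratum is removed before forming the
#' error term). P-values are BH-adjusted across variables.
#'
#' @param data Long tibble with `animal`, `time`, `variable`, `value`;
#'   balanced design, no missing values.
#' @return A tibble `variable`, `F`, `df1`, `df2`, `p`, `adj_p` sorted by
#'   `adj_p`.
#' @export
rm_anova <- function(data) {
  check_balanced(distinct(data, .data$animal, .data$time))
  if (dplyr::n_distinct(data$animal) < 2L) {
    abort("At least 2 animals are required.", class = "acth_data_error")
  }
  if (dplyr::n_distinct(data$time) < 2L) {
    abort("At least 2 time points are required.", class = "acth_data_error")
  }
  res <- data %>%
    group_by(.data$variable) %>%
    dplyr::group_modify(function(d, key) {
      d$time_f <- factor(d$time)
      d$animal_f <- factor(d$animal)
      fit <- aov(value ~ time_f + Error(animal_f), data = d)
      tab <- summary(fit)[["Error: Within"]][[1L]]
      ss_time <- tab["time_f", "Sum Sq"]
      # no within-animal variation at all: the time effect is exactly null
      degenerate <- ss_time <= 1e-12 * max(var(d$value), .Machine$double.eps)
      tibble(
        F = if (degenerate) 0 else tab["time_f", "F value"],
        df1 = tab["time_f", "Df"],
        df2 = tab["Residuals", "Df"],
        p = if (degenerate) 1 else tab["time_f", "Pr(>F)"]
      )
    }) %>%
    ungroup()
  res$adj_p <- adjust_pvalues(res$p, "BH")
  arrange(res, .data$adj_p)
}

#' Two-way repeated-measures ANOVA with sex
#'
#' Tests, per variable, the sex main effect (a between-animal factor) in a
#' model with time as the within-animal factor. Sex is tested against the
#' between-animal stratum. P-values are BH-adjusted across variables.
#'
#' @inheritParams rm_anova
#' @return A tibble `variable`, `F_sex`, `df1`, `df2`, `p`, `adj_p`.
#' @export
sex_anova <- function(data) {
  check_balanced(distinct(data, .data$animal, .data$time))
  if (dplyr::n_distinct(data$sex) < 2L) {
    abort("Both sexes must be present.", class = "acth_design_error")
  }
  res <- data %>%
    group_by(.data$variable) %>%
    dplyr::group_modify(function(d, key) {
      d$time_f <- factor(d$time)
      d$sex_f <- factor(d$sex)
      d$animal_f <- factor(d$animal)
      fit <- aov(value ~ sex_f * time_f + Error(animal_f), data = d)
      tab <- summary(fit)[["Error: animal_f"]][[1L]]
      tibble(
        F_sex = tab["sex_f", "F value"],
        df1 = tab["sex_f", "Df"],
        df2 = tab["Residuals", "Df"],
        p = tab["sex_f", "Pr(>F)"]
      )
    }) %>%
    ungroup()
  res$adj_p <- adjust_pvalues(res$p, "BH")
  arrange(res, .data$adj_p)
}

paired_stats <- function(diffs) {
  n <- ncol(diffs)
  md <- rowMeans(diffs)
  s <- sqrt(rowSums((diffs - md)^2) / (n - 1L))
  # all differences exactly 0: no evidence either way (t = 0, p = 1);
  # constant nonzero difference: the statistic is undefined, reported NA
  t_stat <- ifelse(s == 0, ifelse(md == 0, 0, NA_real_), md / (s / sqrt(n)))
  p <- 2 * pt(-abs(t_stat), df = n - 1L)
  tibble(diff = unname(md), t = unname(t_stat), df = n - 1L, p = unname(p))
}

#' Paired contrasts of every post-injection time against baseline
#'
#' For each feature and each time `t > 0`, a classic paired t-test of the
#' within-animal difference `value(t) - value(0)`. The full pooled list of
#' p-values (all features x contrasts) is adjusted in one family — BH for
#' clinical variables, Bonferroni for transcripts, per the respective
#' screening conventions. Features with zero difference variance get `NA`
#' with a warning and do not count towards the family size.
#'
#' @param data Long tibble (`animal`, `time`, `variable`, `value`) or an
#'   `expr_study` (probe-level, vectorised).
#' @param baseline Baseline time (default 0).
#' @param method Adjustment for the pooled p-value list.
#' @param alpha Significance threshold used to call direction.
#' @param ... Passed to methods.
#' @return A tibble `feature`, `contrast`, `diff`, `t`, `df`, `p`, `adj_p`,
#'   `direction` (`"up"`/`"down"` where `adj_p < alpha`, `NA` otherwise).
#' @export
paired_tests <- function(data, baseline = 0, method = c("BH", "bonferroni"),
                         alpha = 0.05, ...) {
  UseMethod("paired_tests")
}

#' @rdname paired_tests
#' @export
paired_tests.data.frame <- function(data, baseline = 0,
                                    method = c("BH", "bonferroni"),
                                    alpha = 0.05, ...) {
  method <- match.arg(method)
  check_balanced(distinct(data, .data$animal, .data$time))
  wide <- long_to_matrix(data)
  finish_paired(wide$values, wide$rows$animal, wide$rows$time,
                baseline, method, alpha, features_in_columns = TRUE)
}

#' @rdname paired_tests
#' @export
paired_tests.expr_study <- function(data, baseline = 0,
                                    method = c("bonferroni", "BH"),
                                    alpha = 0.05, ...) {
  method <- match.arg(method)
  check_balanced(data$samples)
  finish_paired(data$values, data$samples$animal, data$samples$time,
                baseline, method, alpha, features_in_columns = FALSE)
}

finish_paired <- function(values, animal, time, baseline, method, alpha,
                          features_in_columns) {
  if (features_in_columns) values <- t(values)  # features x samples
  times <- time_levels(time)
  if (!baseline %in% times) {
    abort("Baseline time not present in the data.", class = "acth_param_error")
  }
  if (dplyr::n_distinct(animal) < 3L) {
    abort("At least 3 animals are required for paired tests.",
          class = "acth_data_error")
  }
  base_idx <- which(time == baseline)[order(animal[time == baseline])]
  out <- purrr::map_dfr(setdiff(times, baseline), function(tt) {
    idx <- which(time == tt)[order(animal[time == tt])]
    diffs <- values[, idx, drop = FALSE] - values[, base_idx, drop = FALSE]
    st <- paired_stats(diffs)
    tibble(feature = rownames(values) %||% as.character(seq_len(nrow(values))),
           contrast = sprintf("0_vs_%g", tt)) %>%
      dplyr::bind_cols(st)
  })
  if (anyNA(out$t)) {
    warn(sprintf("%d feature x contrast pair(s) have zero difference variance; reported as NA.",
                 sum(is.na(out$t))))
  }
  out$adj_p <- adjust_pvalues(out$p, method)
  out$direction <- dplyr::case_when(
    is.na(out$adj_p) | out$adj_p >= alpha ~ NA_character_,
    out$diff > 0 ~ "up",
    TRUE ~ "down"
  )
  out
}

#' Consolidate duplicated probes into unique genes
#'
#' A gene interrogated by several probes is called differentially expressed
#' only when at least `min_fraction` of its probes are themselves DE (any
#' contrast, adjusted p below `alpha`) and the DE probes are mutually
#' consistent (all pairwise Pearson correlations of their expression at least
#' `min_corr`). Single-probe genes are called on the probe alone. The
#' retained representative is the probe with the smallest adjusted p.
#' The 3/4 rule is generalised to `ceiling(min_fraction * n_probes)` for
#' genes with a different duplication count.
#'
#' @param de Result of [paired_tests()] on the probe-level study.
#' @param expr The `expr_study` the tests were run on.
#' @param min_fraction Minimum fraction of DE probes (default 3/4).
#' @param min_corr Minimum pairwise correlation among DE probes (default
#'   0.65).
#' @param alpha Adjusted-p threshold calling a probe DE.
#' @return A tibble `gene`, `n_probes`, `n_de`, `min_pairwise_cor`, `pass`,
#'   `representative`, `adj_p` (representative's smallest adjusted p),
#'   with unannotated DE probes reported in `attr(, "unannotated")`.
#' @export
consolidate_probes <- function(de, expr, min_fraction = 0.75,
                               min_corr = 0.65, alpha = 0.05) {
  stopifnot(inherits(expr, "expr_study"))
  probe_best <- de %>%
    group_by(.data$feature) %>%
    summarise(adj_p = suppressWarnings(min(.data$adj_p, na.rm = TRUE)),
              .groups = "drop") %>%
    mutate(adj_p = ifelse(is.finite(.data$adj_p), .data$adj_p, NA_real_),
           de = !is.na(.data$adj_p) & .data$adj_p < alpha)
  map <- expr$probes %>%
    filter(!.data$is_control) %>%
    left_join(probe_best, by = c(probe = "feature"))
  unannotated <- filter(map, is.na(.data$gene) & .data$de)
  map <- filter(map, !is.na(.data$gene))

  res <- map %>%
    group_by(.data$gene) %>%
    dplyr::group_modify(function(d, key) {
      n_probes <- nrow(d)
      de_probes <- d$probe[which(d$de)]
      n_de <- length(de_probes)
      min_r <- NA_real_
      if (n_de >= 2L) {
        r <- cor(t(expr$values[de_probes, , drop = FALSE]))
        min_r <- min(r[upper.tri(r)])
      }
      need <- ceiling(min_fraction * n_probes)
      pass <- if (n_probes == 1L) n_de == 1L else {
        n_de >= need && (n_de < 2L || min_r >= min_corr)
      }
      rep_probe <- if (n_de) de_probes[which.min(d$adj_p[match(de_probes, d$probe)])] else NA_character_
      tibble(n_probes = n_probes, n_de = n_de, min_pairwise_cor = min_r,
             pass = pass, representative = rep_probe,
             adj_p = if (n_de) min(d$adj_p[d$de], na.rm = TRUE) else NA_real_)
    }) %>%
    ungroup()
  attr(res, "unannotated") <- unannotated
  res
}

#' Within-subject correlation of every feature to the cortisol peak
#'
#' For each feature and each time point, the Pearson correlation (across
#' animals) between the feature's within-animal deviation at that time and
#' the anchor's within-animal deviation at its peak time (cortisol at +1 h).
#' Significance is the t-test for a Pearson correlation on `n - 2` degrees of
#' freedom; the full feature x time list is BH-adjusted in one family.
#'
#' @param x A `multilevel_decomp` tibble (clinical variables) or a
#'   decomposed `expr_study`.
#' @param anchor Numeric vector of the anchor's within-subject values, one
#'   per animal (sorted by animal), e.g. from [anchor_vector()].
#' @param alpha Significance threshold for the `significant` flag.
#' @param ... Passed to methods.
#' @return A tibble `feature`, `time`, `n`, `r`, `se`, `t`, `p`, `adj_p`,
#'   `significant` (the layout of a correlation-to-cortisol table).
#' @export
correlate_to_anchor <- function(x, anchor, alpha = 0.05, ...) {
  UseMethod("correlate_to_anchor")
}

#' @rdname correlate_to_anchor
#' @export
correlate_to_anchor.multilevel_decomp <- function(x, anchor, alpha = 0.05, ...) {
  cm <- component_matrix(x, "within")
  anchor_correlations(t(cm$values), cm$rows$animal, cm$rows$time, anchor, alpha)
}

#' @rdname correlate_to_anchor
#' @export
correlate_to_anchor.expr_study <- function(x, anchor, alpha = 0.05, ...) {
  anchor_correlations(x$values, x$samples$animal, x$samples$time, anchor, alpha)
}

anchor_correlations <- function(values, animal, time, anchor, alpha) {
  animals <- sort(unique(animal))
  if (length(anchor) != length(animals)) {
    abort("`anchor` must have one value per animal.", class = "acth_align_error")
  }
  out <- purrr::map_dfr(time_levels(time), function(tt) {
    idx <- which(time == tt)[order(animal[time == tt])]
    sub <- values[, idx, drop = FALSE]
    sds <- apply(sub, 1L, sd)
    r <- rep(NA_real_, nrow(sub))
    nz <- sds > 0
    if (any(nz)) r[nz] <- as.vector(cor(t(sub[nz, , drop = FALSE]), anchor))
    n <- length(anchor)
    se <- sqrt(pmax(1 - r^2, 0) / (n - 2L))
    t_stat <- r * sqrt(n - 2L) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    tibble(feature = rownames(sub) %||% as.character(seq_len(nrow(sub))),
           time = tt, n = n, r = r, se = se, t = t_stat, df = n - 2L,
           p = 2 * pt(-abs(t_stat), n - 2L))
  })
  if (anyNA(out$r)) {
    warn(sprintf("%d feature x time pair(s) have zero variance; correlation NA.",
                 sum(is.na(out$r))))
  }
  out$adj_p <- adjust_pvalues(out$p, "BH")
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha
  out
}

#' Within-subject anchor vector at a given time
#'
#' Extracts, per animal, the within-animal deviation of one variable at one
#' time point — typically cortisol at +1 h, the reference measure of adrenal
#' sensitivity to ACTH.
#'
#' @param decomp A `multilevel_decomp` tibble.
#' @param variable Anchor variable name.
#' @param time Anchor time.
#' @return Named numeric vector, one value per animal (sorted by animal).
#' @export
anchor_vector <- function(decomp, variable = "cortisol", time = 1) {
  d <- decomp %>%
    filter(.data$variable == .env$variable, .data$time == .env$time) %>%
    arrange(.data$animal)
  if (!nrow(d)) {
    abort("Anchor variable/time not found in the decomposition.",
          class = "acth_param_error")
  }
  setNames(d$within, d$animal)
}
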