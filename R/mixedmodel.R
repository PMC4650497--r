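# Per-gene linear mixed models: time fixed effects, lymphocyte/granulocyte
# ratio covariate, animal random intercept. Separates transcriptional
# regulation from the leukocyte redistribution that follows a cortisol surge.

#' Lymphocyte-to-granulocyte ratio per observation
#'
#' @param bio Long clinical tibble containing `lymphocytes` and
#'   `granulocytes` variables (proportions).
#' @param log_ratio Optionally log-transform the ratio.
#' @return A tibble `animal`, `time`, `lg_ratio`.
#' @export
lg_ratio <- function(bio, log_ratio = FALSE) {
  out <- bio %>%
    filter(.data$variable %in% c("lymphocytes", "granulocytes")) %>%
    select("animal", "time", "variable", "value") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value") %>%
    mutate(lg_ratio = .data$lymphocytes / .data$granulocytes) %>%
    select("animal", "time", "lg_ratio")
  if (log_ratio) out$lg_ratio <- log(out$lg_ratio)
  out
}

#' Fit the cell-composition mixed model for every gene
#'
#' For each gene, fits by REML the linear mixed model
#' `expression ~ time (factor, baseline reference) + L/G ratio + (1 | animal)`
#' and reports Wald z-tests per coefficient. Because every gene shares the
#' same design, the model is fitted once and refitted with each gene's
#' response, which makes genome-scale screens fast.
#'
#' @param expr An `expr_study` (typically the consolidated gene matrix on the
#'   observed log2 scale).
#' @param lg Tibble `animal`, `time`, `lg_ratio` (see [lg_ratio()]) covering
#'   every sample.
#' @param genes Optional subset of row names to fit.
#' @return A tibble of class `gene_lmm_fits`: `gene`, `term`, `estimate`,
#'   `se`, `statistic`, `p`, `sigma_u` (random-intercept SD), `sigma_e`
#'   (residual SD), `converged`.
#' @export
fit_gene_lmm <- function(expr, lg, genes = NULL) {
  stopifnot(inherits(expr, "expr_study"))
  d <- expr$samples %>%
    left_join(lg, by = c("animal", "time"))
  if (anyNA(d$lg_ratio)) {
    abort("L/G ratio missing for some samples.", class = "acth_align_error")
  }
  if (sd(d$lg_ratio) == 0) {
    abort("L/G ratio is constant: its coefficient is confounded with the intercept.",
          class = "acth_param_error")
  }
  d$time_f <- factor(d$time, levels = time_levels(d$time))
  d$animal_f <- factor(d$animal)

  genes <- genes %||% rownames(expr$values)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) {
    abort(sprintf("Gene(s) not in the matrix: %s.",
                  paste(head(missing, 5L), collapse = ", ")),
          class = "acth_param_error")
  }

  d$y <- expr$values[genes[1L], ]
  base_fit <- lme4::lmer(y ~ time_f + lg_ratio + (1 | animal_f),
                         data = d, REML = TRUE)
  res <- purrr::map_dfr(genes, function(g) {
    fit <- tryCatch(
      suppressMessages(lme4::refit(base_fit, newresp = expr$values[g, ])),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble(gene = g, term = NA_character_, estimate = NA_real_,
                    se = NA_real_, statistic = NA_real_, p = NA_real_,
                    sigma_u = NA_real_, sigma_e = NA_real_, converged = FALSE))
    }
    msgs <- fit@optinfo$conv$lme4$messages
    conv <- is.null(msgs) || length(msgs) == 0L
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    z <- beta / se
    vc <- as.data.frame(lme4::VarCorr(fit))
    tibble(gene = g, term = names(beta), estimate = unname(beta),
           se = unname(se), statistic = unname(z),
           p = 2 * pnorm(-abs(unname(z))),
           sigma_u = vc$sdcor[vc$grp == "animal_f"],
           sigma_e = vc$sdcor[vc$grp == "Residual"],
           converged = conv)
  })
  class(res) <- c("gene_lmm_fits", class(res))
  res
}

#' Time-effect tests adjusted within each time point
#'
#' Wald tests of the time coefficients (each post-baseline level against the
#' baseline reference), BH-adjusted across genes within each time point.
#' Non-converged fits are excluded from the family and reported with `NA`.
#'
#' @param fits A `gene_lmm_fits` tibble.
#' @param alpha FDR threshold for the `significant` flag.
#' @return A tibble `gene`, `time`, `estimate`, `se`, `p`, `adj_p`,
#'   `significant`.
#' @export
test_time_effect <- function(fits, alpha = 0.05) {
  out <- fits %>%
    filter(stringr::str_detect(.data$term, "^time_f")) %>%
    mutate(time = as.numeric(sub("^time_f", "", .data$term)),
           p = if_else(.data$converged, .data$p, NA_real_)) %>%
    group_by(.data$time) %>%
    mutate(adj_p = adjust_pvalues(.data$p, "BH")) %>%
    ungroup() %>%
    mutate(significant = !is.na(.data$adj_p) & .data$adj_p < alpha) %>%
    select("gene", "time", "estimate", "se", "p", "adj_p", "significant")
  arrange(out, .data$time, .data$adj_p)
}

#' L/G-ratio effect tests across genes
#'
#' Wald test of the leukocyte-composition coefficient per gene, BH-adjusted
#' across genes, with the effect direction (a negative coefficient means the
#' gene is over-expressed when the L/G ratio drops, i.e. during
#' glucocorticoid-driven granulocytosis).
#'
#' @inheritParams test_time_effect
#' @return A tibble `gene`, `estimate`, `se`, `p`, `adj_p`, `significant`,
#'   `sign`.
#' @export
test_lg_effect <- function(fits, alpha = 0.05) {
  out <- fits %>%
    filter(.data$term == "lg_ratio") %>%
    mutate(p = if_else(.data$converged, .data$p, NA_real_),
           adj_p = adjust_pvalues(.data$p, "BH"),
           significant = !is.na(.data$adj_p) & .data$adj_p < alpha,
           sign = dplyr::case_when(
             !.data$significant ~ NA_character_,
             .data$estimate < 0 ~ "negative",
             TRUE ~ "positive"
           )) %>%
    select("gene", "estimate", "se", "p", "adj_p", "significant", "sign")
  arrange(out, .data$adj_p)
}

#' @describeIn fit_gene_lmm One row per gene with convergence and variance
#'   components.
#' @param x,... Broom-generic arguments.
#' @export
glance.gene_lmm_fits <- function(x, ...) {
  x %>%
    group_by(.data$gene) %>%
    summarise(sigma_u = first(.data$sigma_u), sigma_e = first(.data$sigma_e),
              converged = first(.data$converged), .groups = "drop")
}
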