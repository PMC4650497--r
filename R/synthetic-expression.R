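#' Default kinetic templates of the four expression clusters
#'
#' Log2 offsets per time point (0, +1, +4, +24 h), unit peak amplitude:
#' cluster 1 peaks at +1 h, cluster 2 peaks at +4 h, cluster 3 dips at +4 h,
#' cluster 4 declines towards +24 h. Null genes are flat.
#'
#' @return A 4 x 4 numeric matrix, rows `cluster1..cluster4`, columns the
#'   time points.
#' @export
kinetic_templates <- function() {
  m <- rbind(
    cluster1 = c(0,  1.0,  0.30,  0.00),
    cluster2 = c(0,  0.30, 1.00,  0.00),
    cluster3 = c(0, -0.50, -1.00, 0.00),
    cluster4 = c(0, -0.30, -0.50, -1.00)
  )
  colnames(m) <- c("0", "1", "4", "24")
  m
}

#' Ground truth of a synthetic expression study
#'
#' Defines the planted structure of the probe-level simulation: which genes
#' belong to which kinetic cluster (the default sizes 18/17/8/22 match the
#' four clusters resolved among 65 unique responsive genes, on top of a large
#' null background), how many probes represent each gene, the per-gene log2
#' effect size, probe noise, the between-animal random-intercept SD and the
#' per-batch shift.
#'
#' @param cluster_sizes Integer vector, genes per kinetic cluster (one entry
#'   per template row).
#' @param n_null Number of flat (null) genes.
#' @param probes_per_gene Probes interrogating each gene (>= 1).
#' @param effect_size Log2 amplitude multiplying the unit templates.
#' @param probe_sd Probe-level residual SD, log2 units.
#' @param animal_sd Between-animal random-intercept SD, log2 units (shared by
#'   all probes of a gene).
#' @param batch_shift Numeric vector of per-batch additive shifts (log2),
#'   recycled over batches.
#' @param n_control_probes Negative-control probes appended to the matrix.
#' @param templates Template matrix as in [kinetic_templates()].
#' @return A list of class `expr_truth` with `genes` (tibble `gene`,
#'   `cluster`, `effect_size`), `probes` (tibble `probe`, `gene`,
#'   `is_control`), and the scalar parameters.
#' @export
expression_truth <- function(cluster_sizes = c(18L, 17L, 8L, 22L),
                             n_null = 900L,
                             probes_per_gene = 3L,
                             effect_size = 1,
                             probe_sd = 0.2,
                             animal_sd = 0.3,
                             batch_shift = c(0.15, -0.15),
                             n_control_probes = 50L,
                             templates = kinetic_templates()) {
  if (length(cluster_sizes) != nrow(templates)) {
    abort("One cluster size per template row is required.", class = "acth_param_error")
  }
  if (any(cluster_sizes < 1L)) {
    abort("Every kinetic cluster must contain at least one gene.",
          class = "acth_param_error")
  }
  if (probes_per_gene < 1L) {
    abort("`probes_per_gene` must be >= 1.", class = "acth_param_error")
  }
  if (probe_sd < 0 || animal_sd < 0) {
    abort("SDs must be non-negative.", class = "acth_param_error")
  }

  cluster <- c(rep(seq_along(cluster_sizes), cluster_sizes),
               rep(NA_integer_, n_null))
  n_genes <- length(cluster)
  genes <- tibble(
    gene = sprintf("G%04d", seq_len(n_genes)),
    cluster = cluster,
    effect_size = ifelse(is.na(cluster), 0, effect_size)
  )
  probes <- tidyr::expand_grid(gene = genes$gene, rep = seq_len(probes_per_gene)) %>%
    mutate(probe = sprintf("%s_P%d", .data$gene, .data$rep), is_control = FALSE) %>%
    select("probe", "gene", "is_control")
  if (n_control_probes > 0L) {
    probes <- bind_rows(probes, tibble(
      probe = sprintf("NEG%03d", seq_len(n_control_probes)),
      gene = NA_character_,
      is_control = TRUE
    ))
  }

  structure(
    list(genes = genes, probes = probes, templates = templates,
         probe_sd = probe_sd, animal_sd = animal_sd,
         batch_shift = batch_shift, probes_per_gene = probes_per_gene),
    class = "expr_truth"
  )
}

#' Simulate a probe-level expression study
#'
#' Builds a log2-scale probe x sample matrix for a balanced design. Each
#' probe value is
#' `mu_gene + effect * template[cluster, time] + U_{gene,animal} + batch + e`,
#' where the gene signal (kinetic template and animal random intercept) is
#' shared by all probes of a gene while the residual `e` is probe-specific.
#' Negative-control probes carry low background signal and no structure.
#'
#' @param design Design tibble from [study_design()] (typically 30 animals x
#'   4 times x 2 batches).
#' @param truth An [expression_truth()] object.
#' @param mu_range Range of per-gene baseline abundance (log2).
#' @param control_mu,control_sd Background level of the negative controls.
#' @param seed Integer seed.
#' @return A list of class `expr_study` with `values` (probe x sample
#'   matrix), `samples` (tibble `sample`, `animal`, `time`, `batch`),
#'   `probes` (probe map) and `truth`.
#' @examples
#' truth <- expression_truth(cluster_sizes = c(2, 2, 2, 2), n_null = 5)
#' sim <- simulate_expression(study_design(6, n_batches = 2), truth, seed = 1)
#' dim(sim$values)
#' @export
simulate_expression <- function(design,
                                truth,
                                mu_range = c(6, 12),
                                control_mu = 4,
                                control_sd = 0.5,
                                seed = NULL) {
  check_balanced(design)
  stopifnot(inherits(truth, "expr_truth"))
  if (!is.null(seed)) set.seed(seed)

  times <- time_levels(design$time)
  t_cols <- colnames(truth$templates)
  if (!all(as.character(times) %in% t_cols)) {
    abort("Template columns do not cover the design's time points.",
          class = "acth_param_error")
  }

  samples <- design %>%
    arrange(.data$animal, .data$time) %>%
    mutate(sample = paste(.data$animal, .data$time, sep = "_")) %>%
    select("sample", "animal", "time", "batch")
  n_s <- nrow(samples)
  genes <- truth$genes
  n_g <- nrow(genes)

  mu <- runif(n_g, mu_range[1], mu_range[2])
  # per-gene kinetic offset for each sample
  tmpl <- rbind(truth$templates, null = 0)
  row_idx <- ifelse(is.na(genes$cluster), nrow(tmpl), genes$cluster)
  offset <- tmpl[row_idx, as.character(samples$time), drop = FALSE] *
    genes$effect_size
  # animal random intercepts, one per gene x animal, shared across probes
  animals <- sort(unique(samples$animal))
  u <- matrix(rnorm(n_g * length(animals), 0, truth$animal_sd),
              n_g, length(animals), dimnames = list(genes$gene, animals))
  # batch shifts
  batches <- sort(unique(samples$batch))
  shift <- setNames(rep_len(truth$batch_shift, length(batches)), batches)

  gene_signal <- mu + offset + u[, samples$animal, drop = FALSE] +
    matrix(shift[samples$batch], n_g, n_s, byrow = TRUE)

  probe_tab <- filter(truth$probes, !.data$is_control)
  g_of_p <- match(probe_tab$gene, genes$gene)
  values <- gene_signal[g_of_p, , drop = FALSE] +
    matrix(rnorm(nrow(probe_tab) * n_s, 0, truth$probe_sd), nrow(probe_tab), n_s)
  rownames(values) <- probe_tab$probe

  ctrl_tab <- filter(truth$probes, .data$is_control)
  if (nrow(ctrl_tab)) {
    ctrl <- matrix(rnorm(nrow(ctrl_tab) * n_s, control_mu, control_sd),
                   nrow(ctrl_tab), n_s, dimnames = list(ctrl_tab$probe, NULL))
    values <- rbind(values, ctrl)
  }
  colnames(values) <- samples$sample
  values <- values[truth$probes$probe, , drop = FALSE]

  structure(
    list(values = values, samples = samples, probes = truth$probes,
         truth = truth),
    class = "expr_study"
  )
}

#' Assemble an expression study from its parts
#'
#' Constructor for the probe x sample container used by the transcriptomic
#' stages: an expression matrix, a sample map and a probe map.
#'
#' @param values Numeric matrix, probes x samples, log2 scale. Column names
#'   must match `samples$sample`.
#' @param samples Tibble `sample`, `animal`, `time`, `batch`.
#' @param probes Tibble `probe`, `gene`, `is_control`; defaults to one
#'   single-probe gene per matrix row.
#' @return An `expr_study` object.
#' @export
expr_study <- function(values, samples, probes = NULL) {
  stopifnot(is.matrix(values), all(c("sample", "animal", "time") %in% names(samples)))
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (!all(samples$sample %in% colnames(values))) {
    abort("Sample map does not match the matrix columns.",
          class = "acth_align_error")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  probes <- probes %||% tibble(probe = rownames(values),
                               gene = rownames(values), is_control = FALSE)
  if (!"batch" %in% names(samples)) samples$batch <- "B1"
  structure(
    list(values = values[, samples$sample, drop = FALSE],
         samples = as_tibble(samples), probes = as_tibble(probes)),
    class = "expr_study"
  )
}

#' Long-format view of an expression study
#'
#' @param x An `expr_study` object.
#' @return A tibble `probe`, `sample`, `animal`, `time`, `batch`, `value`.
#' @export
expr_long <- function(x) {
  stopifnot(inherits(x, "expr_study"))
  as_tibble(x$values, rownames = "probe") %>%
    tidyr::pivot_longer(-"probe", names_to = "sample", values_to = "value") %>%
    left_join(x$samples, by = "sample") %>%
    select("probe", "sample", "animal", "time", "batch", "value")
}

#' @export
print.expr_study <- function(x, ...) {
  cat(sprintf("<expr_study> %d probes x %d samples (%d animals, %d times)\n",
              nrow(x$values), ncol(x$values),
              dplyr::n_distinct(x$samples$animal),
              dplyr::n_distinct(x$samples$time)))
  invisible(x)
}
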