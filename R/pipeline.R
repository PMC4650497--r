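# End-to-end orchestration of the synthetic ACTH-challenge study. Each stage
# reads the upstream stage's files from the run directory, writes its own
# outputs as TSV, and appends a structured record to `pipeline_log.jsonl`, so
# every artifact is regenerable from the config and seed alone.

#' Pipeline configuration
#'
#' Validated bundle of design parameters, thresholds and method switches for
#' the synthetic end-to-end run. Defaults mirror the study layout: 120
#' animals in 3 batches for the clinical panel, the first 30 animals in 2
#' batches for the expression study, 4 kinetic clusters of 18/17/8/22 genes
#' over a 900-gene null background with 3 probes per gene.
#'
#' @param out_dir Run directory (created if needed).
#' @param seed Global integer seed; per-stage substreams are derived from it.
#' @param n_bio_animals,n_bio_batches Clinical-panel design.
#' @param n_expr_animals,n_expr_batches Expression design.
#' @param cluster_sizes,n_null,probes_per_gene,effect_size,probe_sd,animal_sd
#'   Passed to [expression_truth()].
#' @param alpha Adjusted-p threshold for DE calls.
#' @param min_fraction,min_corr Duplicate-probe consolidation rule.
#' @param k_clusters Number of kinetic clusters to cut.
#' @param keepX Genes kept per sparse-PLS component.
#' @param n_comp Latent components for PCA/PLS.
#' @param distance_mode Gene distance (see [gene_distance()]).
#' @param pls_mode Deflation mode (see [fit_pls()]).
#' @param de_adjust Adjustment for the transcript screen (`"bonferroni"`)
#'   and for the clinical contrasts (always BH).
#' @param min_genes,fdr Enrichment reporting rule.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_bio_animals = 120L, n_bio_batches = 3L,
                            n_expr_animals = 30L, n_expr_batches = 2L,
                            cluster_sizes = c(18L, 17L, 8L, 22L),
                            n_null = 900L, probes_per_gene = 3L,
                            effect_size = 1, probe_sd = 0.2, animal_sd = 0.3,
                            alpha = 0.05, min_fraction = 0.75, min_corr = 0.65,
                            k_clusters = 4L, keepX = 10L, n_comp = 2L,
                            distance_mode = "cor_rows",
                            pls_mode = "canonical",
                            de_adjust = "bonferroni",
                            min_genes = 3L, fdr = 0.05) {
  stopifnot(alpha > 0, alpha < 1, min_fraction > 0, min_fraction <= 1,
            min_corr >= -1, min_corr <= 1, fdr > 0, fdr < 1,
            keepX >= 1, k_clusters >= 1, n_comp >= 1)
  if (n_expr_animals > n_bio_animals) {
    abort("Expression animals must be a subset of the clinical-panel animals.",
          class = "acth_param_error")
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_path <- function(cfg, file) file.path(cfg$out_dir, file)

log_stage <- function(cfg, stage, params = list()) {
  rec <- list(stage = stage, seed = cfg$seed, params = params)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE),
      file = stage_path(cfg, "pipeline_log.jsonl"), sep = "\n", append = TRUE)
  invisible(rec)
}

require_stage_file <- function(cfg, file, produced_by) {
  p <- stage_path(cfg, file)
  if (!file.exists(p)) {
    abort(sprintf("Missing artifact '%s'; run %s first.", file, produced_by),
          class = "acth_stage_error")
  }
  p
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

write_tsv_out <- function(x, cfg, file) {
  readr::write_tsv(x, stage_path(cfg, file))
  invisible(x)
}

read_expr_tsv <- function(cfg, matrix_file, sample_file, probe_file, stage) {
  vals <- read_tsv_quiet(require_stage_file(cfg, matrix_file, stage))
  m <- as.matrix(vals[-1L])
  rownames(m) <- vals[[1L]]
  samples <- read_tsv_quiet(require_stage_file(cfg, sample_file, stage))
  probes <- read_tsv_quiet(require_stage_file(cfg, probe_file, stage))
  structure(list(values = m[, samples$sample, drop = FALSE],
                 samples = samples, probes = probes),
            class = "expr_study")
}

write_expr_tsv <- function(expr, cfg, matrix_file, sample_file, probe_file) {
  write_tsv_out(as_tibble(expr$values, rownames = "probe"), cfg, matrix_file)
  write_tsv_out(expr$samples, cfg, sample_file)
  write_tsv_out(expr$probes, cfg, probe_file)
  invisible(expr)
}

#' Pipeline stages
#'
#' Each `run_*` stage consumes the previous stage's TSV artifacts in
#' `config$out_dir`, writes its own, and logs its parameters. [run_all()]
#' chains every stage on synthetic data. Calling a stage whose inputs are
#' missing raises an error naming the stage to run first.
#'
#' @param config A [pipeline_config()].
#' @return Each stage invisibly returns its main in-memory results;
#'   `run_all()` returns a named list of all of them.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bio_design <- study_design(config$n_bio_animals, n_batches = config$n_bio_batches)
  bio <- simulate_biology(bio_design, seed = substream_seed(config$seed, "bio"))
  truth <- expression_truth(
    cluster_sizes = config$cluster_sizes, n_null = config$n_null,
    probes_per_gene = config$probes_per_gene, effect_size = config$effect_size,
    probe_sd = config$probe_sd, animal_sd = config$animal_sd
  )
  expr_design <- study_design(config$n_expr_animals,
                              n_batches = config$n_expr_batches, sexes = "F")
  expr <- simulate_expression(expr_design, truth,
                              seed = substream_seed(config$seed, "expression"))

  write_tsv_out(bio$data, config, "bio_raw.tsv")
  write_tsv_out(bio$truth$effects, config, "truth_bio_effects.tsv")
  write_tsv_out(bio$mask, config, "bio_mask.tsv")
  write_expr_tsv(expr, config, "expr_raw.tsv", "sample_map.tsv", "probe_map.tsv")
  write_tsv_out(truth$genes, config, "truth_genes.tsv")
  log_stage(config, "run_simulate",
            list(n_bio_animals = config$n_bio_animals,
                 n_expr_animals = config$n_expr_animals,
                 cluster_sizes = config$cluster_sizes, n_null = config$n_null))
  invisible(list(bio = bio, expr = expr))
}

#' @rdname pipeline
#' @export
run_preprocess <- function(config) {
  bio <- read_tsv_quiet(require_stage_file(config, "bio_raw.tsv", "run_simulate"))
  bio_clean <- bio %>%
    impute_knn(k = 5L) %>%
    apply_transforms() %>%
    align_batch_medians()
  write_tsv_out(bio_clean, config, "bio_clean.tsv")

  expr <- read_expr_tsv(config, "expr_raw.tsv", "sample_map.tsv",
                        "probe_map.tsv", "run_simulate")
  expr <- quantile_normalize_within(expr, mode = "median")
  expr <- quantile_normalize_within(expr, mode = "quantile")
  expr <- filter_probes(expr)
  write_expr_tsv(expr, config, "expr_clean.tsv", "sample_map.tsv",
                 "probe_map_filtered.tsv")
  log_stage(config, "run_preprocess",
            c(list(k = 5), attr(expr, "filter_report")))
  invisible(list(bio = bio_clean, expr = expr))
}

#' @rdname pipeline
#' @export
run_decompose <- function(config) {
  bio <- read_tsv_quiet(require_stage_file(config, "bio_clean.tsv", "run_preprocess"))
  dec <- multilevel_decompose(bio)
  write_tsv_out(dec, config, "bio_decomposed.tsv")

  expr <- read_expr_tsv(config, "expr_clean.tsv", "sample_map.tsv",
                        "probe_map_filtered.tsv", "run_preprocess")
  expr_w <- multilevel_decompose(expr)
  write_expr_tsv(expr_w, config, "expr_within.tsv", "sample_map.tsv",
                 "probe_map_filtered.tsv")
  log_stage(config, "run_decompose")
  invisible(list(bio = dec, expr_within = expr_w))
}

#' @rdname pipeline
#' @export
run_de <- function(config) {
  bio <- read_tsv_quiet(require_stage_file(config, "bio_clean.tsv", "run_preprocess"))
  global <- rm_anova(bio)
  responding <- global$variable[!is.na(global$adj_p) & global$adj_p < config$alpha]
  contrasts <- paired_tests(filter(bio, .data$variable %in% responding),
                            method = "BH", alpha = config$alpha)
  write_tsv_out(global, config, "bio_anova.tsv")
  write_tsv_out(contrasts, config, "bio_contrasts.tsv")

  expr <- read_expr_tsv(config, "expr_clean.tsv", "sample_map.tsv",
                        "probe_map_filtered.tsv", "run_preprocess")
  de <- paired_tests(expr, method = config$de_adjust, alpha = config$alpha)
  cons <- consolidate_probes(de, expr, min_fraction = config$min_fraction,
                             min_corr = config$min_corr, alpha = config$alpha)
  write_tsv_out(de, config, "de_probes.tsv")
  write_tsv_out(select(cons, -dplyr::any_of("genes")), config, "de_genes.tsv")
  log_stage(config, "run_de",
            list(adjust = config$de_adjust, alpha = config$alpha,
                 n_responding_variables = length(responding),
                 n_de_probes = dplyr::n_distinct(de$feature[!is.na(de$direction)]),
                 n_de_genes = sum(cons$pass)))
  invisible(list(bio_anova = global, bio_contrasts = contrasts,
                 de = de, consolidation = cons))
}

#' @rdname pipeline
#' @export
run_cluster <- function(config) {
  cons <- read_tsv_quiet(require_stage_file(config, "de_genes.tsv", "run_de"))
  expr_w <- read_expr_tsv(config, "expr_within.tsv", "sample_map.tsv",
                          "probe_map_filtered.tsv", "run_decompose")
  genes_w <- gene_matrix(expr_w, cons)
  d <- gene_distance(genes_w, mode = config$distance_mode)
  clust <- hac_ward(d, genes_w, k = config$k_clusters)
  tests <- cluster_time_tests(clust, genes_w)
  write_tsv_out(clust$assignments, config, "cluster_assignments.tsv")
  write_tsv_out(clust$profiles, config, "cluster_profiles.tsv")
  write_tsv_out(tests, config, "cluster_tests.tsv")
  write_tsv_out(
    tibble(step = seq_along(clust$tree$height), height = clust$tree$height,
           merge1 = clust$tree$merge[, 1L], merge2 = clust$tree$merge[, 2L]),
    config, "cluster_linkage.tsv"
  )
  if (requireNamespace("ape", quietly = TRUE)) {
    export_newick(clust, stage_path(config, "cluster_dendrogram.nwk"))
  }
  log_stage(config, "run_cluster",
            list(k = config$k_clusters, distance = config$distance_mode,
                 sizes = as.integer(table(clust$assignments$cluster))))
  invisible(list(clustering = clust, tests = tests, genes_within = genes_w))
}

#' @rdname pipeline
#' @export
run_lmm <- function(config) {
  cons <- read_tsv_quiet(require_stage_file(config, "de_genes.tsv", "run_de"))
  expr <- read_expr_tsv(config, "expr_clean.tsv", "sample_map.tsv",
                        "probe_map_filtered.tsv", "run_preprocess")
  bio <- read_tsv_quiet(require_stage_file(config, "bio_raw.tsv", "run_simulate"))
  genes <- gene_matrix(expr, cons)
  lg <- lg_ratio(impute_knn(bio, k = 5L)) %>%
    filter(.data$animal %in% genes$samples$animal)
  fits <- fit_gene_lmm(genes, lg)
  time_tests <- test_time_effect(fits, alpha = config$alpha)
  lg_tests <- test_lg_effect(fits, alpha = config$alpha)
  write_tsv_out(fits, config, "lmm_fits.tsv")
  write_tsv_out(time_tests, config, "lmm_time_tests.tsv")
  write_tsv_out(lg_tests, config, "lmm_lg_tests.tsv")
  log_stage(config, "run_lmm",
            list(n_genes = dplyr::n_distinct(fits$gene),
                 n_lg_negative = sum(lg_tests$sign == "negative", na.rm = TRUE)))
  invisible(list(fits = fits, time_tests = time_tests, lg_tests = lg_tests))
}

#' @rdname pipeline
#' @export
run_spls <- function(config) {
  cons <- read_tsv_quiet(require_stage_file(config, "de_genes.tsv", "run_de"))
  expr_w <- read_expr_tsv(config, "expr_within.tsv", "sample_map.tsv",
                          "probe_map_filtered.tsv", "run_decompose")
  genes_w <- gene_matrix(expr_w, cons)
  bio_dec <- read_tsv_quiet(require_stage_file(config, "bio_decomposed.tsv",
                                               "run_decompose"))
  bio_w <- bio_dec %>%
    filter(.data$animal %in% genes_w$samples$animal) %>%
    select("animal", "time", "variable", within = "within") %>%
    rename(value = "within") %>%
    long_to_matrix()
  key <- paste(bio_w$rows$animal, bio_w$rows$time, sep = "_")
  x <- t(genes_w$values)[key, , drop = FALSE]
  fit <- fit_spls(x, bio_w$values, n_comp = config$n_comp,
                  keepX = config$keepX, mode = config$pls_mode,
                  scale_x = FALSE, scale_y = TRUE)
  fit$rows <- bio_w$rows
  fit$scores <- dplyr::bind_cols(bio_w$rows,
                                 select(fit$scores, dplyr::starts_with("comp")))
  write_tsv_out(fit$scores, config, "spls_scores.tsv")
  write_tsv_out(fit$x_loadings, config, "spls_gene_loadings.tsv")
  write_tsv_out(fit$y_loadings, config, "spls_bio_loadings.tsv")
  write_tsv_out(selected_variables(fit, "x"), config, "spls_selected_genes.tsv")
  log_stage(config, "run_spls",
            list(keepX = config$keepX, n_comp = config$n_comp,
                 mode = config$pls_mode))
  invisible(list(spls = fit))
}

#' @rdname pipeline
#' @export
run_enrich <- function(config) {
  cons <- read_tsv_quiet(require_stage_file(config, "de_genes.tsv", "run_de"))
  clusters <- read_tsv_quiet(require_stage_file(config, "cluster_assignments.tsv",
                                                "run_cluster"))
  truth <- read_tsv_quiet(require_stage_file(config, "truth_genes.tsv",
                                             "run_simulate"))
  ann <- synthetic_annotation(truth, seed = substream_seed(config$seed, "enrich"))
  reference <- truth$gene
  res <- purrr::map_dfr(sort(unique(clusters$cluster)), function(c_) {
    q <- clusters$gene[clusters$cluster == c_]
    fisher_enrichment(q, reference, ann, min_genes = config$min_genes,
                      fdr = config$fdr) %>%
      mutate(cluster = c_, .before = 1L)
  })
  write_tsv_out(res, config, "enrichment.tsv")
  log_stage(config, "run_enrich",
            list(n_terms_enriched = sum(res$enriched)))
  invisible(list(enrichment = res))
}

#' @rdname pipeline
#' @export
run_all <- function(config) {
  sim <- run_simulate(config)
  pre <- run_preprocess(config)
  dec <- run_decompose(config)
  de <- run_de(config)
  cl <- run_cluster(config)
  lmm <- run_lmm(config)
  spls <- run_spls(config)
  enr <- run_enrich(config)
  invisible(list(simulate = sim, preprocess = pre, decompose = dec, de = de,
                 cluster = cl, lmm = lmm, spls = spls, enrich = enr))
}

#' Synthetic term annotation with planted enrichment
#'
#' Builds an annotation table in which each kinetic cluster has one dedicated
#' term covering most of its genes (plus background genes), alongside purely
#' random terms — a self-contained fixture for the over-representation test.
#'
#' @param truth_genes Tibble `gene`, `cluster` (the simulation truth).
#' @param n_random Number of random background terms.
#' @param coverage Fraction of each cluster's genes annotated to its term.
#' @param seed Integer seed.
#' @return An [annotation_table()].
#' @export
synthetic_annotation <- function(truth_genes, n_random = 20L,
                                 coverage = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  all_genes <- truth_genes$gene
  planted <- purrr::map_dfr(sort(unique(na.omit(truth_genes$cluster))), function(c_) {
    members <- truth_genes$gene[!is.na(truth_genes$cluster) &
                                  truth_genes$cluster == c_]
    take <- sample(members, max(1L, round(coverage * length(members))))
    bg <- sample(setdiff(all_genes, members), length(take))
    tibble(term_id = sprintf("SYN:%04d", c_),
           term_name = sprintf("synthetic cluster %d response", c_),
           gene = c(take, bg))
  })
  random <- purrr::map_dfr(seq_len(n_random), function(i) {
    tibble(term_id = sprintf("SYN:%04d", 100L + i),
           term_name = sprintf("synthetic background term %d", i),
           gene = sample(all_genes, sample(10:60, 1L)))
  })
  annotation_table(bind_rows(planted, random))
}
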