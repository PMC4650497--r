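# Hierarchical ascending classification of DE genes into kinetic clusters,
# and per-cluster time testing at the average-gene level.

#' Gene-level matrix of consolidated DE genes
#'
#' Restricts a probe-level study to the representative probe of every gene
#' passing duplicate-probe consolidation, renaming rows to gene symbols.
#'
#' @param expr An `expr_study`.
#' @param consolidation Output of [consolidate_probes()].
#' @return An `expr_study` with one row per passing gene.
#' @export
gene_matrix <- function(expr, consolidation) {
  stopifnot(inherits(expr, "expr_study"))
  passed <- filter(consolidation, .data$pass)
  if (!nrow(passed)) abort("No gene passed consolidation.", class = "acth_data_error")
  vals <- expr$values[passed$representative, , drop = FALSE]
  rownames(vals) <- passed$gene
  expr$values <- vals
  expr$probes <- tibble(probe = passed$representative, gene = passed$gene,
                        is_control = FALSE)
  expr$components <- NULL
  expr
}

#' Gene-gene kinetic distance
#'
#' Default: the Euclidean distance between rows of the gene-gene Pearson
#' correlation matrix, so two genes are close when they correlate the same
#' way with every other gene. The `"cor_sqrt"` alternative is the common
#' direct transform `sqrt(2 * (1 - r))`.
#'
#' @param x An `expr_study` (typically the within-animal component of the
#'   consolidated gene matrix) or a genes x samples numeric matrix.
#' @param mode `"cor_rows"` (default) or `"cor_sqrt"`.
#' @return A `dist` object over genes.
#' @export
gene_distance <- function(x, mode = c("cor_rows", "cor_sqrt")) {
  mode <- match.arg(mode)
  m <- if (inherits(x, "expr_study")) x$values else x
  if (nrow(m) < 2L) abort("At least 2 genes are required.", class = "acth_data_error")
  sds <- apply(m, 1L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance gene(s): %s.",
                  paste(head(rownames(m)[sds == 0], 5L), collapse = ", ")),
          class = "acth_data_error")
  }
  r <- cor(t(m))
  if (mode == "cor_rows") dist(r) else stats::as.dist(sqrt(pmax(2 * (1 - r), 0)))
}

#' Ward clustering of kinetic profiles
#'
#' Agglomerative clustering with the Ward.D2 criterion, cut at `k` clusters
#' (default 4). When `k` matches the number of canonical kinetic templates,
#' clusters are relabelled so that cluster 1 is the +1 h peak, cluster 2 the
#' +4 h peak, cluster 3 the +4 h dip and cluster 4 the net decrease at +24 h,
#' by best correlation of the cluster's mean profile with the templates.
#'
#' @param d A `dist` from [gene_distance()].
#' @param expr The `expr_study` the distances came from (within-animal
#'   component), used for mean kinetic profiles.
#' @param k Number of clusters.
#' @param templates Template matrix used for relabelling (see
#'   [kinetic_templates()]); set `NULL` to keep raw cut labels.
#' @return An object of class `kinetic_clustering`: the `hclust` tree, `k`,
#'   `assignments` (tibble `gene`, `cluster`), and `profiles` (tibble
#'   `cluster`, `time`, `mean`, `se`, `n_genes`; every gene translated to 0
#'   at t = 0 before averaging).
#' @export
hac_ward <- function(d, expr, k = 4L, templates = kinetic_templates()) {
  n <- attr(d, "Size")
  if (k > n) abort("`k` exceeds the number of genes.", class = "acth_param_error")
  tree <- hclust(d, method = "ward.D2")
  raw <- cutree(tree, k = k)

  m <- expr$values
  times <- time_levels(expr$samples$time)
  # per-gene mean profile over time, translated to 0 at baseline
  prof <- vapply(times, function(tt) {
    rowMeans(m[, expr$samples$time == tt, drop = FALSE])
  }, numeric(nrow(m)))
  prof <- prof - prof[, which(times == 0)]
  colnames(prof) <- as.character(times)

  relabel <- setNames(seq_len(k), seq_len(k))
  if (!is.null(templates) && k == nrow(templates) &&
      all(as.character(times) %in% colnames(templates))) {
    cl_prof <- t(vapply(seq_len(k), function(c_) colMeans(prof[raw == c_, , drop = FALSE]),
                        numeric(length(times))))
    tmpl <- templates[, as.character(times), drop = FALSE]
    score <- cor(t(cl_prof), t(tmpl))  # k x k, raw cluster x template
    remaining_r <- seq_len(k); remaining_c <- seq_len(k)
    while (length(remaining_r)) {
      sub <- score[remaining_r, remaining_c, drop = FALSE]
      best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
      relabel[remaining_r[best[1L]]] <- remaining_c[best[2L]]
      remaining_r <- remaining_r[-best[1L]]
      remaining_c <- remaining_c[-best[2L]]
    }
  }
  cluster <- as.integer(relabel[as.character(raw)])
  assignments <- tibble(gene = rownames(m) %||% names(raw), cluster = cluster)

  profiles <- as_tibble(prof) %>%
    mutate(gene = assignments$gene, cluster = cluster) %>%
    tidyr::pivot_longer(cols = -c("gene", "cluster"),
                        names_to = "time", values_to = "value") %>%
    mutate(time = as.numeric(.data$time)) %>%
    group_by(.data$cluster, .data$time) %>%
    summarise(mean = mean(.data$value),
              se = sd(.data$value) / sqrt(dplyr::n()),
              n_genes = dplyr::n(), .groups = "drop")

  structure(
    list(tree = tree, k = k, assignments = assignments, profiles = profiles,
         relabel = relabel, gene_profiles = prof),
    class = "kinetic_clustering"
  )
}

#' Per-cluster paired time contrasts
#'
#' Averages the member genes of each cluster per animal x time, runs the
#' three paired contrasts against baseline on that average-gene signal, and
#' adjusts p-values with BH within each cluster.
#'
#' @param clustering A `kinetic_clustering`.
#' @param expr The within-animal `expr_study` used for clustering.
#' @param baseline Baseline time.
#' @return A tibble `cluster`, `contrast`, `diff`, `t`, `df`, `p`, `adj_p`.
#' @export
cluster_time_tests <- function(clustering, expr, baseline = 0) {
  stopifnot(inherits(clustering, "kinetic_clustering"))
  purrr::map_dfr(sort(unique(clustering$assignments$cluster)), function(c_) {
    genes <- clustering$assignments$gene[clustering$assignments$cluster == c_]
    if (!length(genes)) {
      warn(sprintf("Cluster %d is empty; skipped.", c_))
      return(tibble())
    }
    avg <- colMeans(expr$values[genes, , drop = FALSE])
    d <- tibble(animal = expr$samples$animal, time = expr$samples$time,
                variable = "avg_gene", value = avg)
    res <- suppressWarnings(
      paired_tests(d, baseline = baseline, method = "BH")
    )
    mutate(select(res, -"feature", -"direction"), cluster = c_, .before = 1L)
  })
}

#' Newick export of the clustering dendrogram
#'
#' @param clustering A `kinetic_clustering`.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_newick <- function(clustering, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Package 'ape' is required for Newick export.")
  }
  phy <- ape::as.phylo(clustering$tree)
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @export
print.kinetic_clustering <- function(x, ...) {
  cat(sprintf("<kinetic_clustering> %d genes in %d clusters (Ward.D2)\n",
              nrow(x$assignments), x$k))
  print(count(x$assignments, .data$cluster))
  invisible(x)
}

#' @describeIn hac_ward Tidy gene-to-cluster assignments.
#' @param x,... Broom-generic arguments.
#' @export
tidy.kinetic_clustering <- function(x, ...) x$assignments

#' @describeIn hac_ward One row per cluster with size and peak behaviour.
#' @export
glance.kinetic_clustering <- function(x, ...) {
  x$profiles %>%
    group_by(.data$cluster) %>%
    summarise(
      n_genes = first(.data$n_genes),
      peak_time = .data$time[which.max(abs(.data$mean))],
      peak_value = .data$mean[which.max(abs(.data$mean))],
      .groups = "drop"
    )
}
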