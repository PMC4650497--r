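# Fisher over-representation test of gene lists against a term annotation.

#' Build an annotation table
#'
#' Normalises a long (term, gene) annotation into the structure the
#' enrichment test expects: gene symbols upper-cased, terms with empty gene
#' sets dropped.
#'
#' @param data Tibble with columns `term_id`, `term_name`, `gene`.
#' @return A tibble of class `annotation_table`.
#' @export
annotation_table <- function(data) {
  stopifnot(all(c("term_id", "term_name", "gene") %in% names(data)))
  out <- data %>%
    mutate(gene = toupper(.data$gene)) %>%
    filter(!is.na(.data$gene), .data$gene != "") %>%
    distinct()
  class(out) <- c("annotation_table", class(out))
  out
}

#' Fisher over-representation test
#'
#' For every annotation term, tests whether the query list is enriched in the
#' term's genes relative to a reference list (all genes expressed on the
#' platform), with a one-sided Fisher exact test on the 2x2 table
#' (query-in-term, query-not-in-term, rest-in-term, rest), BH adjustment
#' across tested terms, and the usual reporting rule: a term is called
#' enriched only when the query overlaps it by at least `min_genes` genes and
#' the adjusted p is below `fdr`.
#'
#' @param query Character vector of query gene symbols (must be a subset of
#'   `reference`; foreign genes are dropped with a warning).
#' @param reference Character vector, the reference gene universe.
#' @param annotation An [annotation_table()].
#' @param min_genes Minimum query-term overlap (default 3).
#' @param fdr FDR threshold for the `enriched` flag (default 0.05).
#' @return A tibble `term_id`, `term_name`, `k` (overlap), `K` (term genes in
#'   reference), `n` (query size), `N` (reference size), `p`, `adj_p`,
#'   `enriched`, sorted by p. Dropped query genes are reported in
#'   `attr(, "dropped")`.
#' @examples
#' ann <- annotation_table(tibble::tibble(
#'   term_id = "T1", term_name = "demo", gene = c("A", "B", "C")
#' ))
#' fisher_enrichment(c("A", "B", "C"), c(LETTERS[1:20]), ann, min_genes = 2)
#' @export
fisher_enrichment <- function(query, reference, annotation,
                              min_genes = 3L, fdr = 0.05) {
  if (nrow(annotation) == 0L) abort("Empty annotation.", class = "acth_param_error")
  query <- unique(toupper(query))
  reference <- unique(toupper(reference))
  dropped <- setdiff(query, reference)
  if (length(dropped)) {
    warn(sprintf("%d query gene(s) absent from the reference were dropped.",
                 length(dropped)))
    query <- intersect(query, reference)
  }
  N <- length(reference)
  n <- length(query)

  res <- annotation %>%
    group_by(.data$term_id, .data$term_name) %>%
    summarise(genes = list(intersect(unique(.data$gene), .env$reference)),
              .groups = "drop") %>%
    mutate(
      K = lengths(.data$genes),
      k = vapply(.data$genes, function(g) length(intersect(g, query)), integer(1))
    ) %>%
    filter(.data$K > 0L) %>%
    mutate(
      n = n, N = N,
      # one-sided over-representation: P(X >= k) under the hypergeometric
      p = phyper(.data$k - 1L, .data$K, N - .data$K, n, lower.tail = FALSE),
      adj_p = adjust_pvalues(.data$p, "BH"),
      enriched = .data$k >= min_genes & .data$adj_p < fdr
    ) %>%
    select("term_id", "term_name", "k", "K", "n", "N", "p", "adj_p", "enriched") %>%
    arrange(.data$p)
  attr(res, "dropped") <- dropped
  res
}
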