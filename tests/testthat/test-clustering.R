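make_gene_study <- function(vals, times = c(0, 1, 4, 24)) {
  n_animals <- ncol(vals) / length(times)
  expr_from_matrix(vals, n_animals = n_animals, times = times)
}

test_that("gene_matrix keeps representatives of passing genes only", {
  set.seed(50)
  vals <- matrix(rnorm(4 * 12), 4, 12,
                 dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
  ex <- expr_from_matrix(vals, n_animals = 3)
  ex$probes <- tibble::tibble(probe = rownames(vals),
                              gene = c("G1", "G1", "G2", "G3"),
                              is_control = FALSE)
  cons <- tibble::tibble(
    gene = c("G1", "G2", "G3"),
    n_probes = c(2, 1, 1), n_de = c(2, 1, 0),
    min_pairwise_cor = c(0.9, NA, NA),
    pass = c(TRUE, TRUE, FALSE),
    representative = c("p2", "p3", NA), adj_p = c(0.01, 0.02, NA)
  )
  gm <- gene_matrix(ex, cons)
  expect_equal(rownames(gm$values), c("G1", "G2"))
  expect_equal(unname(gm$values["G1", ]), unname(vals["p2", ]))
  expect_error(gene_matrix(ex, dplyr::mutate(cons, pass = FALSE)),
               class = "acth_data_error")
})

test_that("gene distances match an explicit double-loop oracle", {
  set.seed(51)
  m <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(paste0("g", 1:6), NULL))
  r <- cor(t(m))

  d1 <- as.matrix(gene_distance(m, mode = "cor_rows"))
  d2 <- as.matrix(gene_distance(m, mode = "cor_sqrt"))
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(d1[i, j], sqrt(sum((r[i, ] - r[j, ])^2)), tolerance = 1e-12)
      expect_equal(d2[i, j], sqrt(2 * (1 - r[i, j])), tolerance = 1e-12)
    }
  }

  expect_error(gene_distance(m[1, , drop = FALSE]), class = "acth_data_error")
  m0 <- rbind(m, g0 = rep(1, 10))
  expect_error(gene_distance(m0), "g0", class = "acth_data_error")
})

test_that("Ward merges follow the Lance-Williams recurrence on 6 points", {
  # stepwise oracle: Ward.D2 updates squared distances by
  # d(AB, C)^2 = ((a + c) d(A,C)^2 + (b + c) d(B,C)^2 - c d(A,B)^2) / (a+b+c)
  set.seed(52)
  x <- matrix(rnorm(12), 6, 2)
  d <- dist(x)
  tree <- hclust(d, method = "ward.D2")

  dm <- as.matrix(d)^2
  sizes <- rep(1, 6)
  active <- as.list(1:6)
  heights <- numeric(5)
  merges <- list()
  for (step in 1:5) {
    n_act <- length(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(n_act - 1)) {
      for (j in (i + 1):n_act) {
        if (dm[i, j] < best_d) { best_d <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(best_d)
    merges[[step]] <- sort(c(active[[i]], active[[j]]))
    a <- sizes[i]; b <- sizes[j]
    new_row <- vapply(seq_len(n_act), function(c_) {
      if (c_ %in% c(i, j)) return(NA_real_)
      cc <- sizes[c_]
      ((a + cc) * dm[i, c_] + (b + cc) * dm[j, c_] - cc * dm[i, j]) /
        (a + b + cc)
    }, numeric(1))
    keep <- setdiff(seq_len(n_act), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    sizes <- c(sizes[keep], a + b)
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
  }
  expect_equal(tree$height, heights, tolerance = 1e-10)
  # same merge composition at every step
  got <- lapply(1:5, function(s) sort(unlist(labels_at <- (function(mr, s) {
    expand <- function(v) {
      out <- integer(0)
      for (e in v) out <- c(out, if (e < 0) -e else expand(mr[e, ]))
      out
    }
    expand(tree$merge[s, ])
  })(tree$merge, s))))
  expect_equal(got, merges)
})

test_that("two well-separated blobs are split perfectly and labels are stable", {
  set.seed(53)
  n_per <- 10
  base <- matrix(rnorm(2 * n_per * 20, 0, 0.1), 2 * n_per, 20)
  base[1:n_per, ] <- base[1:n_per, ] + rep(sin(seq(0, 3, length.out = 20)), each = n_per)
  base[(n_per + 1):(2 * n_per), ] <- base[(n_per + 1):(2 * n_per), ] -
    rep(sin(seq(0, 3, length.out = 20)), each = n_per)
  rownames(base) <- paste0("g", 1:(2 * n_per))
  ex <- expr_from_matrix(base, n_animals = 5)
  d <- gene_distance(ex)
  cl <- hac_ward(d, ex, k = 2, templates = NULL)
  lab <- cl$assignments$cluster
  expect_equal(length(unique(lab[1:n_per])), 1)
  expect_equal(length(unique(lab[(n_per + 1):(2 * n_per)])), 1)
  expect_false(lab[1] == lab[n_per + 1])

  # permutation of gene order does not change the partition
  perm <- sample(2 * n_per)
  ex2 <- ex; ex2$values <- base[perm, ]
  cl2 <- hac_ward(gene_distance(ex2), ex2, k = 2, templates = NULL)
  a1 <- cl$assignments$cluster[match(cl2$assignments$gene, cl$assignments$gene)]
  expect_equal(length(unique(paste(a1, cl2$assignments$cluster))), 2)
})

test_that("k = n gives singletons and k > n errors", {
  set.seed(54)
  m <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
  ex <- expr_from_matrix(m, n_animals = 2)
  d <- gene_distance(ex)
  cl <- hac_ward(d, ex, k = 5, templates = NULL)
  expect_equal(sort(cl$assignments$cluster), 1:5)
  expect_error(hac_ward(d, ex, k = 6), class = "acth_param_error")
})

test_that("template relabelling maps noisy template genes to their own cluster", {
  set.seed(55)
  tmpl <- kinetic_templates()
  n_animals <- 8
  genes_per <- 6
  times <- c(0, 1, 4, 24)
  design <- study_design(n_animals, sexes = "F")
  vals <- do.call(rbind, lapply(1:4, function(c_) {
    t(vapply(seq_len(genes_per), function(g) {
      tmpl[c_, as.character(design$time)] + rnorm(nrow(design), 0, 0.05)
    }, numeric(nrow(design))))
  }))
  rownames(vals) <- paste0("c", rep(1:4, each = genes_per), "_g",
                           rep(seq_len(genes_per), 4))
  samples <- design %>%
    dplyr::mutate(sample = paste(animal, time, sep = "_")) %>%
    dplyr::select(sample, animal, time, batch)
  colnames(vals) <- samples$sample
  ex <- expr_study(vals, samples)
  cl <- hac_ward(gene_distance(ex, mode = "cor_sqrt"), ex, k = 4)
  truth <- rep(1:4, each = genes_per)
  expect_equal(cl$assignments$cluster, truth)

  gl <- glance(cl)
  expect_equal(gl$n_genes, rep(genes_per, 4))
  # cluster 1 peaks at +1 h up; cluster 3 dips at +4 h
  expect_equal(gl$peak_time[1], 1)
  expect_gt(gl$peak_value[1], 0)
  expect_equal(gl$peak_time[3], 4)
  expect_lt(gl$peak_value[3], 0)
  expect_equal(tidy(cl), cl$assignments)
})

test_that("profile summaries are translated to zero at baseline", {
  set.seed(56)
  m <- matrix(rnorm(4 * 12, 10), 4, 12, dimnames = list(paste0("g", 1:4), NULL))
  ex <- expr_from_matrix(m, n_animals = 3)
  cl <- hac_ward(gene_distance(ex), ex, k = 2, templates = NULL)
  base <- cl$profiles[cl$profiles$time == 0, ]
  expect_equal(base$mean, rep(0, nrow(base)))
  expect_equal(unname(cl$gene_profiles[, "0"]), rep(0, 4))
})

test_that("cluster time tests detect planted kinetics at the average-gene level", {
  set.seed(57)
  tmpl <- kinetic_templates()
  n_animals <- 12
  design <- study_design(n_animals, sexes = "F")
  mk <- function(c_, n_genes) {
    t(vapply(seq_len(n_genes), function(g) {
      tmpl[c_, as.character(design$time)] + rnorm(nrow(design), 0, 0.1)
    }, numeric(nrow(design))))
  }
  vals <- rbind(mk(1, 5), mk(3, 5))
  rownames(vals) <- paste0("g", 1:10)
  samples <- design %>%
    dplyr::mutate(sample = paste(animal, time, sep = "_")) %>%
    dplyr::select(sample, animal, time, batch)
  colnames(vals) <- samples$sample
  ex <- expr_study(vals, samples)
  cl <- hac_ward(gene_distance(ex, mode = "cor_sqrt"), ex, k = 2,
                 templates = NULL)
  res <- cluster_time_tests(cl, ex)
  expect_setequal(unique(res$contrast), c("0_vs_1", "0_vs_4", "0_vs_24"))

  # identify which label holds the +1 h peak genes
  lab1 <- cl$assignments$cluster[1]
  peak <- res[res$cluster == lab1 & res$contrast == "0_vs_1", ]
  expect_lt(peak$adj_p, 0.01)
  expect_gt(peak$diff, 0)
  dip <- res[res$cluster != lab1 & res$contrast == "0_vs_4", ]
  expect_lt(dip$adj_p, 0.01)
  expect_lt(dip$diff, 0)
  # template 3 returns to baseline at +24 h: no effect there
  back <- res[res$cluster != lab1 & res$contrast == "0_vs_24", ]
  expect_gt(back$p, 0.05)
})

test_that("mean_silhouette matches the cluster-package reference", {
  set.seed(91)
  x <- matrix(rnorm(40 * 3), 40, 3)
  lab <- rep(1:4, 10)
  ref <- mean(cluster::silhouette(lab, dist(x))[, "sil_width"])
  expect_equal(mean_silhouette(x, lab), ref, tolerance = 1e-12)
  # well-separated groups score near 1
  y <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
             matrix(rnorm(20, 10, 0.01), 10, 2))
  expect_gt(mean_silhouette(y, rep(1:2, each = 10)), 0.99)
})

test_that("the dendrogram exports to a valid Newick string", {
  set.seed(58)
  m <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("g", 1:4), NULL))
  ex <- expr_from_matrix(m, n_animals = 2)
  cl <- hac_ward(gene_distance(ex), ex, k = 2, templates = NULL)
  nwk <- export_newick(cl)
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(paste0("g", 1:4), grepl, logical(1), x = nwk)))
})
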