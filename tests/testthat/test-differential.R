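test_that("BH and Bonferroni hand examples are exact", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.001, rep(0.5, 99)), "bonferroni")[1], 0.1)
  # NA excluded from the family size
  expect_equal(adjust_pvalues(c(0.01, NA, 0.02), "bonferroni"),
               c(0.02, NA, 0.04))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "acth_param_error")
})

test_that("BH matches a brute-force step-up over random vectors", {
  set.seed(30)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_pvalues(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("rm_anova matches a hand-computed sums-of-squares oracle", {
  set.seed(31)
  n <- 4; times <- c(0, 1, 4)
  vals <- matrix(rnorm(n * 3), n, 3)
  d <- tibble::tibble(
    animal = rep(paste0("a", 1:n), each = 3),
    time = rep(times, n),
    variable = "x",
    value = as.vector(t(vals))
  )
  res <- rm_anova(d)

  # oracle: classic within-subject decomposition
  grand <- mean(vals)
  ss_time <- n * sum((colMeans(vals) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(vals) - grand)^2)
  ss_tot <- sum((vals - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- 3 - 1; df2 <- (n - 1) * (3 - 1)
  f_oracle <- (ss_time / df1) / (ss_err / df2)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_equal(res$p, pf(f_oracle, df1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("rm_anova returns F = 0, p = 1 without within-animal variation", {
  d <- tibble::tibble(
    animal = rep(c("a", "b", "c"), each = 2),
    time = rep(c(0, 1), 3),
    variable = "x",
    value = rep(c(1, 5, 9), each = 2)
  )
  res <- rm_anova(d)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("rm_anova F equals the squared paired t on two time points", {
  set.seed(32)
  d <- random_long(8, times = c(0, 1), p = 1, seed = 32)
  f <- rm_anova(d)$F
  tt <- paired_tests(d)
  expect_equal(f, tt$t^2, tolerance = 1e-10)
  expect_equal(rm_anova(d)$p, tt$p, tolerance = 1e-10)
})

test_that("sex_anova finds a planted sex effect and respects the null", {
  set.seed(33)
  design <- study_design(20)
  d <- design %>%
    tidyr::expand_grid(variable = "x") %>%
    dplyr::mutate(value = rnorm(dplyr::n()) + ifelse(sex == "M", 4, 0))
  res <- sex_anova(d)
  expect_lt(res$p, 1e-6)

  d0 <- dplyr::mutate(d, value = rnorm(dplyr::n()))
  expect_gt(sex_anova(d0)$p, 1e-4)

  one_sex <- dplyr::filter(d, sex == "F")
  expect_error(sex_anova(one_sex), class = "acth_design_error")
})

test_that("paired tests reproduce the closed-form t for differences 1,2,3", {
  d <- tibble::tibble(
    animal = rep(c("a", "b", "c"), each = 2),
    time = rep(c(0, 1), 3),
    variable = "x",
    value = c(0, 1, 0, 2, 0, 3)
  )
  res <- paired_tests(d)
  expect_equal(res$contrast, "0_vs_1")
  expect_equal(res$diff, 2)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  # and against stats::t.test as an independent oracle
  oracle <- t.test(c(1, 2, 3))
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
})

test_that("paired tests are antisymmetric under a sign flip", {
  d <- random_long(6, p = 2, seed = 34)
  up <- paired_tests(d)
  dn <- paired_tests(dplyr::mutate(d, value = -value))
  expect_equal(dn$t, -up$t, tolerance = 1e-12)
  expect_equal(dn$p, up$p, tolerance = 1e-12)
})

test_that("paired tests handle degenerate difference vectors as documented", {
  d <- tibble::tibble(
    animal = rep(rep(c("a", "b", "c"), each = 2), 2),
    time = rep(c(0, 1), 6),
    variable = rep(c("zero", "constant"), each = 6),
    value = c(1, 1, 2, 2, 3, 3,   # differences all exactly 0
              0, 2, 1, 3, 5, 7)   # differences constant and nonzero
  )
  expect_warning(res <- paired_tests(d), "zero difference variance")
  zero <- res[res$feature == "zero", ]
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  cst <- res[res$feature == "constant", ]
  expect_true(is.na(cst$t) && is.na(cst$p) && is.na(cst$adj_p))
})

test_that("the pooled adjustment family spans all contrasts", {
  d <- random_long(6, p = 3, seed = 35)
  res <- paired_tests(d)              # 3 variables x 3 contrasts
  expect_equal(nrow(res), 9)
  expect_equal(unname(res$adj_p), unname(bh_stepup(res$p)), tolerance = 1e-12)
  resb <- paired_tests(d, method = "bonferroni")
  expect_equal(unname(resb$adj_p), unname(pmin(resb$p * 9, 1)),
               tolerance = 1e-12)
})

test_that("probe consolidation implements the 3-of-4 + correlation rule", {
  set.seed(36)
  design <- study_design(6, sexes = "F")
  samples <- design %>%
    dplyr::mutate(sample = paste(animal, time, sep = "_")) %>%
    dplyr::select(sample, animal, time, batch)
  base <- rnorm(nrow(samples))
  # gene_pass: 3/4 DE probes tracking one shared profile (r ~ 1)
  # gene_few: only 2/4 probes DE
  # gene_anticor: 3/4 DE but one runs opposite to the others
  # gene_single: one probe, DE
  # gene_pair: 2 probes, both DE (ceiling(0.75 * 2) = 2 needed)
  vals <- rbind(
    p_pass1 = base, p_pass2 = base + 0.01, p_pass3 = base - 0.01, p_pass4 = rnorm(24),
    p_few1 = base, p_few2 = base, p_few3 = rnorm(24), p_few4 = rnorm(24),
    p_anti1 = base, p_anti2 = base, p_anti3 = -base, p_anti4 = rnorm(24),
    p_single = base,
    p_pair1 = base, p_pair2 = base
  )
  colnames(vals) <- samples$sample
  probes <- tibble::tibble(
    probe = rownames(vals),
    gene = c(rep("GPASS", 4), rep("GFEW", 4), rep("GANTI", 4),
             "GSINGLE", rep("GPAIR", 2)),
    is_control = FALSE
  )
  ex <- expr_study(vals, samples, probes)
  de <- tibble::tibble(
    feature = rownames(vals),
    adj_p = c(0.001, 0.002, 0.003, 0.9,   # GPASS: 3 DE
              0.001, 0.002, 0.9, 0.9,     # GFEW: 2 DE
              0.001, 0.002, 0.003, 0.9,   # GANTI: 3 DE, one anti
              0.001,                      # GSINGLE
              0.001, 0.002)               # GPAIR
  )
  res <- consolidate_probes(de, ex)
  get <- function(g) res[res$gene == g, ]
  expect_true(get("GPASS")$pass)
  expect_equal(get("GPASS")$representative, "p_pass1")
  expect_false(get("GFEW")$pass)
  expect_false(get("GANTI")$pass)
  expect_lt(get("GANTI")$min_pairwise_cor, 0.65)
  expect_true(get("GSINGLE")$pass)
  expect_true(get("GPAIR")$pass)
  expect_equal(get("GPASS")$n_de, 3)
})

test_that("consolidation agrees with a brute-force rule check on random input", {
  set.seed(37)
  design <- study_design(5, sexes = "F")
  samples <- design %>%
    dplyr::mutate(sample = paste(animal, time, sep = "_")) %>%
    dplyr::select(sample, animal, time, batch)
  n_genes <- 60
  probes_per <- sample(1:4, n_genes, replace = TRUE)
  probes <- tibble::tibble(
    gene = rep(sprintf("G%03d", 1:n_genes), probes_per),
    probe = paste0(gene, "_p", unlist(lapply(probes_per, seq_len))),
    is_control = FALSE
  )
  vals <- matrix(rnorm(nrow(probes) * nrow(samples)), nrow(probes),
                 dimnames = list(probes$probe, samples$sample))
  ex <- expr_study(vals, samples, probes[, c("probe", "gene", "is_control")])
  de <- tibble::tibble(feature = probes$probe,
                       adj_p = sample(c(0.001, 0.2), nrow(probes),
                                      replace = TRUE))
  res <- consolidate_probes(de, ex, alpha = 0.05)

  for (g in unique(probes$gene)) {
    pr <- probes$probe[probes$gene == g]
    de_pr <- pr[de$adj_p[match(pr, de$feature)] < 0.05]
    need <- ceiling(0.75 * length(pr))
    ok_count <- if (length(pr) == 1L) length(de_pr) == 1L else length(de_pr) >= need
    ok_corr <- TRUE
    if (length(de_pr) >= 2L) {
      r <- cor(t(vals[de_pr, , drop = FALSE]))
      ok_corr <- min(r[upper.tri(r)]) >= 0.65
    }
    expect_equal(res$pass[res$gene == g], ok_count && ok_corr)
  }
})

test_that("unannotated DE probes are reported, not silently dropped", {
  design <- study_design(4, sexes = "F")
  samples <- design %>%
    dplyr::mutate(sample = paste(animal, time, sep = "_")) %>%
    dplyr::select(sample, animal, time, batch)
  set.seed(38)
  vals <- matrix(rnorm(2 * 16), 2, 16,
                 dimnames = list(c("p1", "p2"), samples$sample))
  probes <- tibble::tibble(probe = c("p1", "p2"), gene = c("G1", NA),
                           is_control = FALSE)
  ex <- expr_study(vals, samples, probes)
  de <- tibble::tibble(feature = c("p1", "p2"), adj_p = c(0.01, 0.01))
  res <- consolidate_probes(de, ex)
  expect_equal(res$gene, "G1")
  expect_equal(attr(res, "unannotated")$probe, "p2")
})

test_that("anchor correlation of the anchor with itself is exactly 1", {
  d <- random_long(10, p = 2, seed = 39)
  dec <- multilevel_decompose(
    dplyr::bind_rows(d, dplyr::mutate(dplyr::filter(d, variable == "v1"),
                                      variable = "cortisol"))
  )
  anchor <- anchor_vector(dec, "cortisol", time = 1)
  res <- correlate_to_anchor(dec, anchor)
  self <- res[res$feature == "cortisol" & res$time == 1, ]
  expect_equal(self$r, 1)
  expect_equal(res$df, rep(10 - 2, nrow(res)))
  # v1 is a copy of cortisol so its +1 h correlation is also exactly 1
  expect_equal(res$r[res$feature == "v1" & res$time == 1], 1)
})

test_that("anchor correlation recovers a planted correlation and the null rate", {
  set.seed(40)
  n <- 120
  # null: raw-p rejection rate close to alpha
  d <- random_long(n, p = 10, seed = 41)
  dec <- multilevel_decompose(d)
  anchor <- anchor_vector(dec, "v1", time = 1)
  res <- correlate_to_anchor(dec, anchor)
  null_res <- res[res$feature != "v1" | res$time != 1, ]
  rate <- mean(null_res$p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), nrow(null_res), 0.05) / nrow(null_res)
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])

  # planted r = 0.45 construction recovered within sampling error
  a <- rnorm(n)
  rho <- 0.45
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  d2 <- tibble::tibble(
    animal = rep(sprintf("A%03d", 1:n), each = 2),
    time = rep(c(0, 1), n),
    variable = "x",
    value = as.vector(rbind(-b, b))  # within at +1 h is exactly b
  )
  dec2 <- multilevel_decompose(d2)
  res2 <- correlate_to_anchor(dec2, a[order(sprintf("A%03d", 1:n))])
  got <- res2$r[res2$time == 1]
  expect_lt(abs(got - cor(a, b)), 1e-10)
  expect_lt(abs(got - 0.45), 0.1)
  # closed-form se and t
  expect_equal(res2$se[res2$time == 1], sqrt((1 - got^2) / (n - 2)),
               tolerance = 1e-12)
  expect_equal(res2$t[res2$time == 1], got * sqrt(n - 2) / sqrt(1 - got^2),
               tolerance = 1e-10)

  expect_error(correlate_to_anchor(dec2, a[1:10]), class = "acth_align_error")
})
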