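# PCA, PLS and sparse PLS with a deterministic sign convention. The PLS/sPLS
# solver is a NIPALS iteration on the cross-covariance matrix with SVD
# initialisation; sparsity is a per-component cardinality constraint applied
# by soft-thresholding the loading vector.

new_latent_model <- function(method, scores, x_loadings, rows,
                             y_scores = NULL, y_loadings = NULL,
                             explained_variance = NULL,
                             keepX = NULL, keepY = NULL,
                             center = NULL, scale = NULL) {
  structure(
    list(method = method, scores = scores, x_loadings = x_loadings,
         rows = rows, y_scores = y_scores, y_loadings = y_loadings,
         explained_variance = explained_variance,
         keepX = keepX, keepY = keepY, center = center, scale = scale),
    class = "latent_model"
  )
}

# Accepts a numeric matrix, a wide numeric data frame, a long tibble
# (variable/value) or a multilevel_decomp (then uses the requested
# component). Returns list(values, rows).
as_latent_input <- function(x, component = "within") {
  if (inherits(x, "multilevel_decomp")) return(component_matrix(x, component))
  if (is.matrix(x)) {
    return(list(values = x, rows = tibble(.row = seq_len(nrow(x)))))
  }
  if (is.data.frame(x) && all(c("variable", "value") %in% names(x))) {
    return(long_to_matrix(x))
  }
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    return(list(values = as.matrix(x[num]), rows = as_tibble(x[!num])))
  }
  abort("Unsupported input for a latent model.", class = "acth_param_error")
}

#' Principal component analysis with a fixed sign convention
#'
#' Thin wrapper around the singular value decomposition: components are
#' ordered by decreasing explained variance and each loading vector is
#' flipped so its largest-magnitude entry is positive, making results
#' reproducible across linear-algebra backends. Applied to the within-animal
#' component of a [multilevel_decompose()] output this is the multilevel PCA.
#'
#' @param x Numeric matrix / wide data frame (rows = observations), a long
#'   tibble with `variable`/`value`, or a `multilevel_decomp` (the `within`
#'   component is used unless `component` says otherwise).
#' @param n_comp Number of components.
#' @param center,scale Centre/scale columns before the fit. Unit scaling is
#'   the sensible default for clinical variables on heterogeneous scales;
#'   use `scale = FALSE` for log-expression data.
#' @param component Component to use when `x` is a `multilevel_decomp`.
#' @return A `latent_model` with scores, loadings and per-component explained
#'   variance.
#' @examples
#' sim <- simulate_biology(study_design(12), seed = 3)
#' dec <- multilevel_decompose(sim$data)
#' fit <- fit_pca(dec, n_comp = 2)
#' glance(fit)
#' @export
fit_pca <- function(x, n_comp = 2L, center = TRUE, scale = TRUE,
                    component = "within") {
  inp <- as_latent_input(x, component)
  m <- inp$values
  if (scale) {
    zero <- colnames(m)[apply(m, 2L, sd) == 0]
    if (length(zero)) {
      abort(sprintf("Cannot unit-scale zero-variance column(s): %s.",
                    paste(zero, collapse = ", ")),
            class = "acth_scale_error")
    }
  }
  if (n_comp > min(dim(m))) {
    abort("`n_comp` exceeds the matrix rank bound.", class = "acth_param_error")
  }
  fit <- prcomp(m, center = center, scale. = scale, rank. = n_comp)
  rot <- fit$rotation
  scores <- fit$x
  for (h in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, h]))
    if (rot[i, h] < 0) {
      rot[, h] <- -rot[, h]
      scores[, h] <- -scores[, h]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  comp_names <- paste0("comp", seq_len(n_comp))
  colnames(rot) <- comp_names
  colnames(scores) <- comp_names
  new_latent_model(
    method = "PCA",
    scores = dplyr::bind_cols(inp$rows, as_tibble(scores)),
    x_loadings = as_tibble(rot, rownames = "variable"),
    rows = inp$rows,
    explained_variance = ev[seq_len(n_comp)],
    center = if (isTRUE(center)) colMeans(inp$values) else NULL,
    scale = scale
  )
}

soft_threshold_keep <- function(u, keep) {
  p <- length(u)
  if (is.null(keep) || keep >= p) return(u)
  if (keep < 1L) abort("keep must be >= 1.", class = "acth_param_error")
  ord <- order(-abs(u), seq_along(u))
  kept <- ord[seq_len(keep)]
  lam <- max(abs(u[ord[-seq_len(keep)]]))
  out <- numeric(p)
  shrunk <- sign(u[kept]) * (abs(u[kept]) - lam)
  # exact ties at the threshold keep their slot with a vanishing weight so the
  # cardinality is exactly `keep`
  shrunk[shrunk == 0] <- sign(u[kept][shrunk == 0]) * .Machine$double.eps
  out[kept] <- shrunk
  out
}

pls_core <- function(X, Y, n_comp, keepX = NULL, keepY = NULL,
                     mode = "canonical", tol = 1e-9, max_iter = 500L) {
  p <- ncol(X); q <- ncol(Y)
  U <- matrix(0, p, n_comp); V <- matrix(0, q, n_comp)
  Xi <- matrix(0, nrow(X), n_comp); Om <- matrix(0, nrow(Y), n_comp)
  for (h in seq_len(n_comp)) {
    M <- crossprod(X, Y)
    sv <- svd(M, nu = 1L, nv = 1L)
    u <- sv$u[, 1L]; v <- sv$v[, 1L]
    kx <- if (is.null(keepX)) NULL else keepX[min(h, length(keepX))]
    ky <- if (is.null(keepY)) NULL else keepY[min(h, length(keepY))]
    for (it in seq_len(max_iter)) {
      u_old <- u
      u <- as.vector(M %*% v)
      u <- soft_threshold_keep(u, kx)
      u <- u / sqrt(sum(u^2))
      v <- as.vector(crossprod(M, u))
      v <- soft_threshold_keep(v, ky)
      v <- v / sqrt(sum(v^2))
      if (max(abs(u - u_old)) < tol) break
    }
    su <- sign(u[which.max(abs(u))]); if (su < 0) u <- -u
    svn <- sign(v[which.max(abs(v))]); if (svn < 0) v <- -v
    xi <- as.vector(X %*% u)
    om <- as.vector(Y %*% v)
    U[, h] <- u; V[, h] <- v; Xi[, h] <- xi; Om[, h] <- om
    cx <- as.vector(crossprod(X, xi)) / sum(xi^2)
    X <- X - tcrossprod(xi, cx)
    if (mode == "canonical") {
      ey <- as.vector(crossprod(Y, om)) / sum(om^2)
      Y <- Y - tcrossprod(om, ey)
    } else {
      dy <- as.vector(crossprod(Y, xi)) / sum(xi^2)
      Y <- Y - tcrossprod(xi, dy)
    }
  }
  list(U = U, V = V, Xi = Xi, Om = Om)
}

prep_block <- function(inp, center, scale, what) {
  m <- inp$values
  if (scale) {
    zero <- colnames(m)[apply(m, 2L, sd) == 0]
    if (length(zero)) {
      abort(sprintf("Cannot unit-scale zero-variance %s column(s): %s.",
                    what, paste(zero, collapse = ", ")),
            class = "acth_scale_error")
    }
  }
  scale(m, center = center, scale = scale)
}

#' Partial least squares between two blocks
#'
#' Canonical-mode PLS (the default, symmetric in the two blocks, as used for
#' omics integration) or regression-mode PLS. The first component's loading
#' pair maximises the covariance of the block scores; later components act on
#' blocks deflated by regression on the preceding scores. Run on the
#' within-animal components of both blocks this is the multilevel PLS.
#'
#' @param x,y Inputs for the two blocks, any format accepted by [fit_pca()].
#'   Rows must be aligned (same animal x time order).
#' @param n_comp Number of components.
#' @param mode `"canonical"` or `"regression"` deflation.
#' @param scale_x,scale_y Unit-scale the block columns.
#' @param keepX,keepY Optional per-component cardinality constraints
#'   (vectors recycled over components); this is [fit_spls()].
#' @param component Component used for `multilevel_decomp` inputs.
#' @return A `latent_model` with block scores and loadings; for sparse fits
#'   the kept-variable sets per component.
#' @export
fit_pls <- function(x, y, n_comp = 2L, mode = c("canonical", "regression"),
                    scale_x = TRUE, scale_y = TRUE,
                    keepX = NULL, keepY = NULL, component = "within") {
  mode <- match.arg(mode)
  ix <- as_latent_input(x, component)
  iy <- as_latent_input(y, component)
  if (nrow(ix$values) != nrow(iy$values)) {
    abort("Blocks have different numbers of rows.", class = "acth_align_error")
  }
  if (!is.null(keepX) && any(keepX > ncol(ix$values))) {
    abort("keepX exceeds the number of X variables.", class = "acth_param_error")
  }
  if (!is.null(keepY) && any(keepY > ncol(iy$values))) {
    abort("keepY exceeds the number of Y variables.", class = "acth_param_error")
  }
  X <- prep_block(ix, TRUE, scale_x, "X")
  Y <- prep_block(iy, TRUE, scale_y, "Y")
  fit <- pls_core(X, Y, n_comp, keepX = keepX, keepY = keepY, mode = mode)
  comp_names <- paste0("comp", seq_len(n_comp))
  dimnames(fit$U) <- list(colnames(X), comp_names)
  dimnames(fit$V) <- list(colnames(Y), comp_names)
  colnames(fit$Xi) <- comp_names
  colnames(fit$Om) <- comp_names
  new_latent_model(
    method = if (is.null(keepX) && is.null(keepY)) "PLS" else "sPLS",
    scores = dplyr::bind_cols(ix$rows, as_tibble(fit$Xi)),
    x_loadings = as_tibble(fit$U, rownames = "variable"),
    rows = ix$rows,
    y_scores = dplyr::bind_cols(iy$rows, as_tibble(fit$Om)),
    y_loadings = as_tibble(fit$V, rownames = "variable"),
    keepX = keepX, keepY = keepY, scale = c(x = scale_x, y = scale_y)
  )
}

#' @rdname fit_pls
#' @export
fit_spls <- function(x, y, n_comp = 2L, keepX, keepY = NULL, ...) {
  fit_pls(x, y, n_comp = n_comp, keepX = keepX, keepY = keepY, ...)
}

#' Variables selected by a sparse PLS fit
#'
#' @param object A `latent_model` from [fit_spls()].
#' @param block `"x"` or `"y"`.
#' @return A tibble `component`, `variable`, `loading` restricted to nonzero
#'   loadings.
#' @export
selected_variables <- function(object, block = c("x", "y")) {
  block <- match.arg(block)
  load <- if (block == "x") object$x_loadings else object$y_loadings
  tidyr::pivot_longer(load, -"variable",
                      names_to = "component", values_to = "loading") %>%
    filter(.data$loading != 0) %>%
    arrange(.data$component, dplyr::desc(abs(.data$loading)))
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> %s, %d component(s), %d observation(s)\n",
              x$method, ncol(x$x_loadings) - 1L, nrow(x$scores)))
  if (!is.null(x$explained_variance)) {
    cat("explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn fit_pca Tidy loadings of a latent model (one row per
#'   variable x component).
#' @param ... Unused, for generic consistency.
#' @export
tidy.latent_model <- function(x, ...) {
  xl <- tidyr::pivot_longer(x$x_loadings, -"variable",
                            names_to = "component", values_to = "loading") %>%
    mutate(block = "x")
  if (!is.null(x$y_loadings)) {
    yl <- tidyr::pivot_longer(x$y_loadings, -"variable",
                              names_to = "component", values_to = "loading") %>%
      mutate(block = "y")
    xl <- bind_rows(xl, yl)
  }
  select(xl, "block", "component", "variable", "loading")
}

#' @describeIn fit_pca One-row summary of a latent model.
#' @export
glance.latent_model <- function(x, ...) {
  tibble(
    method = x$method,
    n_comp = ncol(x$x_loadings) - 1L,
    n_obs = nrow(x$scores),
    var_explained_1 = if (!is.null(x$explained_variance)) x$explained_variance[1L] else NA_real_,
    total_var_explained = if (!is.null(x$explained_variance)) sum(x$explained_variance) else NA_real_
  )
}
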