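# ica_core: FastICA decomposition with deterministic conventions.
#
# Model: centered expression E_c (genes x samples) ~ S %*% W, with
# S (genes x k) holding statistically independent gene-loading sources and
# W (k x samples) the per-sample mixing weights. Conventions making the fit
# reproducible and the top-gene step well defined:
#   * each column of S is scaled to unit variance (W rescaled to compensate),
#   * each column of S is flipped so its skewness is >= 0,
#   * components are ordered by decreasing explained variance of their W row.

#' Fit an independent component decomposition of an expression matrix
#'
#' Symmetric (parallel-extraction) FastICA with the logcosh contrast, run on
#' the double-centered expression matrix after PCA whitening to `k`
#' dimensions. Deterministic given `(expr, k, seed)`.
#'
#' @param expr Gene x sample numeric matrix (log-scale expression).
#' @param k Number of components; must not exceed `min(dim(expr)) - 1`.
#' @param seed Integer seed controlling the random orthogonal start.
#' @param max_iter Maximum fixed-point iterations (default 1000).
#' @param tol Convergence tolerance on the rotation update (default 1e-6).
#' @param alpha Logcosh contrast parameter in [1, 2] (default 1).
#' @return An object of class `ica_decomposition`: list with `S`
#'   (genes x k), `W` (k x samples), `k`, `center` (the double-centered
#'   matrix's row/column means, for reconstruction), `converged`,
#'   `iterations`, `seed`.
#' @export
fit_ica <- function(expr, k, seed = 1L, max_iter = 1000L, tol = 1e-6,
                    alpha = 1) {
  assert_matrix_named(expr, "expr")
  k <- as.integer(k)
  if (anyNA(expr)) stopf("NaN/NA in expression input")
  n_genes <- nrow(expr); n_samples <- ncol(expr)
  if (k < 1 || k > min(n_genes, n_samples) - 1L)
    stopf("k=%d out of range [1, %d]", k, min(n_genes, n_samples) - 1L)

  rm_ <- rowMeans(expr)
  xc <- expr - rm_
  cm_ <- colMeans(xc)
  xc <- sweep(xc, 2, cm_, "-")

  sv <- svd(xc, nu = k, nv = k)
  if (sv$d[k] < 1e-12 * sv$d[1])
    stopf("k=%d exceeds the numerical rank of the centered matrix", k)
  # Whitened gene-space representation: columns orthonormal -> unit variance
  Y <- sv$u * sqrt(n_genes)                      # genes x k

  R <- withr::with_seed(as.integer(seed), {
    matrix(rnorm(k * k), k, k)
  })
  R <- sym_orth(R)
  Z <- t(Y)                                      # k x genes
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    U <- R %*% Z                                 # k x genes, current sources
    G <- tanh(alpha * U)
    Gp <- alpha * (1 - G^2)
    R_new <- (G %*% t(Z)) / n_genes - diag(rowMeans(Gp)) %*% R
    R_new <- sym_orth(R_new)
    delta <- max(abs(abs(diag(R_new %*% t(R))) - 1))
    R <- R_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    idicss_log("FastICA did not converge in ", max_iter, " iterations",
               level = "WARN")

  S <- Y %*% t(R)                                # genes x k
  # Least squares mixing: S'S = n_genes * I by construction
  W <- (t(S) %*% xc) / n_genes                   # k x samples

  # unit-variance columns of S, compensate in W
  s_sd <- apply(S, 2, sd)
  S <- sweep(S, 2, s_sd, "/")
  W <- sweep(W, 1, s_sd, "*")
  # non-negative skewness sign convention
  flip <- ifelse(col_skewness(S) < 0, -1, 1)
  S <- sweep(S, 2, flip, "*")
  W <- sweep(W, 1, flip, "*")
  # order by explained variance (row variance of W)
  ord <- order(apply(W, 1, var), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  W <- W[ord, , drop = FALSE]

  ids <- paste0("IC", seq_len(k))
  dimnames(S) <- list(rownames(expr), ids)
  dimnames(W) <- list(ids, colnames(expr))
  structure(
    list(S = S, W = W, k = k, converged = converged, iterations = iter,
         seed = as.integer(seed),
         center = list(row = rm_, col = cm_)),
    class = "ica_decomposition"
  )
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W via eigendecomposition.
#' @noRd
sym_orth <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d genes x %d samples, k=%d (%s, %d iterations)\n",
              nrow(x$S), ncol(x$W), x$k,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Relative reconstruction error of a decomposition
#'
#' Frobenius-norm ratio `||E_c - S W|| / ||E_c||` where `E_c` is the
#' double-centered expression matrix the fit used.
#'
#' @param decomp An `ica_decomposition`.
#' @param expr The expression matrix it was fitted to.
#' @return Scalar in [0, Inf); small when `k` covers the true sources.
#' @export
reconstruction_error <- function(decomp, expr) {
  xc <- expr - decomp$center$row
  xc <- sweep(xc, 2, decomp$center$col, "-")
  sqrt(sum((xc - decomp$S %*% decomp$W)^2) / sum(xc^2))
}

#' Multi-restart stability of the components
#'
#' Repeats the fit with seeds derived from `seed`; components of the first
#' run are matched to each other run by greedy maximal absolute Pearson
#' correlation of the S columns. The stability index of a component is the
#' mean matched |r| across the other runs — near 1 for reproducible sources,
#' lower for noise-driven components.
#'
#' @inheritParams fit_ica
#' @param n_runs Number of restarts (>= 2).
#' @return Tibble with `component`, `stability`, plus attributes `n_runs`
#'   and `matching` ("greedy_abs_pearson").
#' @export
stability_select <- function(expr, k, n_runs = 10L, seed = 1L, ...) {
  if (n_runs < 2L) stopf("n_runs must be >= 2")
  seeds <- derive_seeds(seed, n_runs)
  fits <- lapply(seeds, function(s) fit_ica(expr, k, seed = s, ...))
  ref <- fits[[1]]$S
  rmat <- vapply(fits[-1], function(f) {
    match_components(ref, f$S)$r
  }, numeric(k))
  rmat <- matrix(rmat, nrow = k)
  out <- tibble::tibble(
    component = colnames(ref),
    stability = rowMeans(rmat)
  )
  attr(out, "n_runs") <- n_runs
  attr(out, "matching") <- "greedy_abs_pearson"
  out
}

# Greedy 1-1 matching of columns of A to columns of B by |Pearson r|.
# Returns, per column of A, the matched column index of B and the |r|.
#' @noRd
match_components <- function(A, B) {
  cm <- abs(cor(A, B))
  k <- ncol(A)
  match_idx <- integer(k); match_r <- numeric(k)
  avail_a <- seq_len(k); avail_b <- seq_len(ncol(B))
  work <- cm
  for (step in seq_len(min(k, ncol(B)))) {
    pos <- which(work == max(work), arr.ind = TRUE)[1, ]
    i <- avail_a[pos[1]]; j <- avail_b[pos[2]]
    match_idx[i] <- j; match_r[i] <- cm[i, j]
    work <- work[-pos[1], -pos[2], drop = FALSE]
    avail_a <- avail_a[-pos[1]]; avail_b <- avail_b[-pos[2]]
    if (length(avail_a) == 0 || length(avail_b) == 0) break
  }
  list(index = match_idx, r = match_r)
}

#' Top genes of a component
#'
#' Genes whose loading, z-scored within the component's S column, exceeds
#' `z_threshold` in absolute value. The sign of the loading is returned so
#' up- and down-weighted genes stay distinguishable.
#'
#' @param decomp An `ica_decomposition`.
#' @param component Component ID (e.g. `"IC3"`) or index.
#' @param z_threshold Positive |z| cutoff (default 3).
#' @return Tibble with `gene`, `loading`, `z`, `sign`.
#' @export
top_genes <- function(decomp, component, z_threshold = 3) {
  if (z_threshold <= 0) stopf("z_threshold must be positive")
  if (is.numeric(component)) component <- colnames(decomp$S)[component]
  if (is.na(component) || !component %in% colnames(decomp$S))
    stopf("unknown component ID")
  col <- decomp$S[, component]
  z <- (col - mean(col)) / sd(col)
  sel <- which(abs(z) > z_threshold)
  tibble::tibble(
    gene = names(col)[sel],
    loading = unname(col[sel]),
    z = unname(z[sel]),
    sign = unname(ifelse(col[sel] >= 0, "+", "-"))
  ) |> dplyr::arrange(dplyr::desc(abs(.data$z)))
}

#' Top-gene sets for all components
#' @inheritParams top_genes
#' @return Named list (component -> character vector of genes).
#' @export
top_gene_sets <- function(decomp, z_threshold = 3) {
  ids <- colnames(decomp$S)
  sets <- lapply(ids, function(id) top_genes(decomp, id, z_threshold)$gene)
  names(sets) <- ids
  sets
}

#' @rdname fit_ica
#' @param x An `ica_decomposition`.
#' @param ... Unused.
#' @export
glance.ica_decomposition <- function(x, ...) {
  tibble::tibble(k = x$k, converged = x$converged, iterations = x$iterations,
                 seed = x$seed, n_genes = nrow(x$S), n_samples = ncol(x$W))
}

#' @rdname fit_ica
#' @export
tidy.ica_decomposition <- function(x, ...) {
  w_var <- apply(x$W, 1, var)
  tibble::tibble(
    component = colnames(x$S),
    w_variance = unname(w_var),
    explained_fraction = unname(w_var / sum(w_var)),
    loading_skewness = unname(col_skewness(x$S))
  )
}
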