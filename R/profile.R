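# idic_profile: mutation impact on key components, lambda blending,
# subgroup discovery.
#
# The iDIC profile adjusts each key component's z-scored sample weights by
# mutation impact terms:
#   iDIC(c, s) = Wz(c, s) + lambda * D(c, s) + (1 - lambda) * I(c, s)
# where D and I are the z-scored summed gene loadings of mutated driver /
# immune genes (formula version "additive-v1"). lambda in [0, 1] trades
# driver-mutation influence against immune-mutation influence; default 0.7.

#' Associate driver mutations with component weights
#'
#' For each (gene, component) pair, a two-sided Wilcoxon rank-sum test
#' compares the component's sample weights between mutated and wild-type
#' samples. The effect size is the rank-biserial correlation; q is BH over
#' all tests performed.
#'
#' @param W Mixing matrix (components x samples) from [fit_ica()].
#' @param mut Binary mutation matrix (genes x samples), samples aligned
#'   with `W`.
#' @param genes Genes to test (e.g. a driver list); genes mutated in fewer
#'   than `min_mutated` samples are skipped.
#' @param min_mutated Minimum mutated-sample count (default 5).
#' @return Tibble: `gene`, `component`, `n_mutated`, `effect`
#'   (rank-biserial, positive when mutated samples have larger weights),
#'   `direction`, `p`, `q`.
#' @export
driver_ic_association <- function(W, mut, genes = rownames(mut),
                                  min_mutated = 5L) {
  shared <- intersect(colnames(W), colnames(mut))
  if (length(shared) < 4L) stopf("too few shared samples between W and mutations")
  W <- W[, shared, drop = FALSE]
  mut <- mut[, shared, drop = FALSE]
  genes <- intersect(genes, rownames(mut))
  rows <- purrr::map_dfr(genes, function(g) {
    carriers <- mut[g, ] == 1
    n_mut <- sum(carriers)
    if (n_mut < min_mutated || n_mut > length(carriers) - min_mutated) {
      idicss_log("gene ", g, " skipped (", n_mut, " mutated)")
      return(tibble::tibble())
    }
    purrr::map_dfr(rownames(W), function(comp) {
      x <- W[comp, carriers]; y <- W[comp, !carriers]
      exact <- min(length(x), length(y)) < 10
      wt <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)
      )
      u <- unname(wt$statistic)
      rb <- 2 * u / (length(x) * length(y)) - 1   # rank-biserial from U
      tibble::tibble(
        gene = g, component = comp, n_mutated = n_mut,
        effect = rb,
        direction = if (median(x) >= median(y)) "+" else "-",
        p = wt$p.value
      )
    })
  })
  if (nrow(rows)) rows$q <- p.adjust(rows$p, method = "BH")
  else rows <- tibble::tibble(gene = character(), component = character(),
                              n_mutated = integer(), effect = numeric(),
                              direction = character(), p = numeric(),
                              q = numeric())
  dplyr::arrange(rows, .data$q, .data$p)
}

#' Mutation impact of a gene set on key components
#'
#' For sample s and component c, the raw impact is the sum of the
#' component's gene loadings `S[g, c]` over genes g in `gene_set` that are
#' mutated in s. Rows (components) are then z-scored across samples; rows
#' with zero variance become 0.
#'
#' @param S Source matrix (genes x components) from [fit_ica()].
#' @param mut Binary mutation matrix (genes x samples).
#' @param gene_set Character vector of gene symbols; its intersection with
#'   both `S` genes and `mut` genes must be non-empty.
#' @param key_ics Component IDs (columns of `S`) to compute impact for.
#' @return Matrix (key components x samples), z-scored by row.
#' @export
mutation_impact <- function(S, mut, gene_set, key_ics = colnames(S)) {
  gs <- intersect(intersect(unique(gene_set), rownames(S)), rownames(mut))
  if (length(gs) == 0) stopf("gene_set has no genes in both S and mutations")
  bad <- setdiff(key_ics, colnames(S))
  if (length(bad)) stopf("unknown component(s): %s", paste(bad, collapse = ", "))
  raw <- t(S[gs, key_ics, drop = FALSE]) %*% mut[gs, , drop = FALSE]
  rownames(raw) <- key_ics
  row_zscore(raw)
}

#' Blend component weights with mutation impacts into the iDIC profile
#'
#' `iDIC = Wz + lambda * D + (1 - lambda) * I`, where `Wz` are z-scored
#' key-component weights and `D`/`I` the driver/immune mutation impact
#' matrices from [mutation_impact()].
#'
#' @param Wz Z-scored key-component weight matrix (key ICs x samples).
#' @param D Driver mutation impact matrix, same shape.
#' @param I Immune mutation impact matrix, same shape.
#' @param lambda Blending weight in [0, 1]; default 0.7.
#' @return Object of class `idic_profile`: list with `profile`
#'   (key ICs x samples), `lambda`, `formula_version`.
#' @export
blend_idic <- function(Wz, D, I, lambda = 0.7) {
  if (!identical(dim(Wz), dim(D)) || !identical(dim(Wz), dim(I)))
    stopf("Wz, D, I must share the same shape")
  if (lambda < 0 || lambda > 1) stopf("lambda must be in [0, 1]")
  prof <- Wz + lambda * D + (1 - lambda) * I
  dimnames(prof) <- dimnames(Wz)
  structure(
    list(profile = prof, lambda = lambda, formula_version = "additive-v1"),
    class = "idic_profile"
  )
}

#' @export
print.idic_profile <- function(x, ...) {
  cat(sprintf("<idic_profile> %d key ICs x %d samples (lambda=%.2f, %s)\n",
              nrow(x$profile), ncol(x$profile), x$lambda, x$formula_version))
  invisible(x)
}

#' Compute the full iDIC profile from pipeline pieces
#'
#' Convenience wrapper: z-scores the key rows of `W`, computes driver and
#' immune mutation impacts, and blends them.
#'
#' @param decomp An `ica_decomposition`.
#' @param mut Binary mutation matrix (genes x samples aligned with `W`).
#' @param key_ics Key component IDs (e.g. from [select_key_ics()]).
#' @param driver_genes Driver gene list.
#' @param immune_genes Immune gene vector (e.g. union of the immune GMT).
#' @param lambda Blending weight (default 0.7).
#' @return An `idic_profile`.
#' @export
idic_profile <- function(decomp, mut, key_ics, driver_genes, immune_genes,
                         lambda = 0.7) {
  if (length(key_ics) == 0) stopf("no key components supplied")
  shared <- intersect(colnames(decomp$W), colnames(mut))
  Wz <- row_zscore(decomp$W[key_ics, shared, drop = FALSE])
  D <- mutation_impact(decomp$S, mut[, shared, drop = FALSE], driver_genes, key_ics)
  I <- mutation_impact(decomp$S, mut[, shared, drop = FALSE], immune_genes, key_ics)
  blend_idic(Wz, D, I, lambda)
}

#' Consensus clustering of the iDIC profile
#'
#' `n_resample` k-means runs on random subsets of samples; the consensus
#' matrix is the co-assignment frequency among co-sampled pairs; final
#' labels come from a hierarchical (average linkage) cut of 1 - consensus
#' at `k`. With `k = 2` the cluster with the lower mean immune signature
#' score (when `expression` and `immune_genes` are given) is "clusterA",
#' otherwise the larger cluster is; remaining labels follow alphabetically.
#'
#' @param profile An `idic_profile` or a features x samples matrix.
#' @param k Number of clusters (default 2).
#' @param n_resample Number of subsampled k-means runs (default 250).
#' @param subsample_frac Fraction of samples per run (default 0.8).
#' @param seed Integer seed.
#' @param expression Optional expression matrix for immune-score anchoring.
#' @param immune_genes Optional immune gene vector for anchoring.
#' @return Object of class `idic_subgroups`: list with `assignment`
#'   (tibble `sample`, `cluster`), `consensus` (samples x samples matrix),
#'   `pac`, `k`, `seed`.
#' @export
consensus_cluster <- function(profile, k = 2L, n_resample = 250L,
                              subsample_frac = 0.8, seed = 1L,
                              expression = NULL, immune_genes = NULL) {
  m <- if (inherits(profile, "idic_profile")) profile$profile else profile
  if (k < 2L) stopf("k must be >= 2")
  n <- ncol(m)
  if (n < 2L * k) stopf("need at least 2k samples")
  X <- t(m)                                     # samples x features
  co_assigned <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_resample)) {
      idx <- sort(sample.int(n, max(2L * k, round(subsample_frac * n))))
      cl <- kmeans(X[idx, , drop = FALSE], centers = k, nstart = 3,
                   iter.max = 50)$cluster
      same <- outer(cl, cl, "==") * 1
      co_assigned[idx, idx] <- co_assigned[idx, idx] + same
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    }
  })
  consensus <- ifelse(co_sampled > 0, co_assigned / co_sampled, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(colnames(m), colnames(m))
  hc <- hclust(as.dist(1 - consensus), method = "average")
  raw <- cutree(hc, k = k)

  off <- consensus[upper.tri(consensus)]
  pac <- mean(off > 0.1 & off < 0.9)

  labels <- order_cluster_labels(raw, m, expression, immune_genes, k)
  structure(
    list(
      assignment = tibble::tibble(sample = colnames(m),
                                  cluster = labels),
      consensus = consensus, pac = pac, k = k, seed = as.integer(seed)
    ),
    class = "idic_subgroups"
  )
}

# clusterA = lower mean immune score (if available) else larger cluster.
#' @noRd
order_cluster_labels <- function(raw, m, expression, immune_genes, k) {
  ids <- sort(unique(raw))
  if (!is.null(expression) && !is.null(immune_genes) &&
      length(intersect(immune_genes, rownames(expression)))) {
    sc <- signature_score(expression, immune_genes)
    sc <- sc[match(colnames(m), names(sc))]
    key <- vapply(ids, function(i) mean(sc[raw == i], na.rm = TRUE),
                  numeric(1))
    ord <- order(key)                  # ascending: lowest immune = clusterA
  } else {
    sizes <- tabulate(raw, nbins = max(ids))[ids]
    ord <- order(-sizes)               # largest = clusterA
  }
  new_names <- paste0("cluster", LETTERS[seq_len(k)])
  map <- setNames(new_names, as.character(ids[ord]))
  unname(map[as.character(raw)])
}

#' @export
print.idic_subgroups <- function(x, ...) {
  tab <- table(x$assignment$cluster)
  cat(sprintf("<idic_subgroups> k=%d, PAC=%.3f; sizes: %s\n", x$k, x$pac,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Mean-z immune (or any) signature score per sample
#'
#' Gene-wise z-scores the expression of the set genes and averages them per
#' sample. Invariant to gene-wise affine rescaling of the input.
#'
#' @param expr Gene x sample expression matrix.
#' @param gene_set Character vector; intersection with `expr` genes must be
#'   non-empty.
#' @return Named numeric vector (one score per sample).
#' @export
signature_score <- function(expr, gene_set) {
  gs <- intersect(unique(gene_set), rownames(expr))
  if (length(gs) == 0) stopf("gene_set shares no genes with expression")
  z <- row_zscore(expr[gs, , drop = FALSE])
  colMeans(z)
}

#' lambda sensitivity of downstream prognosis
#'
#' Recomputes the iDIC profile over a lambda grid and reports, per lambda,
#' the subgroup ARI against the lambda = default assignment and the
#' C-index of a profile-based risk proxy (first principal component of the
#' profile) against overall survival. Leaves the lambda choice to the user.
#'
#' @param decomp,mut,key_ics,driver_genes,immune_genes As [idic_profile()].
#' @param clinical Clinical tibble with `sample`, `os_time`, `os_event`.
#' @param lambdas Grid (default `c(0.5, 0.7, 0.8, 1.0)`).
#' @param seed Integer seed for the clustering runs.
#' @return Tibble: `lambda`, `pac`, `cindex_pc1`.
#' @export
lambda_sensitivity <- function(decomp, mut, key_ics, driver_genes,
                               immune_genes, clinical,
                               lambdas = c(0.5, 0.7, 0.8, 1.0), seed = 1L) {
  purrr::map_dfr(lambdas, function(lam) {
    prof <- idic_profile(decomp, mut, key_ics, driver_genes, immune_genes,
                         lambda = lam)
    cl <- consensus_cluster(prof, seed = seed)
    pc1 <- stats::prcomp(t(prof$profile), center = TRUE, scale. = FALSE)$x[, 1]
    idx <- match(names(pc1), clinical$sample)
    ok <- !is.na(idx)
    ci <- concordance_index(pc1[ok], clinical$os_time[idx[ok]],
                            clinical$os_event[idx[ok]])
    ci <- max(ci, 1 - ci)              # orientation-free summary
    tibble::tibble(lambda = lam, pac = cl$pac, cindex_pc1 = ci)
  })
}
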