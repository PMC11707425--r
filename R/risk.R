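# risk_model: subgroup differential expression -> LASSO-Cox signature ->
# median-split iDICss risk groups.

#' Differential expression between iDIC subgroups
#'
#' Per-gene two-sided Wilcoxon rank-sum test of clusterB vs clusterA, with
#' log2 fold change computed as mean(clusterB) - mean(clusterA) (expression
#' is log scale). BH adjustment over all genes. A gene is a candidate when
#' `q < q_max` and `|log2FC| >= fc_min`.
#'
#' @param expr Gene x sample matrix (log scale).
#' @param subgroups An `idic_subgroups` object or a tibble with `sample`,
#'   `cluster` columns (two clusters).
#' @param q_max BH q cutoff (default 0.05).
#' @param fc_min Absolute log2 fold-change cutoff (default 1).
#' @return Tibble: `gene`, `log2fc`, `p`, `q`, `candidate`.
#' @export
differential_genes <- function(expr, subgroups, q_max = 0.05, fc_min = 1) {
  asg <- if (inherits(subgroups, "idic_subgroups")) subgroups$assignment
         else tibble::as_tibble(subgroups)
  asg <- asg[asg$sample %in% colnames(expr), ]
  cl <- sort(unique(asg$cluster))
  if (length(cl) != 2L) stopf("exactly two clusters required")
  a <- asg$sample[asg$cluster == cl[1]]
  b <- asg$sample[asg$cluster == cl[2]]
  if (length(a) < 3L || length(b) < 3L)
    stopf("each cluster needs at least 3 samples")
  A <- expr[, a, drop = FALSE]; B <- expr[, b, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)), function(i) {
    suppressWarnings(wilcox.test(B[i, ], A[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  lfc <- rowMeans(B) - rowMeans(A)
  q <- p.adjust(p, method = "BH")
  tibble::tibble(
    gene = rownames(expr), log2fc = unname(lfc), p = p, q = q,
    candidate = q < q_max & abs(lfc) >= fc_min
  ) |> dplyr::arrange(.data$q, .data$p)
}

#' Fit the iDICss LASSO-Cox gene signature
#'
#' L1-penalized Cox partial likelihood on candidate genes (gene-wise
#' z-scored), penalty chosen by cross-validated partial-likelihood
#' deviance. Genes with nonzero coefficients form the signature.
#' Deterministic given `seed` (fold assignment is seeded).
#'
#' The default penalty rule is the 1-SE rule: on planted-signal
#' simulations the CV-minimum rule admits several times as many null genes
#' as true ones, while 1-SE keeps the full planted set with few
#' passengers. The minimum rule remains available via
#' `penalty_rule = "min"`.
#'
#' @param expr Gene x sample matrix, restricted (or restrictable via
#'   `candidates`) to the candidate pool.
#' @param clinical Tibble with `sample`, `os_time`, `os_event`.
#' @param candidates Optional character vector of candidate genes.
#' @param n_folds CV folds (default 10).
#' @param seed Integer seed.
#' @param penalty_rule `"1se"` (default) or `"min"`.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 0.01; bounds the overfit tail of the path).
#' @return Object of class `gene_signature`: list with `coefficients`
#'   (named numeric, nonzero), `penalty` (the chosen lambda),
#'   `penalty_rule`, `n_folds`, `seed`, `threshold` (training-median
#'   iDICss, frozen), `training_scores`.
#' @export
fit_lasso_cox <- function(expr, clinical, candidates = rownames(expr),
                          n_folds = 10L, seed = 1L,
                          penalty_rule = c("1se", "min"),
                          lambda_min_ratio = 0.01) {
  penalty_rule <- match.arg(penalty_rule)
  candidates <- intersect(candidates, rownames(expr))
  if (length(candidates) < 2L) stopf("need at least 2 candidate genes")
  shared <- intersect(colnames(expr), clinical$sample)
  cl <- clinical[match(shared, clinical$sample), ]
  ok <- !is.na(cl$os_time) & !is.na(cl$os_event) & cl$os_time > 0
  cl <- cl[ok, ]; shared <- shared[ok]
  if (length(shared) < 30L) stopf("need at least 30 samples with survival data")
  if (sum(cl$os_event) < 10L) stopf("need at least 10 events")

  X <- t(expr[candidates, shared, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    idicss_log(sum(sds == 0), " constant candidate genes dropped")
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2L) stopf("fewer than 2 non-constant candidates")
  }
  Xz <- scale(X)
  y <- survival::Surv(cl$os_time, cl$os_event)
  foldid <- withr::with_seed(as.integer(seed), {
    sample(rep(seq_len(n_folds), length.out = nrow(Xz)))
  })
  cvfit <- glmnet::cv.glmnet(Xz, y, family = "cox", alpha = 1,
                             foldid = foldid, standardize = FALSE,
                             lambda.min.ratio = lambda_min_ratio)
  s_choice <- if (penalty_rule == "1se") "lambda.1se" else "lambda.min"
  beta <- as.numeric(coef(cvfit, s = s_choice))
  names(beta) <- colnames(Xz)
  beta <- beta[beta != 0]
  if (length(beta) == 0 && penalty_rule == "1se") {
    idicss_log("1-SE penalty kept no genes; falling back to CV minimum")
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))
    names(beta) <- colnames(Xz)
    beta <- beta[beta != 0]
    s_choice <- "lambda.min"
  }
  if (length(beta) == 0) stopf("LASSO selected no genes")
  sig <- structure(
    list(coefficients = beta, penalty = unname(cvfit[[s_choice]]),
         penalty_rule = penalty_rule, n_folds = n_folds,
         seed = as.integer(seed), threshold = NULL,
         training_scores = NULL),
    class = "gene_signature"
  )
  tr <- score_idicss(expr[, shared, drop = FALSE], sig)
  sig$threshold <- tr$threshold
  sig$training_scores <- tr$scores
  sig
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d genes (penalty %.4g, threshold %s)\n",
              length(x$coefficients), x$penalty,
              if (is.null(x$threshold)) "unset" else sprintf("%.4g", x$threshold)))
  invisible(x)
}

#' @rdname fit_lasso_cox
#' @param x A `gene_signature`.
#' @param ... Unused.
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble::tibble(gene = names(x$coefficients),
                 beta = unname(x$coefficients)) |>
    dplyr::arrange(dplyr::desc(abs(.data$beta)))
}

#' @rdname fit_lasso_cox
#' @export
glance.gene_signature <- function(x, ...) {
  tibble::tibble(n_genes = length(x$coefficients), penalty = x$penalty,
                 n_folds = x$n_folds, seed = x$seed,
                 threshold = x$threshold %||% NA_real_)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score samples with an iDICss gene signature
#'
#' `iDICss(s) = sum_g beta_g * z_g(s)` over signature genes, where z is the
#' gene-wise z-score within the scored cohort (absorbing cohort-specific
#' location/scale). Missing signature genes contribute 0 and are logged;
#' coverage below 50% is an error. The risk group is "high" iff the score
#' strictly exceeds the threshold (training median when not supplied), so
#' ties at the threshold fall to "low".
#'
#' @param expr Gene x sample matrix of the cohort to score.
#' @param signature A `gene_signature` (or a named coefficient vector).
#' @param threshold Optional frozen threshold; default: the signature's
#'   stored training median, else the scored cohort's median.
#' @return Object of class `idicss_scores`: list with `scores` (tibble
#'   `sample`, `idicss`, `group`), `threshold`, `coverage`.
#' @export
score_idicss <- function(expr, signature, threshold = NULL) {
  beta <- if (inherits(signature, "gene_signature")) signature$coefficients
          else signature
  if (length(beta) == 0 || all(beta == 0)) stopf("empty signature")
  present <- intersect(names(beta), rownames(expr))
  coverage <- length(present) / length(beta)
  if (coverage < 0.5)
    stopf("only %.0f%% of signature genes present (need >= 50%%)",
          100 * coverage)
  if (coverage < 1)
    idicss_log(length(beta) - length(present),
               " signature genes absent; contributing 0")
  z <- row_zscore(expr[present, , drop = FALSE])
  val <- as.numeric(t(z) %*% beta[present])
  names(val) <- colnames(expr)
  if (is.null(threshold)) {
    threshold <- if (inherits(signature, "gene_signature") &&
                     !is.null(signature$threshold)) signature$threshold
                 else median(val)
  }
  structure(
    list(
      scores = tibble::tibble(
        sample = names(val), idicss = unname(val),
        group = unname(ifelse(val > threshold, "high", "low"))
      ),
      threshold = threshold, coverage = coverage
    ),
    class = "idicss_scores"
  )
}

#' @export
print.idicss_scores <- function(x, ...) {
  tab <- table(x$scores$group)
  cat(sprintf("<idicss_scores> %d samples (threshold %.4g): %s\n",
              nrow(x$scores), x$threshold,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @rdname score_idicss
#' @param x An `idicss_scores`.
#' @param ... Unused.
#' @export
tidy.idicss_scores <- function(x, ...) x$scores
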