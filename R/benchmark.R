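# evaluate/benchmark: combinatorial survival machine-learning comparison.
#
# An adapter wraps one survival learner behind fit(X, time, event, seed) /
# predict(model, X) / selected(model). X is samples x genes, gene-wise
# z-scored per cohort. Adapters marked `selector = TRUE` can also act as
# the variable-selection stage of an ordered (selector, fitter) pair.
# CoxBoost, plsRcox, SuperPC and survival-SVM are native approximations of
# the original R learners (componentwise boosting, supervised PLS + Cox,
# screening + PCA + Cox, eps-regression SVM on event times).

#' Default survival-learner adapter registry
#'
#' @param steps_boost Boosting steps for the componentwise CoxBoost
#'   approximation (default 100).
#' @return Named list of adapters (see source for the adapter contract).
#' @export
default_registry <- function(steps_boost = 100L) {
  list(
    lasso = adapter_glmnet("lasso", alpha = 1, selector = TRUE),
    enet = adapter_glmnet("enet", alpha = 0.5, selector = TRUE),
    ridge = adapter_glmnet("ridge", alpha = 0, selector = FALSE),
    stepwise_cox = adapter_stepwise(),
    coxboost = adapter_coxboost(steps = steps_boost),
    rsf = adapter_rsf(),
    gbm = adapter_gbm(),
    survival_svm = adapter_survsvm(),
    superpc = adapter_superpc(),
    plscox = adapter_plscox()
  )
}

#' @noRd
adapter_glmnet <- function(label, alpha, selector) {
  list(
    label = label, selector = selector,
    fit = function(X, time, event, seed) {
      foldid <- withr::with_seed(seed, sample(rep(1:5, length.out = nrow(X))))
      cv <- glmnet::cv.glmnet(X, survival::Surv(time, event), family = "cox",
                              alpha = alpha, foldid = foldid,
                              standardize = FALSE)
      list(cv = cv, genes = colnames(X))
    },
    predict = function(model, X) {
      as.numeric(predict(model$cv, X[, model$genes, drop = FALSE],
                         s = "lambda.min", type = "link"))
    },
    selected = function(model) {
      b <- as.numeric(coef(model$cv, s = "lambda.min"))
      model$genes[b != 0]
    }
  )
}

# Univariate Cox z per gene (score-test style via coxph Wald z).
#' @noRd
univariate_cox_z <- function(X, time, event) {
  y <- survival::Surv(time, event)
  vapply(seq_len(ncol(X)), function(j) {
    f <- tryCatch(survival::coxph(y ~ X[, j]), error = function(e) NULL)
    if (is.null(f)) return(0)
    s <- summary(f)$coefficients
    z <- s[1, "z"]
    if (is.finite(z)) z else 0
  }, numeric(1))
}

#' @noRd
adapter_stepwise <- function(max_steps = 10L, screen_top = 30L) {
  list(
    label = "stepwise_cox", selector = TRUE,
    fit = function(X, time, event, seed) {
      z <- abs(univariate_cox_z(X, time, event))
      pool <- order(z, decreasing = TRUE)[seq_len(min(screen_top, ncol(X)))]
      y <- survival::Surv(time, event)
      chosen <- integer(0)
      best_aic <- Inf
      repeat {
        if (length(chosen) >= max_steps) break
        cand <- setdiff(pool, chosen)
        if (length(cand) == 0) break
        aics <- vapply(cand, function(j) {
          f <- tryCatch(
            survival::coxph(y ~ X[, c(chosen, j), drop = FALSE]),
            error = function(e) NULL)
          if (is.null(f)) Inf else AIC(f)
        }, numeric(1))
        if (min(aics) >= best_aic - 1e-8) break
        best_aic <- min(aics)
        chosen <- c(chosen, cand[which.min(aics)])
      }
      if (length(chosen) == 0) chosen <- pool[1]
      f <- survival::coxph(y ~ X[, chosen, drop = FALSE])
      list(fit = f, genes = colnames(X)[chosen])
    },
    predict = function(model, X) {
      as.numeric(X[, model$genes, drop = FALSE] %*% coef(model$fit))
    },
    selected = function(model) model$genes
  )
}

# Componentwise likelihood boosting for the Cox model: at each step a
# single coefficient gets one damped Newton update, chosen by score^2 /
# information.
#' @noRd
adapter_coxboost <- function(steps = 100L, nu = 0.1) {
  list(
    label = "coxboost", selector = TRUE,
    fit = function(X, time, event, seed) {
      ord <- order(time, decreasing = TRUE)   # risk set = prefix in this order
      Xo <- X[ord, , drop = FALSE]
      ev <- event[ord]; tt <- time[ord]
      n <- nrow(Xo); p <- ncol(Xo)
      beta <- numeric(p)
      for (m in seq_len(steps)) {
        eta <- as.numeric(Xo %*% beta)
        w <- exp(eta - max(eta))
        cw <- cumsum(w)
        cwx <- apply(Xo * w, 2, cumsum)          # n x p
        cwx2 <- apply(Xo^2 * w, 2, cumsum)
        ev_idx <- which(ev == 1)
        xbar <- cwx[ev_idx, , drop = FALSE] / cw[ev_idx]
        U <- colSums(Xo[ev_idx, , drop = FALSE] - xbar)
        Iinf <- colSums(cwx2[ev_idx, , drop = FALSE] / cw[ev_idx] - xbar^2)
        Iinf <- pmax(Iinf, 1e-8)
        j <- which.max(U^2 / Iinf)
        beta[j] <- beta[j] + nu * U[j] / Iinf[j]
      }
      list(beta = setNames(beta, colnames(X)))
    },
    predict = function(model, X) {
      as.numeric(X[, names(model$beta), drop = FALSE] %*% model$beta)
    },
    selected = function(model) names(model$beta)[model$beta != 0]
  )
}

#' @noRd
adapter_rsf <- function(num_trees = 300L) {
  list(
    label = "rsf", selector = FALSE,
    fit = function(X, time, event, seed) {
      dat <- data.frame(time = time, event = event, X, check.names = FALSE)
      fit <- ranger::ranger(
        survival::Surv(time, event) ~ ., data = dat,
        num.trees = num_trees, seed = seed, respect.unordered.factors = TRUE
      )
      list(fit = fit, genes = colnames(X))
    },
    predict = function(model, X) {
      pr <- predict(model$fit,
                    data = data.frame(X[, model$genes, drop = FALSE],
                                      check.names = FALSE))
      chf <- pr$chf
      as.numeric(chf[, ncol(chf)])        # cumulative hazard at last time
    },
    selected = function(model) NULL
  )
}

#' @noRd
adapter_gbm <- function(nrounds = 150L, eta = 0.05, max_depth = 2L) {
  list(
    label = "gbm", selector = FALSE,
    fit = function(X, time, event, seed) {
      # xgboost Cox: negative label marks a censored observation
      lab <- ifelse(event == 1, time, -time)
      dm <- xgboost::xgb.DMatrix(X, label = lab)
      fit <- xgboost::xgb.train(
        params = list(objective = "survival:cox", eta = eta,
                      max_depth = max_depth, subsample = 0.8,
                      nthread = 1, seed = seed),
        data = dm, nrounds = nrounds, verbose = 0
      )
      list(fit = fit, genes = colnames(X))
    },
    predict = function(model, X) {
      as.numeric(predict(model$fit,
                         xgboost::xgb.DMatrix(X[, model$genes, drop = FALSE])))
    },
    selected = function(model) NULL
  )
}

# Survival SVM approximation: eps-regression of -log(time) on the events
# only; censored observations are dropped from training.
#' @noRd
adapter_survsvm <- function() {
  list(
    label = "survival_svm", selector = FALSE,
    fit = function(X, time, event, seed) {
      idx <- which(event == 1)
      if (length(idx) < 10) idx <- seq_along(event)
      fit <- e1071::svm(X[idx, , drop = FALSE], -log(time[idx] + 1),
                        type = "eps-regression", kernel = "linear")
      list(fit = fit, genes = colnames(X))
    },
    predict = function(model, X) {
      as.numeric(predict(model$fit, X[, model$genes, drop = FALSE]))
    },
    selected = function(model) NULL
  )
}

# Supervised principal components: univariate-Cox screen, PCA on the top
# genes, Cox on the leading PCs.
#' @noRd
adapter_superpc <- function(screen_top = 20L, n_pc = 2L) {
  list(
    label = "superpc", selector = FALSE,
    fit = function(X, time, event, seed) {
      z <- abs(univariate_cox_z(X, time, event))
      keep <- order(z, decreasing = TRUE)[seq_len(min(screen_top, ncol(X)))]
      pc <- stats::prcomp(X[, keep, drop = FALSE], center = FALSE)
      npc <- min(n_pc, ncol(pc$x))
      f <- survival::coxph(survival::Surv(time, event) ~
                             pc$x[, seq_len(npc), drop = FALSE])
      list(genes = colnames(X)[keep], rotation = pc$rotation[, seq_len(npc),
                                                             drop = FALSE],
           beta = coef(f))
    },
    predict = function(model, X) {
      pcs <- X[, model$genes, drop = FALSE] %*% model$rotation
      as.numeric(pcs %*% model$beta)
    },
    selected = function(model) NULL
  )
}

# PLS-Cox approximation: one supervised component with gene weights
# proportional to univariate Cox z, then Cox on the component.
#' @noRd
adapter_plscox <- function() {
  list(
    label = "plscox", selector = FALSE,
    fit = function(X, time, event, seed) {
      z <- univariate_cox_z(X, time, event)
      u <- z / sqrt(sum(z^2) + 1e-12)
      comp <- as.numeric(X %*% u)
      f <- survival::coxph(survival::Surv(time, event) ~ comp)
      list(genes = colnames(X), u = u, beta = unname(coef(f)))
    },
    predict = function(model, X) {
      as.numeric(X[, model$genes, drop = FALSE] %*% model$u) * model$beta
    },
    selected = function(model) NULL
  )
}

#' Enumerate machine-learning model combinations
#'
#' Catalogue rule: every single adapter, plus every ordered
#' (selector, fitter) pair with a variable-selection-capable selector and
#' `fitter != selector`. Ordering is deterministic (singles by label, then
#' pairs by selector then fitter label).
#'
#' @param registry Named adapter list (see [default_registry()]).
#' @return Tibble: `label`, `selector`, `fitter`.
#' @export
enumerate_ml_combinations <- function(registry = default_registry()) {
  if (length(registry) == 0) stopf("empty adapter registry")
  labs <- sort(vapply(registry, `[[`, character(1), "label"))
  singles <- tibble::tibble(label = labs, selector = NA_character_,
                            fitter = labs)
  sels <- sort(vapply(Filter(function(a) isTRUE(a$selector), registry),
                      `[[`, character(1), "label"))
  pairs <- purrr::map_dfr(sels, function(s) {
    fits <- setdiff(labs, s)
    tibble::tibble(label = paste(s, fits, sep = "+"), selector = s,
                   fitter = fits)
  })
  if (nrow(pairs))
    pairs <- dplyr::arrange(pairs, .data$selector, .data$fitter)
  out <- dplyr::bind_rows(singles, pairs)
  stopifnot(!anyDuplicated(out$label))
  out
}

#' Run the combinatorial survival benchmark
#'
#' Trains each combination on the training cohort (gene-wise z-scored
#' candidate genes), scores every validation cohort, and reports the
#' per-cohort and average Harrell's C. Rows failing to fit carry `NA`
#' C-indices with the error recorded; the table is sorted by decreasing
#' average C-index.
#'
#' @param combinations Tibble from [enumerate_ml_combinations()] (any
#'   subset of its rows).
#' @param train A `cohort_bundle` for training.
#' @param validations Named list of `cohort_bundle`s for validation.
#' @param candidates Candidate gene vector (default: all training genes).
#' @param registry Adapter registry (default [default_registry()]).
#' @param seed Integer seed.
#' @return Tibble: `label`, one `cindex_<cohort>` column per validation
#'   cohort, `cindex_avg`, `n_genes_used`, `error`.
#' @export
run_benchmark <- function(combinations, train, validations,
                          candidates = NULL, registry = default_registry(),
                          seed = 1L) {
  if (length(validations) == 0) stopf("empty validation list")
  if (is.null(names(validations)))
    names(validations) <- paste0("cohort", seq_along(validations))
  genes <- Reduce(intersect, c(list(rownames(train$expression)),
                               lapply(validations,
                                      function(b) rownames(b$expression))))
  if (!is.null(candidates)) genes <- intersect(genes, candidates)
  if (length(genes) < 2L) stopf("fewer than 2 shared candidate genes")

  prep <- function(bundle) {
    X <- t(row_zscore(bundle$expression[genes, , drop = FALSE]))
    cl <- bundle$clinical
    list(X = X, time = cl$os_time, event = cl$os_event)
  }
  tr <- prep(train)
  va <- lapply(validations, prep)
  by_label <- setNames(registry,
                       vapply(registry, `[[`, character(1), "label"))
  # per-combination seed derived from the label so results do not depend
  # on submission order
  label_seed <- function(label) {
    h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) %% 97 + 1))
    as.integer((as.numeric(seed) * 7919 + h) %% 2147483646 + 1)
  }

  rows <- purrr::map_dfr(seq_len(nrow(combinations)), function(i) {
    combo <- combinations[i, ]
    s <- label_seed(combo$label)
    res <- tryCatch({
      use_genes <- genes
      if (!is.na(combo$selector)) {
        sel_ad <- by_label[[combo$selector]]
        sel_model <- sel_ad$fit(tr$X, tr$time, tr$event, s)
        picked <- sel_ad$selected(sel_model)
        if (length(picked) < 2L) stop("selector kept < 2 genes")
        use_genes <- picked
      }
      ad <- by_label[[combo$fitter]]
      model <- ad$fit(tr$X[, use_genes, drop = FALSE], tr$time, tr$event, s)
      cis <- vapply(va, function(v) {
        sc <- ad$predict(model, v$X[, use_genes, drop = FALSE])
        concordance_index(sc, v$time, v$event)
      }, numeric(1))
      list(cis = cis, n = length(use_genes), err = NA_character_)
    }, error = function(e) {
      list(cis = setNames(rep(NA_real_, length(va)), names(va)),
           n = NA_integer_, err = conditionMessage(e))
    })
    out <- tibble::tibble(label = combo$label)
    for (nm in names(res$cis)) out[[paste0("cindex_", nm)]] <- res$cis[[nm]]
    out$cindex_avg <- mean(unlist(res$cis))
    out$n_genes_used <- res$n
    out$error <- res$err
    out
  })
  dplyr::arrange(rows, dplyr::desc(.data$cindex_avg))
}

#' Plot a benchmark table
#' @param object Tibble from [run_benchmark()].
#' @param top Show at most this many rows (default 20).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(object, top = 20L) {
  dat <- head(object[!is.na(object$cindex_avg), ], top)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cindex_avg, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "average validation C-index", y = NULL) +
    ggplot2::theme_minimal()
}
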