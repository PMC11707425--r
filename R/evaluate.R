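# evaluate: survival and response metrics, comparator baselines, drug
# screen. The benchmark lives in R/benchmark.R.

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit estimates per group (via [survival::survfit()]) and the
#' two-group log-rank chi-square (1 df) with its p-value (via
#' [survival::survdiff()]).
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 groups, each with >= 1 subject; at
#'   least one event overall).
#' @return Object of class `survival_comparison`: list with `curves`
#'   (tibble `group`, `time`, `surv`, `n_risk`, `n_event`), `chisq`, `df`,
#'   `p`, `n_per_group`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) == 0L)) stopf("empty group")
  if (sum(events) == 0L) stopf("no events observed")
  df_in <- data.frame(time = times, event = events, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df_in)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- tibble::tibble(
    group = sub("^group=", "", strata),
    time = fit$time, surv = fit$surv,
    n_risk = fit$n.risk, n_event = fit$n.event
  )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df_in)
  dfree <- length(sd_$n) - 1L
  p <- pchisq(sd_$chisq, df = dfree, lower.tail = FALSE)
  structure(
    list(curves = curves, chisq = unname(sd_$chisq), df = dfree, p = p,
         n_per_group = as.integer(table(groups))),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> log-rank chisq=%.3f (df=%d), p=%.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' @rdname km_logrank
#' @param object A `survival_comparison`.
#' @param ... Unused.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  # prepend t=0, S=1 per group for a conventional staircase
  base <- object$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  dat <- dplyr::bind_rows(base,
                          object$curves[, c("group", "time", "surv")])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (the shorter observed time has the event)
#' in which the shorter-time subject carries the higher score; score ties
#' count 0.5. Higher scores are taken as higher risk.
#'
#' @param scores Risk scores (higher = worse predicted outcome).
#' @param times Follow-up times.
#' @param events 0/1 event indicators.
#' @return C-index in [0, 1].
#' @export
concordance_index <- function(scores, times, events) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      # pair (i, j) comparable when i fails strictly before j's time
      if (times[i] < times[j] || (times[i] == times[j] && events[j] == 0)) {
        comp <- comp + 1
        if (scores[i] > scores[j]) conc <- conc + 1
        else if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) stopf("no comparable pairs")
  conc / comp
}

#' AUROC for response prediction
#'
#' Rank-statistic AUROC (Mann-Whitney U divided by n1*n0) of `scores`
#' against binary response labels. The reported orientation is
#' score-as-given; use `orient = TRUE` to report `max(AUC, 1 - AUC)` with
#' the flip logged (lower iDICss predicts response, so the raw AUC of the
#' score against responder labels is typically below 0.5).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; 1/TRUE/"responder"/"CR"/"PR" count as
#'   responders.
#' @param orient Report the orientation-free AUC? Default FALSE.
#' @return AUC in [0, 1] (attribute `flipped` when `orient = TRUE`).
#' @export
response_auc <- function(scores, labels, orient = FALSE) {
  y <- as_responder(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient && auc < 0.5) {
    idicss_log("AUC orientation flipped (lower score predicts response)")
    auc <- structure(1 - auc, flipped = TRUE)
  }
  auc
}

#' @noRd
as_responder <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) {
    y <- as.integer(labels)
    if (!all(y %in% c(0L, 1L))) stopf("numeric labels must be 0/1")
    return(y)
  }
  up <- toupper(as.character(labels))
  pos <- c("CR", "PR", "RESPONDER", "R", "1", "TRUE")
  neg <- c("SD", "PD", "NON-RESPONDER", "NONRESPONDER", "NR", "0", "FALSE")
  bad <- setdiff(up, c(pos, neg))
  if (length(bad)) stopf("unrecognized response label: %s", bad[1])
  ifelse(up %in% pos, 1L, 0L)
}

#' Threshold classification metrics
#'
#' Confusion matrix of `scores > threshold` (prediction = positive) against
#' binary labels, and the six standard metrics. Metrics with an empty
#' denominator are reported as `NA` rather than propagating NaN.
#'
#' @param scores Numeric scores (higher = predicted positive).
#' @param labels Binary labels (see [response_auc()]).
#' @param threshold Operating point; default the median score.
#' @return Tibble with `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(scores, labels, threshold = NULL) {
  y <- as_responder(labels)
  if (is.null(threshold)) threshold <- median(scores)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn); ppv <- safe(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(ppv) || (sens + ppv) == 0) NA_real_
        else 2 * sens * ppv / (sens + ppv)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = safe(tn, tn + fp),
    ppv = ppv, npv = safe(tn, tn + fn), f1 = f1,
    accuracy = safe(tp + tn, tp + fp + fn + tn)
  )
}

#' Time-dependent (cumulative/dynamic) AUC with IPCW
#'
#' At horizon t, cases are subjects with an event by t and controls are
#' subjects still under observation beyond t; pairs are weighted by inverse
#' probabilities of censoring from the Kaplan-Meier estimate of the
#' censoring distribution. With no censoring this reduces to the plain
#' binary AUC of `time <= t` against the score.
#'
#' @param scores Risk scores (higher = earlier failure predicted).
#' @param times,events Survival data.
#' @param horizons Evaluation times, each within the observed follow-up.
#' @return Tibble: `horizon`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(scores, times, events, horizons) {
  if (any(horizons > max(times))) stopf("horizon beyond last observed time")
  # KM of the censoring distribution G(t); censoring event = 1 - event
  gfit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G <- stats::stepfun(gfit$time, c(1, gfit$surv), right = FALSE)
  Gm <- function(t) {                    # G(t-): left limit
    vapply(t, function(tt) {
      lt <- gfit$time < tt
      if (!any(lt)) 1 else c(1, gfit$surv)[max(which(lt)) + 1]
    }, numeric(1))
  }
  purrr::map_dfr(horizons, function(h) {
    case <- which(times <= h & events == 1)
    ctrl <- which(times > h)
    if (length(case) == 0 || length(ctrl) == 0)
      return(tibble::tibble(horizon = h, auc = NA_real_,
                            n_cases = length(case),
                            n_controls = length(ctrl)))
    wc <- 1 / pmax(Gm(times[case]), 1e-12)
    wt <- rep(1 / pmax(G(h), 1e-12), length(ctrl))
    sc <- scores[case]; st <- scores[ctrl]
    num <- 0
    for (a in seq_along(sc)) {
      gt <- sum(wt[sc[a] > st]); eq <- sum(wt[sc[a] == st])
      num <- num + wc[a] * (gt + 0.5 * eq)
    }
    tibble::tibble(horizon = h, auc = num / (sum(wc) * sum(wt)),
                   n_cases = length(case), n_controls = length(ctrl))
  })
}

#' Simple comparator baseline scores
#'
#' Single-gene baselines are the z-scored expression row of the named gene
#' (e.g. PD-1 = PDCD1, PD-L1 = CD274, TCF7). Gene-pair baselines count the
#' configured pairs (a, b) for which `expr[a, s] > expr[b, s]`. Baselines
#' whose genes are absent are skipped with a log entry.
#'
#' @param expr Gene x sample matrix.
#' @param single_genes Named character vector, baseline name -> gene.
#' @param pair_sets Optional named list; each element a 2-column matrix or
#'   data frame of (a, b) gene pairs.
#' @return Tibble: `sample`, one column per surviving baseline.
#' @export
baseline_scores <- function(expr,
                            single_genes = c(PD1 = "PDCD1", PDL1 = "CD274",
                                             TCF7 = "TCF7"),
                            pair_sets = NULL) {
  out <- tibble::tibble(sample = colnames(expr))
  for (nm in names(single_genes)) {
    g <- single_genes[[nm]]
    if (!g %in% rownames(expr)) {
      idicss_log("baseline ", nm, " skipped: gene ", g, " absent")
      next
    }
    out[[nm]] <- as.numeric(row_zscore(expr[g, , drop = FALSE]))
  }
  for (nm in names(pair_sets)) {
    pr <- as.matrix(pair_sets[[nm]])
    keep <- pr[, 1] %in% rownames(expr) & pr[, 2] %in% rownames(expr)
    if (!any(keep)) {
      idicss_log("pair baseline ", nm, " skipped: no pairs present")
      next
    }
    pr <- pr[keep, , drop = FALSE]
    out[[nm]] <- unname(colSums(expr[pr[, 1], , drop = FALSE] >
                                  expr[pr[, 2], , drop = FALSE]))
  }
  out
}

#' Drug-sensitivity correlation screen
#'
#' Per drug: Spearman correlation of IC50 against the cell-line iDICss
#' score, BH adjustment over drugs, candidate when `|rho| >= rho_min` and
#' `q < q_max`; plus a rank-sum test of IC50 between high/low score groups
#' (median split). Drugs with constant IC50 are flagged `degenerate` and
#' never candidates.
#'
#' @param cellline_scores Named numeric vector, iDICss per cell line.
#' @param ic50 Drug x cell-line matrix of IC50 values.
#' @param rho_min Minimum |Spearman rho| (default 0.3).
#' @param q_max BH q cutoff (default 0.05).
#' @return Tibble: `drug`, `rho`, `p`, `q`, `group_p` (high vs low
#'   rank-sum), `candidate`, `degenerate`.
#' @export
drug_screen <- function(cellline_scores, ic50, rho_min = 0.3, q_max = 0.05) {
  shared <- intersect(names(cellline_scores), colnames(ic50))
  if (length(shared) < 10L) stopf("need at least 10 shared cell lines")
  sc <- cellline_scores[shared]
  ic50 <- ic50[, shared, drop = FALSE]
  grp_high <- sc > median(sc)
  rows <- purrr::map_dfr(rownames(ic50), function(d) {
    y <- ic50[d, ]
    if (sd(y) == 0) {
      return(tibble::tibble(drug = d, rho = NA_real_, p = NA_real_,
                            group_p = NA_real_, degenerate = TRUE))
    }
    ct <- suppressWarnings(cor.test(sc, y, method = "spearman"))
    gp <- suppressWarnings(
      wilcox.test(y[grp_high], y[!grp_high], exact = FALSE)$p.value
    )
    tibble::tibble(drug = d, rho = unname(ct$estimate), p = ct$p.value,
                   group_p = gp, degenerate = FALSE)
  })
  rows$q <- p.adjust(rows$p, method = "BH")
  rows$candidate <- !rows$degenerate & !is.na(rows$q) &
    abs(rows$rho) >= rho_min & rows$q < q_max
  dplyr::arrange(
    rows[, c("drug", "rho", "p", "q", "group_p", "candidate", "degenerate")],
    .data$q
  )
}

#' ORR comparison between risk groups
#'
#' Responder counts per risk group with Fisher's exact test, alongside a
#' rank-sum comparison of scores between responders and non-responders.
#'
#' @param scores Numeric iDICss values.
#' @param groups "high"/"low" risk labels.
#' @param labels Response labels (see [response_auc()]).
#' @return Tibble: `orr_low`, `orr_high`, `fisher_p`, `ranksum_p`.
#' @export
orr_comparison <- function(scores, groups, labels) {
  y <- as_responder(labels)
  tab <- table(factor(groups, levels = c("low", "high")),
               factor(y, levels = c(0, 1)))
  fp <- fisher.test(tab)$p.value
  rp <- suppressWarnings(
    wilcox.test(scores[y == 1], scores[y == 0], exact = FALSE)$p.value
  )
  tibble::tibble(
    orr_low = safe_rate(sum(groups == "low" & y == 1), sum(groups == "low")),
    orr_high = safe_rate(sum(groups == "high" & y == 1), sum(groups == "high")),
    fisher_p = fp, ranksum_p = rp
  )
}

#' @noRd
safe_rate <- function(num, den) if (den == 0) NA_real_ else num / den
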