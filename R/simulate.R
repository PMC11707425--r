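# synthetic_data: cohorts with planted latent components, mutation links,
# survival/response signal, and cell-line drug panels. Sources are Laplace
# (heavy-tailed) so the ICA model is identifiable; Gaussian sources would
# not be.
#
# Planted structure mirrors the melanoma study design: samples fall into an
# immune-hot and an immune-cold regime separated on the immune components'
# weights; driver mutations linked to immune components are enriched where
# the component weight is high; hazard genes load negatively on the immune
# components (immune-hot tumors fare better) while keeping private,
# noise-scaled variation of their own so individual hazard genes remain
# identifiable by penalized regression.

#' @noRd
rlaplace <- function(n, scale = 1) {
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Simulation configuration
#'
#' Defaults describe a desk-scale melanoma-like cohort: 2,000 genes x 300
#' samples mixing 10 Laplace sources (3 immune), 20 driver genes, 10 risk
#' genes with hazard ratio 2 per SD, ~30% censoring, and two planted
#' immune regimes.
#'
#' @param n_genes,n_samples,n_components,n_immune_components Dimensions.
#' @param support_size Genes with large loadings per component (supports
#'   are disjoint across components).
#' @param immune_set_extra Extra (non-support) genes added to each emitted
#'   immune gene set.
#' @param loading_scale Laplace scale of support loadings.
#' @param background_scale Laplace scale of off-support loadings.
#' @param noise_sd Gaussian expression noise SD.
#' @param n_drivers Driver genes; the first `n_driver_links` are linked to
#'   components (round-robin, immune components first, positive-loading
#'   support genes so mutation enrichment aligns with the hot regime).
#' @param n_driver_links Planted driver-component links.
#' @param mutation_rate Baseline per-gene mutation probability.
#' @param driver_effect Log-odds shift per SD of the linked component's
#'   weight.
#' @param n_risk_genes Planted hazard genes (off-support genes given a
#'   `risk_loading` on an immune component plus private noise).
#' @param risk_loading Loading of each risk gene on its immune component
#'   (negative: immune-hot lowers hazard).
#' @param risk_private_mult Private risk-gene noise SD as a multiple of
#'   `noise_sd` (keeps the noiseless case an exact factorization).
#' @param hazard_per_sd Log hazard ratio per SD of a risk gene (default
#'   `log(2)`).
#' @param censoring_rate Target fraction censored.
#' @param cluster_shift Gap between the regime means of immune-component
#'   weights.
#' @param cluster_within_sd Within-regime SD of immune-component weights.
#' @param response_slope Logistic slope of response on the negated,
#'   z-scored true log-hazard.
#' @param seed Integer seed (mandatory).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 300L,
                       n_components = 10L, n_immune_components = 3L,
                       support_size = 40L, immune_set_extra = 20L,
                       loading_scale = 3, background_scale = 0.05,
                       noise_sd = 0.3, n_drivers = 20L,
                       n_driver_links = 10L, mutation_rate = 0.1,
                       driver_effect = 1.5, n_risk_genes = 10L,
                       risk_loading = -0.7, risk_private_mult = 3,
                       hazard_per_sd = log(2), censoring_rate = 0.3,
                       cluster_shift = 2, cluster_within_sd = 0.4,
                       response_slope = 1.5, seed = 1L) {
  cfg <- as.list(environment())
  counts <- cfg[c("n_genes", "n_samples", "n_components",
                  "n_immune_components", "support_size", "n_drivers",
                  "n_risk_genes")]
  if (any(unlist(counts) <= 0)) stopf("all counts must be positive")
  rates <- cfg[c("mutation_rate", "censoring_rate")]
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stopf("rates must be in [0, 1]")
  if (cfg$n_immune_components > cfg$n_components)
    stopf("n_immune_components exceeds n_components")
  if (cfg$n_components * cfg$support_size + cfg$n_risk_genes +
        cfg$n_drivers > cfg$n_genes)
    stopf("component supports, drivers and risk genes exceed the gene count")
  if (cfg$n_driver_links > cfg$n_drivers)
    stopf("n_driver_links exceeds n_drivers")
  if (is.null(seed)) stopf("seed is mandatory")
  structure(cfg, class = "sim_config")
}

# Draw the planted structure (gene identities, loadings, links) once; it is
# shared by the training cohort and any validation cohorts.
#' @noRd
simulate_structure <- function(c_) {
  genes <- sprintf("G%05d", seq_len(c_$n_genes))
  k <- c_$n_components
  perm <- sample(genes)
  supports <- split(perm[seq_len(k * c_$support_size)],
                    rep(seq_len(k), each = c_$support_size))
  free_genes <- perm[-seq_len(k * c_$support_size)]

  S <- matrix(rlaplace(c_$n_genes * k, c_$background_scale),
              c_$n_genes, k, dimnames = list(genes, NULL))
  for (c0 in seq_len(k))
    S[supports[[c0]], c0] <- rlaplace(c_$support_size, c_$loading_scale)

  imm <- seq_len(c_$n_immune_components)

  # risk genes: off-support, negative loading on an immune component
  risk_genes <- sample(free_genes, c_$n_risk_genes)
  free_genes <- setdiff(free_genes, risk_genes)
  risk_comp <- imm[((seq_len(c_$n_risk_genes) - 1) %% length(imm)) + 1]
  for (i in seq_len(c_$n_risk_genes))
    S[risk_genes[i], risk_comp[i]] <- c_$risk_loading

  # immune gene sets: support genes of the immune components + extras
  immune_sets <- lapply(imm, function(c0) {
    unique(c(supports[[c0]], sample(free_genes, c_$immune_set_extra)))
  })
  names(immune_sets) <- sprintf("immune_set_%d", imm)
  attr(immune_sets, "description") <-
    setNames(rep("synthetic immune signature", length(imm)),
             names(immune_sets))

  # linked drivers: round-robin starting at the immune components; on
  # immune components the link is a positive-loading support gene with
  # sign +1 so mutation enrichment tracks the hot regime
  links <- tibble::tibble(gene = character(0), component = integer(0),
                          sign = numeric(0))
  linked <- character(0)
  k_order <- c(imm, setdiff(seq_len(k), imm))
  for (j in seq_len(c_$n_driver_links)) {
    comp <- k_order[((j - 1) %% k) + 1L]
    pool <- setdiff(supports[[comp]], linked)
    if (comp %in% imm) {
      pos <- pool[S[pool, comp] > 0]
      g <- sample(if (length(pos)) pos else pool, 1)
      sgn <- 1
    } else {
      g <- sample(pool, 1)
      sgn <- sample(c(-1, 1), 1)
    }
    linked <- c(linked, g)
    links <- dplyr::bind_rows(links, tibble::tibble(
      gene = g, component = comp, sign = sgn))
  }
  other_drivers <- sample(free_genes, c_$n_drivers - c_$n_driver_links)
  driver_genes <- c(linked, other_drivers)
  mut_genes <- unique(c(driver_genes, unlist(immune_sets)))

  list(genes = genes, supports = supports, free_genes = free_genes,
       S = S, immune_components = imm, immune_sets = immune_sets,
       risk_genes = risk_genes, risk_components = risk_comp,
       driver_links = links, driver_genes = driver_genes,
       mut_genes = mut_genes, config = c_)
}

# Sample one cohort (samples, expression, mutations, clinical) from a
# planted structure.
#' @noRd
sample_cohort <- function(str, n_samples, sample_prefix = "S") {
  c_ <- str$config
  k <- c_$n_components
  samples <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  imm <- str$immune_components

  W <- matrix(rnorm(k * n_samples), k, n_samples,
              dimnames = list(NULL, samples))
  hot <- seq_len(n_samples) > n_samples / 2
  W[imm, ] <- rep(ifelse(hot, c_$cluster_shift / 2, -c_$cluster_shift / 2),
                  each = length(imm)) +
    rnorm(length(imm) * n_samples, sd = c_$cluster_within_sd)
  clusters <- ifelse(hot, "hot", "cold")

  expr <- str$S %*% W
  if (c_$noise_sd > 0)
    expr <- expr + matrix(rnorm(length(expr), sd = c_$noise_sd),
                          nrow(expr), ncol(expr))
  # private risk-gene variation, scaled by the noise level so the
  # noiseless configuration stays an exact factorization
  priv_sd <- c_$risk_private_mult * c_$noise_sd
  if (priv_sd > 0)
    expr[str$risk_genes, ] <- expr[str$risk_genes, ] +
      matrix(rnorm(c_$n_risk_genes * n_samples, sd = priv_sd),
             c_$n_risk_genes, n_samples)
  dimnames(expr) <- list(str$genes, samples)

  mut <- matrix(rbinom(length(str$mut_genes) * n_samples, 1,
                       c_$mutation_rate),
                length(str$mut_genes), n_samples,
                dimnames = list(str$mut_genes, samples))
  for (r in seq_len(nrow(str$driver_links))) {
    wz <- as.numeric(scale(W[str$driver_links$component[r], ]))
    pr <- stats::plogis(stats::qlogis(c_$mutation_rate) +
                          c_$driver_effect * str$driver_links$sign[r] * wz)
    mut[str$driver_links$gene[r], ] <- rbinom(n_samples, 1, pr)
  }

  beta <- setNames(rep(c_$hazard_per_sd, c_$n_risk_genes), str$risk_genes)
  zr <- row_zscore(expr[str$risk_genes, , drop = FALSE])
  log_hazard <- as.numeric(t(zr) %*% beta)
  base_rate <- log(2) / 730            # median ~2 years at zero risk
  ev_time <- rexp(n_samples, rate = base_rate * exp(log_hazard))
  cens_rate <- base_rate * c_$censoring_rate /
    max(1 - c_$censoring_rate, 1e-6)
  cens_time <- rexp(n_samples, rate = cens_rate)
  os_time <- pmin(ev_time, cens_time, 3650)
  os_event <- as.integer(ev_time <= pmin(cens_time, 3650))

  resp_logit <- -c_$response_slope * as.numeric(scale(log_hazard))
  response <- ifelse(rbinom(n_samples, 1, stats::plogis(resp_logit)) == 1,
                     "responder", "non-responder")

  clinical <- tibble::tibble(sample = samples, os_time = os_time,
                             os_event = os_event, response = response)
  bundle <- align_cohort(expr, clinical, mutations = mut,
                         metadata = list(source = "idicss simulation",
                                         seed = c_$seed))
  list(bundle = bundle, W = W,
       log_hazard = setNames(log_hazard, samples),
       clusters = setNames(clusters, samples))
}

#' Simulate a cohort with planted structure
#'
#' Expression is `S %*% W` plus Gaussian noise, with disjoint sparse
#' Laplace loading supports per component. Immune components' support
#' genes seed the emitted immune gene sets and carry planted PPI cliques.
#' Samples split into an immune-hot and an immune-cold regime (the two
#' planted iDIC regimes) separated on the immune components' weights.
#' Driver mutations are Bernoulli with log-odds shifted by the linked
#' component's weights. Survival is exponential with log-hazard
#' `sum(beta_g * z_g)` over planted risk genes, which load negatively on
#' the immune components (hot regime = better outcome); censoring is
#' independent exponential calibrated to the configured rate. Response is
#' Bernoulli with logit `-slope * z(true risk)` — lower risk, higher
#' response probability.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (a `cohort_bundle`), `truth` (planted S, W,
#'   immune component indices, supports, driver links, risk
#'   genes/coefficients, per-sample log-hazard, regime labels, config),
#'   `immune_sets` (GMT-style list), `driver_genes`, `ppi` (igraph).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), {
    str <- simulate_structure(config)
    coh <- sample_cohort(str, config$n_samples)
    imm_sup <- str$supports[str$immune_components]
    # clique members = strongest-loading support genes (immune hub genes),
    # which are also the genes the top-gene step will report
    hubs <- lapply(seq_along(imm_sup), function(i) {
      sup <- imm_sup[[i]]
      comp <- str$immune_components[i]
      sup[order(-abs(str$S[sup, comp]))]
    })
    ppi <- simulate_ppi(str$genes, hubs)
    truth <- list(
      S = str$S, W = coh$W, immune_components = str$immune_components,
      supports = str$supports, driver_links = str$driver_links,
      driver_genes = str$driver_genes, risk_genes = str$risk_genes,
      risk_coefficients = setNames(rep(config$hazard_per_sd,
                                       config$n_risk_genes),
                                   str$risk_genes),
      log_hazard = coh$log_hazard, clusters = coh$clusters,
      structure = str, config = config
    )
    list(bundle = coh$bundle, truth = truth, immune_sets = str$immune_sets,
         driver_genes = str$driver_genes, ppi = ppi)
  })
}

#' Simulate a validation cohort from an existing planted structure
#'
#' Draws new samples (weights, noise, mutations, survival, response) from
#' the same generative model — same gene identities, loadings, driver
#' links and risk genes — as a cohort produced by [simulate_cohort()].
#'
#' @param sim Output of [simulate_cohort()].
#' @param n_samples Number of new samples (default: the training size).
#' @param seed Integer seed for the new draw.
#' @param sample_prefix Prefix for the new sample IDs (default "V").
#' @return List with `bundle`, `log_hazard`, `clusters`.
#' @export
simulate_validation <- function(sim, n_samples = NULL, seed = 1L,
                                sample_prefix = "V") {
  str <- sim$truth$structure
  if (is.null(n_samples)) n_samples <- str$config$n_samples
  withr::with_seed(as.integer(seed), {
    coh <- sample_cohort(str, n_samples, sample_prefix = sample_prefix)
    list(bundle = coh$bundle, log_hazard = coh$log_hazard,
         clusters = coh$clusters)
  })
}

# Scale-free background graph over a gene subset plus planted cliques on
# part of each immune component's support.
#' @noRd
simulate_ppi <- function(genes, immune_supports,
                         n_background = 1200L, clique_size = 12L) {
  support_genes <- unique(unlist(immune_supports))
  background <- unique(c(
    support_genes,
    sample(setdiff(genes, support_genes),
           min(n_background, length(genes) - length(support_genes)))
  ))
  g <- igraph::sample_pa(length(background), m = 2, directed = FALSE)
  igraph::V(g)$name <- sample(background)   # detach degree from identity
  for (sup in immune_supports) {
    cl <- sup[seq_len(min(clique_size, length(sup)))]
    new_edges <- t(utils::combn(cl, 2))
    g <- igraph::add_edges(g, t(new_edges))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Simulate a cell-line drug panel tied to a signature
#'
#' Cell-line expression contains the signature genes (plus background
#' genes); for the designated "true hit" drugs, IC50 is a monotone function
#' of the line's signature score plus noise, other drugs are independent.
#'
#' @param signature A `gene_signature` (or named coefficient vector).
#' @param n_lines Number of cell lines (default 40).
#' @param n_drugs Number of drugs (default 50).
#' @param n_hits Number of true-hit drugs (default 5).
#' @param noise_sd IC50 noise SD for hit drugs (default 0.3; 0 gives
#'   |rho| = 1).
#' @param n_background_genes Extra non-signature genes (default 200).
#' @param seed Integer seed.
#' @return List with `expression` (genes x lines), `ic50`
#'   (drugs x lines), `truth` (hit drug names and signs), `scores`
#'   (iDICss per line).
#' @export
simulate_cellline_panel <- function(signature, n_lines = 40L, n_drugs = 50L,
                                    n_hits = 5L, noise_sd = 0.3,
                                    n_background_genes = 200L, seed = 1L) {
  beta <- if (inherits(signature, "gene_signature")) signature$coefficients
          else signature
  if (length(beta) == 0) stopf("signature is empty")
  withr::with_seed(as.integer(seed), {
    lines <- sprintf("CL%03d", seq_len(n_lines))
    bg <- sprintf("BG%04d", seq_len(n_background_genes))
    genes <- c(names(beta), bg)
    expr <- matrix(rnorm(length(genes) * n_lines), length(genes), n_lines,
                   dimnames = list(genes, lines))
    sc <- score_idicss(expr, beta)$scores$idicss
    names(sc) <- lines
    drugs <- sprintf("drug_%03d", seq_len(n_drugs))
    ic50 <- matrix(rnorm(n_drugs * n_lines), n_drugs, n_lines,
                   dimnames = list(drugs, lines))
    hits <- character(0); signs <- numeric(0)
    if (n_hits > 0) {
      hits <- drugs[seq_len(min(n_hits, n_drugs))]
      signs <- sample(c(-1, 1), length(hits), replace = TRUE)
      for (i in seq_along(hits)) {
        ic50[hits[i], ] <- signs[i] * as.numeric(scale(sc)) +
          rnorm(n_lines, sd = noise_sd)
      }
    }
    list(expression = expr, ic50 = ic50,
         truth = list(hits = hits, signs = signs), scores = sc)
  })
}
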