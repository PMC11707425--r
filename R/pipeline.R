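# End-to-end pipeline: ica -> select -> profile -> train -> evaluate.

#' Run the full iDICss pipeline on one cohort
#'
#' Convenience wrapper chaining [fit_ica()], [select_key_ics()],
#' [idic_profile()], [consensus_cluster()], [differential_genes()],
#' [fit_lasso_cox()], [score_idicss()] and the survival evaluation. When
#' selection yields no key component, the top `fallback_key_ics`
#' components by enrichment q are used so downstream stages stay runnable
#' (recorded in the result).
#'
#' @param bundle A `cohort_bundle` with mutations and clinical data.
#' @param immune_sets Immune gene-set list (GMT-style).
#' @param ppi PPI igraph.
#' @param driver_genes Driver gene vector.
#' @param k Number of components (default 10 for desk-scale cohorts; the
#'   melanoma-scale analysis uses ~100).
#' @param lambda Blending weight (default 0.7).
#' @param n_perm PPI permutations (default 499).
#' @param de_q_max,de_fc_min Differential-expression thresholds passed to
#'   [differential_genes()]. Candidate pool falls back to the
#'   `max_candidates` smallest-q genes when fewer than `min_candidates`
#'   pass.
#' @param min_candidates,max_candidates Candidate pool bounds
#'   (defaults 20 and 200).
#' @param seed Integer seed driving every stochastic stage.
#' @return List of stage results: `decomp`, `relevance`, `key_ics`,
#'   `profile`, `subgroups`, `de_table`, `signature`, `scores`,
#'   `survival`, `fallback_used`.
#' @export
run_pipeline <- function(bundle, immune_sets, ppi, driver_genes,
                         k = 10L, lambda = 0.7, n_perm = 499L,
                         de_q_max = 0.05, de_fc_min = 1,
                         min_candidates = 20L, max_candidates = 200L,
                         seed = 1L) {
  seeds <- derive_seeds(seed, 6)
  decomp <- fit_ica(bundle$expression, k = k, seed = seeds[1])
  relevance <- select_key_ics(decomp, immune_sets, ppi, n_perm = n_perm,
                              seed = seeds[2])
  key_ics <- relevance$component[relevance$selected]
  fallback_used <- FALSE
  if (length(key_ics) == 0) {
    key_ics <- head(relevance$component, 3L)
    fallback_used <- TRUE
    idicss_log("no component passed selection; using top 3 by q",
               level = "WARN")
  }
  immune_genes <- unique(unlist(immune_sets))
  profile <- idic_profile(decomp, bundle$mutations, key_ics, driver_genes,
                          immune_genes, lambda = lambda)
  subgroups <- consensus_cluster(profile, seed = seeds[3],
                                 expression = bundle$expression,
                                 immune_genes = immune_genes)
  de_table <- differential_genes(bundle$expression, subgroups,
                                 q_max = de_q_max, fc_min = de_fc_min)
  candidates <- de_table$gene[de_table$candidate]
  if (length(candidates) < min_candidates) {
    candidates <- head(de_table$gene, max_candidates)
    idicss_log("DE candidates below ", min_candidates,
               "; using top ", max_candidates, " by q")
  } else if (length(candidates) > max_candidates) {
    candidates <- head(de_table$gene[de_table$candidate], max_candidates)
  }
  signature <- fit_lasso_cox(bundle$expression, bundle$clinical,
                             candidates = candidates, seed = seeds[4])
  scores <- score_idicss(bundle$expression, signature)
  merged <- dplyr::inner_join(scores$scores, bundle$clinical, by = "sample")
  surv_cmp <- km_logrank(merged$os_time, merged$os_event, merged$group)
  list(decomp = decomp, relevance = relevance, key_ics = key_ics,
       profile = profile, subgroups = subgroups, de_table = de_table,
       signature = signature, scores = scores, survival = surv_cmp,
       fallback_used = fallback_used)
}
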