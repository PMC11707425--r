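# ic_select: immune-relevance screening of independent components.
#
# A component is called "key" when its top-gene set is (a) over-represented
# in at least one immune gene set (hypergeometric test, BH across the full
# component x set family) and (b) more densely connected in the reference
# PPI than degree-matched random gene sets (permutation test). The crosstalk
# network (Jaccard overlap of top-gene sets) is reported for inspection and
# visual clustering; it does not itself gate selection.

#' Build the component crosstalk network
#'
#' Nodes are components; an edge joins components whose top-gene sets have
#' Jaccard overlap at least `min_jaccard`, with the Jaccard as edge weight.
#'
#' @param decomp An `ica_decomposition`.
#' @param z_threshold Top-gene |z| cutoff (default 3).
#' @param min_jaccard Minimum Jaccard for an edge (default 0.05).
#' @return List with `graph` (weighted [igraph::graph]), `edges` (tibble
#'   `from`, `to`, `jaccard`) and `nodes` (tibble `component`,
#'   `n_top_genes`).
#' @export
build_crosstalk_network <- function(decomp, z_threshold = 3,
                                    min_jaccard = 0.05) {
  sets <- top_gene_sets(decomp, z_threshold)
  ids <- names(sets)
  k <- length(ids)
  edges <- purrr::map_dfr(seq_len(k - 1), function(i) {
    purrr::map_dfr(seq(i + 1, k), function(j) {
      jac <- jaccard(sets[[i]], sets[[j]])
      if (jac >= min_jaccard && jac > 0)
        tibble::tibble(from = ids[i], to = ids[j], jaccard = jac)
      else tibble::tibble()
    })
  })
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else tibble::tibble(from = character(),
                                               to = character(),
                                               jaccard = numeric()),
    directed = FALSE,
    vertices = data.frame(name = ids, n_top_genes = lengths(sets))
  )
  if (nrow(edges)) igraph::E(g)$weight <- edges$jaccard
  list(graph = g, edges = edges,
       nodes = tibble::tibble(component = ids, n_top_genes = lengths(sets)))
}

#' @noRd
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Hypergeometric over-representation test
#'
#' One-sided tail probability `P[X >= overlap]` for the overlap between a
#' query gene set and a target set drawn from a finite universe.
#'
#' @param query,target Character vectors of gene symbols; both must be
#'   subsets of `universe`.
#' @param universe Character vector, the gene universe.
#' @return List with `p` and `overlap`.
#' @export
hypergeom_enrichment <- function(query, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("empty universe")
  query <- unique(query); target <- unique(target)
  if (length(setdiff(query, universe)))
    stopf("query contains genes outside the universe")
  if (length(setdiff(target, universe)))
    stopf("target contains genes outside the universe")
  q <- length(intersect(query, target))
  # P[X >= q] with X ~ Hypergeom(white = |target|, black = N - |target|,
  # drawn = |query|)
  p <- phyper(q - 1, length(target), length(universe) - length(target),
              length(query), lower.tail = FALSE)
  list(p = min(1, p), overlap = q)
}

#' Degree-matched PPI connectivity permutation test
#'
#' Observed statistic: number of PPI edges with both endpoints in the query
#' set. Null: gene sets of the same size drawn degree-matched — network
#' genes are binned into degree deciles and nulls sample within the query's
#' bins. One-sided p with the add-one correction
#' `(1 + #\{null >= obs\}) / (1 + n_perm)`.
#'
#' @param genes Query gene set; at least 2 must be PPI nodes.
#' @param ppi An [igraph::graph] (see [read_ppi()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param n_bins Number of degree-quantile bins (default 10).
#' @return List with `p`, `observed` (edge count), `null_mean`, `n_in_ppi`.
#' @export
ppi_connectivity_test <- function(genes, ppi, n_perm = 999L, seed = 1L,
                                  n_bins = 10L) {
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  nodes <- igraph::V(ppi)$name
  present <- intersect(unique(genes), nodes)
  if (length(present) < 2L) stopf("fewer than 2 query genes in the PPI")
  deg <- igraph::degree(ppi)
  breaks <- unique(quantile(deg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  names(bin) <- nodes
  by_bin <- split(nodes, bin)

  adj <- igraph::as_adjacency_matrix(ppi, sparse = TRUE)
  count_edges <- function(set) {
    idx <- match(set, nodes)
    sum(adj[idx, idx]) / 2
  }
  observed <- count_edges(present)
  qbins <- bin[present]
  bin_tab <- table(qbins)
  nulls <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      draw <- unlist(lapply(names(bin_tab), function(b) {
        pool <- by_bin[[b]]
        if (length(pool) == 1) pool
        else sample(pool, bin_tab[[b]], replace = FALSE)
      }), use.names = FALSE)
      count_edges(draw)
    }, numeric(1))
  })
  list(p = (1 + sum(nulls >= observed)) / (1 + n_perm),
       observed = observed, null_mean = mean(nulls),
       n_in_ppi = length(present))
}

#' Select key immune-relevant components
#'
#' For every component: the best BH-adjusted immune-set enrichment q
#' (adjustment over the full component x set family) and the PPI
#' connectivity permutation p. A component is selected when
#' `best_q < q_max` and `ppi_p < p_max`.
#'
#' @param decomp An `ica_decomposition`.
#' @param immune_sets Named list of immune gene sets (see [read_gmt()]).
#' @param ppi An [igraph::graph] PPI reference.
#' @param z_threshold Top-gene |z| cutoff (default 3).
#' @param q_max,p_max Selection thresholds (defaults 0.05).
#' @param n_perm Permutations for the PPI test (default 999).
#' @param seed Integer seed.
#' @return Tibble (one row per component, sorted by `best_q`):
#'   `component`, `n_top_genes`, `best_set`, `best_p`, `best_q`,
#'   `best_overlap`, `ppi_p`, `ppi_observed`, `selected`.
#' @export
select_key_ics <- function(decomp, immune_sets, ppi, z_threshold = 3,
                           q_max = 0.05, p_max = 0.05, n_perm = 999L,
                           seed = 1L) {
  if (length(immune_sets) == 0) stopf("no immune gene sets supplied")
  universe <- rownames(decomp$S)
  sets <- top_gene_sets(decomp, z_threshold)
  immune_sets <- lapply(immune_sets, intersect, y = universe)

  enr <- purrr::map_dfr(names(sets), function(comp) {
    purrr::map_dfr(names(immune_sets), function(is_name) {
      h <- hypergeom_enrichment(sets[[comp]], immune_sets[[is_name]], universe)
      tibble::tibble(component = comp, immune_set = is_name,
                     p = h$p, overlap = h$overlap)
    })
  })
  enr$q <- p.adjust(enr$p, method = "BH")

  seeds <- derive_seeds(seed, length(sets))
  ppi_rows <- purrr::map2_dfr(names(sets), seeds, function(comp, s) {
    res <- tryCatch(
      ppi_connectivity_test(sets[[comp]], ppi, n_perm = n_perm, seed = s),
      error = function(e) list(p = NA_real_, observed = NA_real_)
    )
    tibble::tibble(component = comp, ppi_p = res$p,
                   ppi_observed = res$observed)
  })

  best <- enr |>
    dplyr::group_by(.data$component) |>
    dplyr::slice_min(.data$q, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(best_set = "immune_set", best_p = "p", best_q = "q",
                  best_overlap = "overlap")
  out <- best |>
    dplyr::left_join(ppi_rows, by = "component") |>
    dplyr::mutate(
      n_top_genes = lengths(sets)[.data$component],
      selected = !is.na(.data$ppi_p) & .data$best_q < q_max &
        .data$ppi_p < p_max
    ) |>
    dplyr::arrange(.data$best_q) |>
    dplyr::select("component", "n_top_genes", "best_set", "best_p",
                  "best_q", "best_overlap", "ppi_p", "ppi_observed",
                  "selected")
  attr(out, "enrichment") <- enr
  out
}

#' Plot a key-IC relevance table
#'
#' Scatter of -log10 enrichment q against -log10 PPI permutation p, with
#' selected components highlighted.
#'
#' @param relevance Output of [select_key_ics()].
#' @return A ggplot object.
#' @export
plot_ic_relevance <- function(relevance) {
  ggplot2::ggplot(relevance,
                  ggplot2::aes(x = -log10(.data$best_q),
                               y = -log10(.data$ppi_p),
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$component),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "-log10 best immune-set q (BH)",
                  y = "-log10 PPI connectivity p",
                  colour = "selected") +
    ggplot2::theme_minimal()
}
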