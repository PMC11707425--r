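test_that("crosstalk edges carry the Jaccard overlap of top-gene sets", {
  # build a fake decomposition whose top-gene sets are fully controlled
  mk_col <- function(hot, n = 200) {
    v <- rnorm(n, sd = 0.01); v[hot] <- 10; v / sd(v)
  }
  genes <- sprintf("g%03d", 1:200)
  S <- cbind(IC1 = mk_col(1:3), IC2 = mk_col(2:4), IC3 = mk_col(101:103),
             IC4 = mk_col(1:3))
  rownames(S) <- genes
  fake <- structure(list(S = S, W = matrix(0, 4, 2,
                                           dimnames = list(colnames(S),
                                                           c("a", "b"))),
                         k = 4L), class = "ica_decomposition")
  net <- build_crosstalk_network(fake, z_threshold = 3, min_jaccard = 0.05)
  e <- net$edges
  # sets: IC1={1,2,3}, IC2={2,3,4}: |i|=2,|u|=4 -> 0.5; IC4 identical to IC1
  expect_equal(e$jaccard[e$from == "IC1" & e$to == "IC2"], 0.5)
  expect_equal(e$jaccard[e$from == "IC1" & e$to == "IC4"], 1.0)
  expect_false(any(e$from == "IC3" | e$to == "IC3"))   # disjoint: no edge
  expect_true(all(e$jaccard >= 0 & e$jaccard <= 1))
})

test_that("hypergeometric tail matches exhaustive enumeration", {
  u <- paste0("g", 1:10)
  res <- hypergeom_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(10, 5))   # 1/252, full overlap of 5
  expect_equal(res$overlap, 5L)
  expect_equal(res$p, oracle_hypergeom(5, 5, 10, 5))

  # zero overlap -> p = 1 (P[X >= 0])
  res0 <- hypergeom_enrichment(u[1:3], u[4:10], u)
  expect_equal(res0$p, 1)
  # query = universe forces overlap = |target|, p = 1
  resu <- hypergeom_enrichment(u, u[1:4], u)
  expect_equal(resu$overlap, 4L)
  expect_equal(resu$p, 1)

  expect_error(hypergeom_enrichment(c(u[1], "absent"), u[1:2], u),
               "outside the universe")
  expect_error(hypergeom_enrichment(u[1], u[2], character(0)), "empty")
})

test_that("BH adjustment agrees with the hand step-up rule and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  set.seed(8)
  for (i in 1:20) {
    pr <- runif(sample(3:12, 1))
    q <- p.adjust(pr, "BH")
    expect_equal(q, oracle_bh(pr))
    expect_true(all(diff(q[order(pr)]) >= -1e-12))   # monotone in p
  }
})

test_that("PPI connectivity test flags planted cliques and is deterministic", {
  set.seed(21)
  g <- igraph::sample_gnp(300, 0.01)
  igraph::V(g)$name <- paste0("g", 1:300)
  clique <- paste0("g", 1:5)
  g <- igraph::add_edges(g, t(t(utils::combn(clique, 2))))
  g <- igraph::simplify(g)

  res <- ppi_connectivity_test(clique, g, n_perm = 999, seed = 4)
  expect_lte(res$p, 0.01)
  expect_gte(res$observed, 10)

  res2 <- ppi_connectivity_test(clique, g, n_perm = 999, seed = 4)
  expect_identical(res$p, res2$p)        # same seed, same p

  # two unconnected genes: observed 0 -> p = 1
  iso <- igraph::make_ring(10)
  igraph::V(iso)$name <- paste0("h", 1:10)
  res0 <- ppi_connectivity_test(c("h1", "h5"), iso, n_perm = 199, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)

  expect_error(ppi_connectivity_test("h1", iso, n_perm = 199, seed = 1),
               "fewer than 2")
  expect_error(ppi_connectivity_test(c("h1", "h2"), iso, n_perm = 10,
                                     seed = 1), "n_perm")
})

test_that("planted immune components are exactly the ones selected", {
  sim <- small_sim()
  d <- fit_ica(sim$bundle$expression, k = 5, seed = 3)
  rel <- select_key_ics(d, sim$immune_sets, sim$ppi, n_perm = 499, seed = 5)
  expect_identical(nrow(rel), 5L)
  expect_true(all(rel$best_q >= 0 & rel$best_q <= 1, na.rm = TRUE))

  truth_map <- idicss:::match_components(
    sim$truth$S[, sim$truth$immune_components, drop = FALSE], d$S)
  planted <- colnames(d$S)[truth_map$index]
  expect_setequal(rel$component[rel$selected], planted)

  # immune sets disjoint from all top genes -> nothing selected, table kept
  alien <- list(alien = paste0("g", 1:20))
  # use genes actually in the universe but never top-loaded
  alien$alien <- setdiff(rownames(d$S), unlist(top_gene_sets(d, 3)))[1:30]
  rel0 <- select_key_ics(d, alien, sim$ppi, n_perm = 199, seed = 5)
  expect_identical(nrow(rel0), 5L)
  expect_false(any(rel0$selected & rel0$best_overlap > 0 & rel0$best_q < 0.05))

  expect_error(select_key_ics(d, list(), sim$ppi), "no immune gene sets")
})
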