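test_that("mutation shifting a component's weights is detected with the right direction", {
  set.seed(14)
  n <- 150
  W <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("IC", 1:3), paste0("s", 1:n)))
  mut <- matrix(0L, 2, n, dimnames = list(c("gShift", "gNull"),
                                          colnames(W)))
  carriers <- sample(n, 40)
  mut["gShift", carriers] <- 1L
  mut["gNull", sample(n, 30)] <- 1L
  W["IC2", carriers] <- W["IC2", carriers] + 2   # +2 SD planted shift

  tab <- driver_ic_association(W, mut, min_mutated = 5)
  hit <- tab[tab$gene == "gShift" & tab$component == "IC2", ]
  expect_lt(hit$q, 0.01)
  expect_identical(hit$direction, "+")
  expect_gt(hit$effect, 0.5)

  # unmutated gene is absent under the min_mutated filter
  mut0 <- rbind(mut, gAbsent = 0L)
  tab0 <- driver_ic_association(W, mut0, min_mutated = 5)
  expect_false("gAbsent" %in% tab0$gene)

  # identical weights across groups -> p near 1, effect near 0
  Wnull <- matrix(rep(seq_len(n), each = 1), 1, n,
                  dimnames = list("IC1", colnames(W)))
  Wnull["IC1", ] <- rep(c(1, 2), length.out = n)
  tabn <- driver_ic_association(Wnull, mut["gNull", , drop = FALSE],
                                min_mutated = 5)
  expect_gt(tabn$p, 0.3)
})

test_that("mutation impact is the loading sum of mutated set genes, z-scored by row", {
  genes <- paste0("g", 1:6)
  S <- matrix(rnorm(12), 6, 2, dimnames = list(genes, c("IC1", "IC2")))
  samples <- paste0("s", 1:4)
  mut <- matrix(0L, 6, 4, dimnames = list(genes, samples))
  mut["g2", "s1"] <- 1L
  mut[c("g2", "g3"), "s2"] <- 1L
  mut[, "s4"] <- mut[, "s2"]         # duplicate mutation profile

  imp <- mutation_impact(S, mut, gene_set = c("g2", "g3"))
  raw <- rbind(IC1 = c(S["g2", 1], S["g2", 1] + S["g3", 1], 0,
                       S["g2", 1] + S["g3", 1]),
               IC2 = c(S["g2", 2], S["g2", 2] + S["g3", 2], 0,
                       S["g2", 2] + S["g3", 2]))
  expect_equal(unname(imp), unname(idicss:::row_zscore(raw)))
  expect_equal(imp[, "s2"], imp[, "s4"])   # identical profiles, identical impact

  # no mutated set gene anywhere -> zero-variance rows -> all-zero impact
  mut0 <- mut; mut0[] <- 0L
  expect_true(all(mutation_impact(S, mut0, c("g2", "g3")) == 0))

  expect_error(mutation_impact(S, mut, "not_a_gene"), "no genes")
})

test_that("lambda blending follows its contract exactly", {
  dims <- list(paste0("IC", 1:2), paste0("s", 1:3))
  Wz <- matrix(rnorm(6), 2, 3, dimnames = dims)
  D <- matrix(rnorm(6), 2, 3, dimnames = dims)
  I1 <- matrix(rnorm(6), 2, 3, dimnames = dims)
  I2 <- matrix(rnorm(6), 2, 3, dimnames = dims)

  # lambda = 1: exactly invariant to the immune matrix
  expect_identical(blend_idic(Wz, D, I1, 1)$profile,
                   blend_idic(Wz, D, I2, 1)$profile)
  # no mutation impact: profile equals z-scored weights exactly
  zero <- matrix(0, 2, 3, dimnames = dims)
  expect_identical(blend_idic(Wz, zero, zero, 0.7)$profile, Wz)
  # scalar arithmetic of the formula at lambda = 0.7
  expect_equal(blend_idic(matrix(0.1, 1, 1, dimnames = list("IC1", "s1")),
                          matrix(1, 1, 1, dimnames = list("IC1", "s1")),
                          matrix(-1, 1, 1, dimnames = list("IC1", "s1")),
                          0.7)$profile[1, 1],
               0.5)
  # affine in lambda with slope D - I
  l1 <- blend_idic(Wz, D, I1, 0.2)$profile
  l2 <- blend_idic(Wz, D, I1, 0.9)$profile
  expect_equal((l2 - l1) / 0.7, D - I1)

  expect_error(blend_idic(Wz, D[, 1:2], I1, 0.5), "shape")
  expect_error(blend_idic(Wz, D, I1, 1.5), "lambda")
})

test_that("consensus clustering recovers well-separated blobs deterministically", {
  set.seed(5)
  n <- 80
  truth <- rep(c(0, 1), each = n / 2)
  prof <- rbind(f1 = rnorm(n, mean = truth * 4),
                f2 = rnorm(n, mean = -truth * 4))
  colnames(prof) <- paste0("s", 1:n)

  cl <- consensus_cluster(prof, k = 2, n_resample = 100, seed = 9)
  expect_gt(oracle_ari(cl$assignment$cluster, truth), 0.9)
  expect_true(all(c("clusterA", "clusterB") %in% cl$assignment$cluster))
  expect_gte(cl$pac, 0)

  cl2 <- consensus_cluster(prof, k = 2, n_resample = 100, seed = 9)
  expect_identical(cl$assignment, cl2$assignment)   # same seed, same labels

  # duplicated samples land in the same cluster
  dup <- cbind(prof, prof)
  colnames(dup) <- paste0("s", seq_len(2 * n))
  cld <- consensus_cluster(dup, k = 2, n_resample = 100, seed = 9)
  lab <- cld$assignment$cluster
  expect_identical(lab[1:n], lab[(n + 1):(2 * n)])

  expect_error(consensus_cluster(prof, k = 1), "k must be")
})

test_that("clusterA is anchored to the lower immune signature score", {
  set.seed(6)
  n <- 60
  hot <- seq_len(n) > n / 2
  genes <- paste0("g", 1:30)
  expr <- matrix(rnorm(30 * n), 30, n,
                 dimnames = list(genes, paste0("s", 1:n)))
  expr[1:10, hot] <- expr[1:10, hot] + 3      # immune-hot half
  prof <- rbind(f1 = ifelse(hot, 4, 0) + rnorm(n, sd = 0.3))
  colnames(prof) <- colnames(expr)
  cl <- consensus_cluster(prof, k = 2, n_resample = 80, seed = 2,
                          expression = expr, immune_genes = genes[1:10])
  sc <- signature_score(expr, genes[1:10])
  agg <- tapply(sc[cl$assignment$sample], cl$assignment$cluster, mean)
  expect_lt(agg[["clusterA"]], agg[["clusterB"]])
})

test_that("signature scores are mean gene z-scores and affine invariant", {
  set.seed(7)
  expr <- matrix(rnorm(50 * 40), 50, 40,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  # singleton set equals that gene's z-scored profile
  s1 <- signature_score(expr, "g5")
  expect_equal(unname(s1),
               as.numeric(scale(expr["g5", ])))
  # planted +1 SD shift on set genes in half the samples
  hot <- seq_len(40) > 20
  expr2 <- expr
  expr2[1:8, hot] <- expr2[1:8, hot] + 1
  sc <- signature_score(expr2, paste0("g", 1:8))
  expect_lt(wilcox.test(sc[hot], sc[!hot])$p.value, 0.01)
  # gene-wise affine rescaling changes nothing
  expr3 <- expr * rep(runif(50, 1, 5), 40) + rep(rnorm(50), 40)
  expect_equal(signature_score(expr3, paste0("g", 1:8)),
               signature_score(expr, paste0("g", 1:8)))
  expect_error(signature_score(expr, "nope"), "no genes")
})

test_that("the assembled iDIC profile has key-IC rows and finite entries", {
  sim <- small_sim()
  d <- fit_ica(sim$bundle$expression, k = 5, seed = 3)
  rel <- select_key_ics(d, sim$immune_sets, sim$ppi, n_perm = 199, seed = 5)
  key <- rel$component[rel$selected]
  prof <- idic_profile(d, sim$bundle$mutations, key, sim$driver_genes,
                       unique(unlist(sim$immune_sets)), lambda = 0.7)
  expect_identical(rownames(prof$profile), key)
  expect_identical(ncol(prof$profile), ncol(sim$bundle$expression))
  expect_true(all(is.finite(prof$profile)))
  expect_identical(prof$lambda, 0.7)
})
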