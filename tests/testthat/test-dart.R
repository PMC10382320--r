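make_z <- function(m) {
  # standardized matrix with stable dimnames for small examples
  standardize_rows(m)
}

test_that("standardize_rows centres and scales every gene row", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(standardize_rows(m)["g1", ], c(s1 = -1, s2 = 0, s3 = 1))

  flat <- matrix(5, 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  z <- standardize_rows(flat)
  expect_equal(unname(z["g1", ]), c(0, 0, 0))
  expect_identical(attr(z, "zero_variance"), "g1")

  set.seed(1)
  rnd <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  z <- standardize_rows(rnd)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(apply(z, 1, sd), rep(1, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("relevance network keeps only Fisher-z significant edges", {
  sig <- gene_signature("s", up = c("g1", "g2"), down = "g3")
  set.seed(11)
  base <- rnorm(50)
  m <- rbind(g1 = base, g2 = base,          # identical rows: r = 1
             g3 = rnorm(50))                # independent
  colnames(m) <- paste0("s", 1:50)
  net <- build_relevance_network(make_z(m), sig)
  expect_identical(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$gene_i, net$edges$gene_j), c("g1", "g2"))

  expect_error(build_relevance_network(make_z(m[, 1:3]), sig), "3 samples")
  one_gene <- gene_signature("one", up = "g1")
  expect_error(build_relevance_network(make_z(m), one_gene),
               "fewer than 2")
})

test_that("correlated blocks are recovered exactly as the oracle says", {
  set.seed(99)
  n <- 100
  f <- rnorm(n)
  block <- t(sapply(1:10, function(i) sqrt(0.9) * f + sqrt(0.1) * rnorm(n)))
  indep <- matrix(rnorm(10 * n), 10, n)
  m <- rbind(block, indep)
  rownames(m) <- sprintf("G%02d", 1:20)
  colnames(m) <- paste0("s", 1:n)
  block_genes <- sprintf("G%02d", 1:10)
  sig <- gene_signature("blk", up = rownames(m))
  z <- make_z(m)
  net <- build_relevance_network(z, sig, alpha = 1e-6)
  within <- net$edges$gene_i %in% block_genes &
    net$edges$gene_j %in% block_genes
  expect_identical(sum(within), 45L)      # all 10-choose-2 block pairs
  expect_identical(sum(!within), 0L)      # no cross or background edges

  ref <- oracle_network_edges(z, rownames(m), 1e-6)
  got <- net$edges[order(net$edges$gene_i, net$edges$gene_j), ]
  ref <- ref[order(ref$gene_i, ref$gene_j), ]
  expect_equal(got$r, ref$r, tolerance = 1e-12)
  expect_equal(got$p, ref$p, tolerance = 1e-12)
  expect_identical(got$gene_i, ref$gene_i)
  expect_identical(got$gene_j, ref$gene_j)
})

test_that("pruning keeps exactly the prior-consistent edges", {
  sig <- gene_signature("s", up = c("u1", "u2"), down = c("d1", "d2"))
  edges <- data.frame(
    gene_i = c("u1", "u1", "d1"),
    gene_j = c("u2", "d1", "d2"),
    r = c(0.9, 0.9, 0.8),   # u1-d1 positive r is sign-inconsistent
    p = rep(1e-9, 3), consistent = NA)
  net <- structure(list(nodes = c("u1", "u2", "d1", "d2"), edges = edges,
                        n_samples = 50, alpha = 1e-6),
                   class = "relevance_network")
  pruned <- prune_inconsistent_edges(net, sig)
  expect_identical(nrow(pruned$edges), 2L)
  expect_false(any(pruned$edges$gene_i == "u1" &
                     pruned$edges$gene_j == "d1"))
  expect_equal(pruned$consistency_fraction, 2 / 3)
})

test_that("pruning matches a per-edge oracle on random signed networks", {
  set.seed(5)
  for (rep in 1:10) {
    genes <- sprintf("G%02d", 1:8)
    sgn <- setNames(sample(c(1, -1), 8, replace = TRUE), genes)
    sig <- gene_signature("r", up = genes[sgn > 0], down = genes[sgn < 0])
    pairs <- t(combn(genes, 2))
    keep <- sample(nrow(pairs), 12)
    edges <- data.frame(gene_i = pairs[keep, 1], gene_j = pairs[keep, 2],
                        r = runif(12, -1, 1), p = 1e-9, consistent = NA,
                        stringsAsFactors = FALSE)
    net <- structure(list(nodes = genes, edges = edges, n_samples = 50,
                          alpha = 1e-6), class = "relevance_network")
    pruned <- prune_inconsistent_edges(net, sig)
    manual <- edges[sapply(seq_len(nrow(edges)), function(k) {
      sign(edges$r[k]) == sgn[edges$gene_i[k]] * sgn[edges$gene_j[k]]
    }), c("gene_i", "gene_j")]
    expect_equal(pruned$edges[, c("gene_i", "gene_j")], manual,
                 ignore_attr = TRUE)
  }
})

test_that("consistency permutation p-value behaves as defined", {
  # all-same-sign signature: any permutation leaves sign products at +1
  sig_same <- gene_signature("same", up = c("a", "b", "c"))
  edges <- data.frame(gene_i = c("a", "a"), gene_j = c("b", "c"),
                      r = c(0.9, 0.8), p = 1e-9, consistent = NA)
  net <- structure(list(nodes = c("a", "b", "c"), edges = edges,
                        n_samples = 50, alpha = 1e-6),
                   class = "relevance_network")
  res <- consistency_significance(net, sig_same, n_perm = 200, seed = 1)
  expect_equal(res$f_obs, 1)
  expect_equal(res$p_value, 1)

  # 4-node mixed-sign star: exhaustive check over all 4! label permutations
  sig_mix <- gene_signature("mix", up = c("u1", "u2"), down = c("d1", "d2"))
  edges <- data.frame(gene_i = c("u1", "u1", "u1"),
                      gene_j = c("u2", "d1", "d2"),
                      r = c(0.9, -0.9, -0.8), p = 1e-9, consistent = NA)
  net <- structure(list(nodes = c("u1", "u2", "d1", "d2"), edges = edges,
                        n_samples = 50, alpha = 1e-6),
                   class = "relevance_network")
  sgn <- c(u1 = 1, u2 = 1, d1 = -1, d2 = -1)
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  i <- match(edges$gene_i, net$nodes); j <- match(edges$gene_j, net$nodes)
  f_all <- apply(perms, 1, function(p) {
    ps <- sgn[p]
    mean(sign(edges$r) == ps[i] * ps[j])
  })
  exhaustive_p_floor <- mean(f_all >= 1)   # fraction of perms tying f = 1
  res <- consistency_significance(net, sig_mix, n_perm = 1000, seed = 7)
  expect_equal(res$f_obs, 1)
  # sampled p concentrates near the exhaustive tie fraction
  expect_lt(abs(res$p_value - exhaustive_p_floor), 0.05)

  expect_error(consistency_significance(net, sig_mix, n_perm = 0), "n_perm")
  empty <- net; empty$edges <- edges[0, ]
  expect_error(consistency_significance(empty, sig_mix), "no edges")
})

test_that("activity scores follow the degree-weighted closed form", {
  sig <- gene_signature("s", up = c("a", "b"))
  edges <- data.frame(gene_i = "a", gene_j = "b", r = 0.9, p = 1e-9,
                      consistent = TRUE)
  net <- structure(list(nodes = c("a", "b"), edges = edges, n_samples = 50,
                        alpha = 1e-6, n_edges_total = 1,
                        consistency_fraction = 1),
                   class = "relevance_network")
  z <- matrix(c(1, 1, 1, -1), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  a <- dart_activity_scores(z, net, sig)
  expect_equal(a[["s1"]], sqrt(2))   # (1 + 1)/sqrt(2)
  expect_equal(a[["s2"]], 0)         # antisymmetric profile cancels

  empty <- net; empty$edges <- edges[0, ]
  expect_error(dart_activity_scores(z, empty, sig), "threshold")
})

test_that("activity scores equal the term-by-term oracle on random networks", {
  set.seed(21)
  for (rep in 1:10) {
    genes <- sprintf("G%02d", 1:8)
    sgn <- setNames(sample(c(1, -1), 8, replace = TRUE), genes)
    sig <- gene_signature("r", up = genes[sgn > 0], down = genes[sgn < 0])
    # random consistent network: r sign forced to match the prior
    pairs <- t(combn(genes, 2))
    keep <- sample(nrow(pairs), 15)
    r <- runif(15, 0.5, 0.99) * sgn[pairs[keep, 1]] * sgn[pairs[keep, 2]]
    net <- structure(list(
      nodes = genes,
      edges = data.frame(gene_i = pairs[keep, 1], gene_j = pairs[keep, 2],
                         r = r, p = 1e-9, consistent = TRUE,
                         stringsAsFactors = FALSE),
      n_samples = 50, alpha = 1e-6), class = "relevance_network")
    z <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(genes, paste0("s", 1:6)))
    got <- dart_activity_scores(z, net, sig)
    comp <- dartmap:::largest_component(net)
    deg <- dartmap:::dart_degrees(net)[comp]
    ref <- oracle_activity(z, comp, as.list(deg), as.list(sgn[comp]))
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("flipping every signature sign negates every activity score", {
  sig <- toy_signature(4, 4)
  sim <- simulate_instances(simulation_config(sig, n_compounds = 5,
                                              replicates = 1, controls = 2,
                                              n_background_genes = 10,
                                              seed = 3))
  flipped <- gene_signature("flip", up = sig$down, down = sig$up)
  f1 <- dart(sim$expression, sig, n_perm = 0)
  f2 <- dart(sim$expression, flipped, n_perm = 0)
  expect_equal(fitted(f2), -fitted(f1), tolerance = 1e-12)
})

test_that("score weights are invariant to a common degree rescaling", {
  sig <- gene_signature("s", up = c("a", "b", "c"))
  edges <- data.frame(gene_i = c("a", "a", "b"), gene_j = c("b", "c", "c"),
                      r = 0.9, p = 1e-9, consistent = TRUE)
  net <- structure(list(nodes = c("a", "b", "c"), edges = edges,
                        n_samples = 50, alpha = 1e-6),
                   class = "relevance_network")
  z <- matrix(rnorm(9), 3, 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:3)))
  base <- dart_activity_scores(z, net, sig)
  # doubling every edge's multiplicity doubles every degree; the sqrt-sum-
  # of-squares normalizer cancels the common factor
  net2 <- net
  net2$edges <- rbind(edges, edges)
  expect_equal(dart_activity_scores(z, net2, sig), base, tolerance = 1e-12)
})

test_that("dart() recovers planted activity shifts across seeds", {
  sig <- toy_signature(5, 5)
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_cohort(sig, deltas = c(tumour = 1, normal = 0),
                           n_per_group = 40, n_background_genes = 10,
                           seed = s)
    fit <- dart(sim$expression, sig, n_perm = 0)
    sc <- fitted(fit)
    if (mean(sc[sim$groups == "tumour"]) > mean(sc[sim$groups == "normal"])) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("dart object methods are coherent", {
  sig <- toy_signature(4, 4)
  sim <- simulate_cohort(sig, deltas = c(a = 1, b = 0), n_per_group = 25,
                         n_background_genes = 5, seed = 2)
  fit <- dart(sim$expression, sig, n_perm = 100, seed = 1)
  expect_s3_class(fit, "dart")
  expect_named(coef(fit), fit$component)
  expect_equal(length(fitted(fit)), ncol(sim$expression))
  # predicting the training matrix reproduces the fitted scores
  expect_equal(predict(fit, sim$expression), fitted(fit), tolerance = 1e-12)
  expect_output(print(fit), "Relevance-network")
  expect_output(print(summary(fit)), "Activity scores")
  expect_error(predict(fit, sim$expression[1:2, ]), "lacks")
})
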