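make_tom_partition <- function(sim, beta = 12, ...) {
  r <- correlation_matrix(sim$expr)
  tom <- compute_tom(signed_adjacency(r, beta))
  detect_modules(tom_dissimilarity(tom), expr = sim$expr, ...)
}

test_that("planted modules are recovered and background stays grey", {
  cfg <- synthetic_config(c(60L, 50L, 40L), c(0.9, 0.9, 0.9),
                          n_background = 100L, n_samples = 120L, seed = 4)
  sim <- simulate_expression(cfg)
  part <- make_tom_partition(sim)
  expect_length(part$labels, 3L)
  expect_gte(ari(part$assignments, sim$truth$partition$assignments), 0.9)
  bg <- names(which(sim$truth$partition$assignments == "grey"))
  expect_gt(mean(part$assignments[bg] == "grey"), 0.8)
  # size-ordered colour naming
  expect_identical(part$labels[1L], "turquoise")
})

test_that("pure noise yields a predominantly grey partition", {
  cfg <- synthetic_config(c(40L, 40L), c(0, 0), n_background = 120L,
                          n_samples = 100L, loading_jitter = 0, seed = 14)
  sim <- simulate_expression(cfg)
  part <- make_tom_partition(sim)
  expect_gte(mean(part$assignments == "grey"), 0.9)
})

test_that("a single coherent block forms exactly one module", {
  cfg <- synthetic_config(40L, 0.99, n_background = 0L, n_samples = 60L,
                          loading_jitter = 0, seed = 6)
  sim <- simulate_expression(cfg)
  part <- make_tom_partition(sim)
  expect_length(part$labels, 1L)
  expect_true(all(part$assignments == "turquoise"))
})

test_that("the partition is invariant to gene order up to labels", {
  cfg <- synthetic_config(c(40L, 35L), c(0.9, 0.85), n_background = 60L,
                          n_samples = 100L, seed = 9)
  sim <- simulate_expression(cfg)
  r <- correlation_matrix(sim$expr)
  tom <- compute_tom(signed_adjacency(r, 12))
  d <- tom_dissimilarity(tom)
  p1 <- detect_modules(d, expr = sim$expr)
  set.seed(1); perm <- sample(nrow(d))
  p2 <- detect_modules(d[perm, perm], expr = sim$expr[perm, ])
  common <- names(p1$assignments)
  expect_equal(ari(p1$assignments[common], p2$assignments[common]), 1)
})

test_that("partition invariants hold: every gene exactly one label", {
  cfg <- synthetic_config(c(40L, 35L), c(0.9, 0.85), n_background = 50L,
                          n_samples = 80L, seed = 10)
  sim <- simulate_expression(cfg)
  part <- make_tom_partition(sim)
  expect_setequal(names(part$assignments), rownames(sim$expr))
  expect_false(anyNA(part$assignments))
  sz <- module_sizes(part, include_unassigned = FALSE)
  expect_true(all(sz >= 30))
  expect_error(detect_modules(matrix(1, 2, 3)),
               class = "coexmod_asymmetric")
  expect_error(
    detect_modules(matrix(0, 3, 3), min_module_size = 10),
    class = "coexmod_bad_config")
})

test_that("module eigengene handles degenerate and planted cases", {
  # identical rows: eigengene is the z-scored common profile
  prof <- c(3, 1, 4, 1, 5, 9, 2, 6)
  x <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(x) <- paste0("s", 1:8)
  eg <- module_eigengene(x, rownames(x))
  expect_equal(unname(eg$eigengene),
               unname((prof - mean(prof)) / sd(prof)), tolerance = 1e-8)
  expect_equal(eg$var_explained, 1)

  # exact negatives: variance explained 1, first gene oriented positive
  y <- rbind(g1 = prof, g2 = -prof)
  colnames(y) <- paste0("s", 1:8)
  ey <- module_eigengene(y, rownames(y))
  expect_equal(ey$var_explained, 1)
  expect_gt(cor(y["g1", ], ey$eigengene), 0.999)

  # constant rows rejected
  z <- rbind(g1 = prof, g2 = rep(2, 8))
  expect_error(module_eigengene(z, rownames(z)),
               class = "coexmod_constant_gene")
})

test_that("the eigengene recovers the planted latent factor", {
  cfg <- synthetic_config(50L, 0.8, n_samples = 200L, seed = 12)
  sim <- simulate_expression(cfg)
  genes <- names(which(sim$truth$partition$assignments == "M1"))
  eg <- module_eigengene(sim$expr, genes)
  expect_gte(abs(cor(eg$eigengene, sim$truth$latent_factors["M1", ])),
             0.95)
  expect_equal(sd(eg$eigengene), 1)
})

test_that("module membership gives kME and rank quantiles", {
  set.seed(20)
  s <- 50
  e <- rnorm(s)
  # five genes with decreasing alignment to the eigengene driver
  x <- t(sapply(c(0.95, 0.8, 0.6, 0.4, 0.2),
                function(a) a * e + sqrt(1 - a^2) * rnorm(s)))
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:s)
  part <- module_partition(setNames(rep("blue", 5), rownames(x)))
  me <- module_eigengenes(x, part)
  mm <- module_membership(x, me, part)
  expect_identical(sort(mm$table$quantile), c(0L, 25L, 50L, 75L, 100L))
  # quantile is monotone in kME
  o <- order(mm$table$kme)
  expect_identical(mm$table$quantile[o], sort(mm$table$quantile))

  # a gene identical to the eigengene scores kME 1
  x2 <- rbind(x, ge = me$eigengenes[, "blue"])
  part2 <- module_partition(setNames(rep("blue", 6), rownames(x2)))
  mm2 <- module_membership(x2, me, part2)
  expect_equal(mm2$kme["ge", "blue"], 1, tolerance = 1e-10)
  expect_identical(
    mm2$table$quantile[mm2$table$gene == "ge"], 100L)

  # sample mismatch is rejected
  expect_error(module_membership(x[, 1:10], me, part),
               class = "coexmod_sample_mismatch")
})

test_that("assignment by highest membership is deterministic", {
  expect_identical(assign_by_membership(c(blue = 0.9, brown = 0.2)),
                   "blue")
  expect_identical(assign_by_membership(c(blue = 0.5, brown = 0.5)),
                   "blue")
  expect_identical(
    assign_by_membership(c(blue = 0.1, brown = 0.2), min_kme = 0.5),
    "grey")
  expect_error(assign_by_membership(numeric(0)),
               class = "coexmod_bad_input")
})

test_that("held-out module genes return to their module by kME", {
  cfg <- synthetic_config(c(60L, 50L), c(0.85, 0.85), n_background = 80L,
                          n_samples = 150L, seed = 15)
  sim <- simulate_expression(cfg)
  truth_av <- sim$truth$partition$assignments
  # hold out 10 genes per module, detect on the rest
  set.seed(30)
  held <- c(sample(names(which(truth_av == "M1")), 10),
            sample(names(which(truth_av == "M2")), 10))
  rest <- setdiff(rownames(sim$expr), held)
  expr_rest <- sim$expr[rest, ]
  part <- make_tom_partition(list(expr = expr_rest))
  me <- module_eigengenes(sim$expr[rest, ], part)
  kme_held <- cor(t(sim$expr[held, ]), me$eigengenes)
  back <- apply(kme_held, 1L, assign_by_membership)
  # map detected labels to truth labels via majority vote
  label_map <- vapply(part$labels, function(l) {
    names(which.max(table(truth_av[names(which(part$assignments == l))])))
  }, character(1))
  expect_gte(mean(label_map[back] == truth_av[held]), 0.95)
})

test_that("eigengene-similar modules merge below the merge height", {
  # two planted modules driven by nearly identical factors
  set.seed(44)
  s <- 120
  f <- rnorm(s)
  f2 <- 0.98 * f + sqrt(1 - 0.98^2) * rnorm(s)
  mk <- function(f, n, a) {
    t(sapply(seq_len(n), function(i) a * f + sqrt(1 - a^2) * rnorm(s)))
  }
  x <- rbind(mk(f, 40, 0.9), mk(f2, 35, 0.9), matrix(rnorm(40 * s), 40))
  rownames(x) <- sprintf("G%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("S%03d", seq_len(s))
  tom <- compute_tom(signed_adjacency(correlation_matrix(x), 12))
  p_plain <- detect_modules(tom_dissimilarity(tom), expr = x)
  p_merged <- detect_modules(tom_dissimilarity(tom), expr = x,
                             merge_height = 0.2)
  expect_lte(length(p_merged$labels), length(p_plain$labels))
  expect_length(p_merged$labels, 1L)
  expect_gte(sum(p_merged$assignments == "turquoise"), 70)
})
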