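test_that("hypergeometric enrichment matches the combinatorial oracle", {
  # N=10, K=4, n=3, observed 2 -> 40/120
  mod <- paste0("g", 1:4)
  qry <- c("g1", "g2", "x1")
  res <- hypergeom_enrich(mod, qry, 10)
  expect_identical(res$observed, 2L)
  expect_equal(res$p_value, 40 / 120, tolerance = 1e-12)
  expect_equal(res$p_value, hyper_tail_oracle(2, 10, 4, 3),
               tolerance = 1e-12)

  # no overlap -> p = 1; module covers the background -> p = 1
  expect_equal(hypergeom_enrich(paste0("g", 1:4),
                                paste0("y", 1:3), 10)$p_value, 1)
  full <- hypergeom_enrich(paste0("g", 1:10), paste0("g", 1:3), 10)
  expect_identical(full$observed, 3L)
  expect_equal(full$p_value, 1)

  expect_error(hypergeom_enrich(paste0("g", 1:11), "g1", 10),
               class = "coexmod_bad_background")
})

test_that("hypergeometric upper tail matches enumeration across configurations", {
  for (N in c(7L, 19L, 38L, 60L)) {
    set.seed(N)
    for (rep in 1:40) {
      K <- sample(N, 1); n <- sample(N, 1)
      obs <- sample(0:min(K, n), 1)
      p <- stats::phyper(obs - 1, K, N - K, n, lower.tail = FALSE)
      expect_equal(p, hyper_tail_oracle(obs, N, K, n), tolerance = 1e-12)
    }
  }
})

test_that("exact clustering probability matches full enumeration", {
  av <- setNames(c(rep("A", 4), rep("B", 6)), paste0("g", 1:10))
  part <- module_partition(av)
  expect_equal(exact_cluster_prob(part, 2, 10), 21 / 45,
               tolerance = 1e-12)
  expect_equal(exact_cluster_prob(part, 2, 10),
               cluster_prob_enum(av, 2, 10), tolerance = 1e-12)
  expect_equal(exact_cluster_prob(part, 2, 5), choose(4, 2) / 45,
               tolerance = 1e-12)

  # single module of size n with m >= n -> certainty
  one <- module_partition(setNames(rep("A", 6), paste0("g", 1:6)))
  expect_equal(exact_cluster_prob(one, 3, 6), 1, tolerance = 1e-12)
  expect_equal(exact_cluster_prob(one, 1, 6), 1, tolerance = 1e-12)

  # grey genes dilute the pool but never count as a success module
  grey <- module_partition(setNames(c(rep("A", 4), rep("grey", 6)),
                                    paste0("g", 1:10)))
  expect_equal(exact_cluster_prob(grey, 2, 10), choose(4, 2) / 45,
               tolerance = 1e-12)
  expect_equal(exact_cluster_prob(grey, 2, 10),
               cluster_prob_enum(setNames(c(rep("A", 4), rep("grey", 6)),
                                          paste0("g", 1:10)), 2, 10),
               tolerance = 1e-12)

  expect_error(exact_cluster_prob(part, 0, 5),
               class = "coexmod_bad_input")
  expect_error(exact_cluster_prob(part, 11, 5),
               class = "coexmod_bad_input")
})

test_that("the Monte-Carlo clustering test converges to the exact probability", {
  av <- setNames(c(rep("A", 4), rep("B", 6)), paste0("g", 1:10))
  part <- module_partition(av)
  spec <- cluster_test_spec(2, 10, n_perm = 1e5, seed = 17)
  res <- permutation_cluster_test(part, spec)
  p_exact <- exact_cluster_prob(part, 2, 10)
  expect_lt(abs(res$p_value - p_exact), 3 * res$mc_se + 1e-12)
  expect_equal(res$mc_se,
               sqrt(res$p_value * (1 - res$p_value) / 1e5),
               tolerance = 1e-12)

  # deterministic given the seed
  res2 <- permutation_cluster_test(part, spec)
  expect_identical(res$p_value, res2$p_value)

  # single module with m at least its size: success is certain
  one <- module_partition(setNames(rep("A", 8), paste0("g", 1:8)))
  expect_equal(
    permutation_cluster_test(one,
                             cluster_test_spec(3, 8, 2000, 5))$p_value, 1)

  expect_error(cluster_test_spec(0, 5), class = "coexmod_bad_input")
  expect_error(cluster_test_spec(2, 5, n_perm = 0),
               class = "coexmod_bad_input")
})

test_that("an impossible clustering reports p-hat 0 printed as a bound", {
  av <- setNames(c(rep("A", 5), rep("B", 5)), paste0("g", 1:10))
  part <- module_partition(av)
  res <- permutation_cluster_test(part, cluster_test_spec(2, 1, 500, 3))
  expect_identical(res$p_value, 0)
  expect_match(paste(capture.output(print(res)), collapse = " "),
               "< 0.002")
})

test_that("Fisher overlap equals the hypergeometric tail", {
  # N=10, |A|=3, |B|=3, overlap 3 -> 1/120
  res <- fisher_overlap(paste0("g", 1:3), paste0("g", 1:3), 10)
  expect_equal(res$p_value, 1 / 120, tolerance = 1e-12)

  # disjoint sets covering the background: no enrichment signal
  res2 <- fisher_overlap(paste0("g", 1:4), paste0("h", 1:6), 10)
  expect_equal(res2$p_value, 1)

  set.seed(60)
  for (rep in 1:20) {
    N <- sample(20:60, 1)
    A <- sample(N, sample(3:10, 1)); B <- sample(N, sample(3:10, 1))
    ga <- paste0("g", A); gb <- paste0("g", B)
    pf <- fisher_overlap(ga, gb, N)$p_value
    ph <- hypergeom_enrich(ga, gb, N)$p_value
    expect_equal(pf, ph, tolerance = 1e-12)
  }

  expect_error(fisher_overlap(paste0("g", 1:5), paste0("h", 1:6), 10),
               class = "coexmod_bad_background")
})

test_that("chi-square overlap matches the direct formula", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  res <- chisq_overlap(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  prop <- matrix(c(20, 10, 40, 20), 2)  # identical row proportions
  expect_equal(chisq_overlap(prop)$statistic, 0, tolerance = 1e-12)

  tab <- matrix(c(30, 10, 10, 30), 2)
  res2 <- chisq_overlap(tab)
  expect_equal(res2$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(res2$statistic, 20, tolerance = 1e-12)
  expect_equal(res2$p_value, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(chisq_overlap(matrix(c(0, 0, 5, 5), 2)),
               class = "coexmod_bad_input")
  expect_error(chisq_overlap(matrix(1:6, 2)), class = "coexmod_bad_input")
})

test_that("the DE filter applies an inclusive threshold and flips under swap", {
  genes <- paste0("g", 1:4)
  case <- matrix(rep(c(150, 149, 50, 100), 3), ncol = 3,
                 dimnames = list(genes, paste0("c", 1:3)))
  ctrl <- matrix(rep(c(100, 100, 100, 100), 3), ncol = 3,
                 dimnames = list(genes, paste0("k", 1:3)))
  de <- de_fold_change_filter(case, ctrl, 1.5)
  expect_identical(de$passes, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(de$direction, c("up", "up", "down", "up"))
  expect_true(all(de$fold_change >= 1))

  # swapping case and control keeps fold changes, flips directions
  sw <- de_fold_change_filter(ctrl, case, 1.5)
  expect_equal(sw$fold_change, de$fold_change, tolerance = 1e-12)
  expect_identical(sw$passes, de$passes)
  expect_identical(sw$direction[1L], "down")
  expect_identical(sw$direction[3L], "up")

  neg <- case; neg[1, ] <- -1
  expect_error(de_fold_change_filter(neg, ctrl),
               class = "coexmod_bad_input")
  expect_error(de_fold_change_filter(case[1:3, ], ctrl),
               class = "coexmod_bad_input")
})

test_that("DE list combination follows set algebra, order-stable", {
  l <- list(c("A", "B", "C"), c("B", "C", "D"), "C", c("C", "E"))
  expect_identical(combine_de_lists(l, "union"),
                   c("A", "B", "C", "D", "E"))
  expect_identical(combine_de_lists(l, "intersection"), "C")

  same <- list(c("X", "Y"), c("X", "Y"))
  expect_identical(combine_de_lists(same, "union"), c("X", "Y"))
  expect_identical(combine_de_lists(same, "intersection"), c("X", "Y"))
  expect_identical(
    combine_de_lists(list(c("A", "B"), c("C", "D")), "intersection"),
    character(0))
  expect_error(combine_de_lists(list("A"), "union"),
               class = "coexmod_bad_input")
  expect_error(combine_de_lists(l, "both"))
})

test_that("gene sets deduplicate with a warning", {
  expect_warning(s <- gene_set("S", c("a", "b", "a")), "duplicate")
  expect_identical(s$genes, c("a", "b"))
})
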