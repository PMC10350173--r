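test_that("a module tested against its own network is perfectly preserved", {
  pair <- preservation_pair(101)
  net <- build_coactivation_network(pair$ref)
  pm <- attr(pair$ref, "planted_modules")
  members <- names(pm)[pm == "pink"]
  obs <- preservation_base_statistics(net, pair$ref, net, pair$ref, members)
  expect_equal(unname(obs[c("cor.kIM", "cor.kME", "cor.kMEall",
                            "cor.cor", "cor.MAR")]),
               rep(1, 5), tolerance = 1e-10)
  expect_equal(unname(obs["meanAdj"]),
               mean(net$A[members, members][upper.tri(diag(15))]))
  expect_error(preservation_base_statistics(net, pair$ref, net, pair$ref,
                                            members[1:2]), "at least 3")
})

test_that("permutation Z values are seed-deterministic and well-formed", {
  pair <- preservation_pair(103, n_regions = 30)
  nr <- build_coactivation_network(pair$ref)
  nt <- build_coactivation_network(pair$test, modules = nr$modules)
  pm <- attr(pair$ref, "planted_modules")
  mods <- pm[pm == "pink"]
  r1 <- module_preservation(nr, pair$ref, nt, pair$test, modules = mods,
                            n_permutations = 60, seed = 5)
  r2 <- module_preservation(nr, pair$ref, nt, pair$test, modules = mods,
                            n_permutations = 60, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_equal(r1$table$Z,
               (r1$table$observed - r1$table$perm_mean) / r1$table$perm_sd)
  expect_error(module_preservation(nr, pair$ref, nt, pair$test,
                                   modules = mods, n_permutations = 1),
               "at least 2")
})

test_that("degenerate permutation distributions are flagged, not silent", {
  # universe equal to the module: every permutation draws the same set
  x <- simulate_counts(count_sim_config(4, 20, "G",
    module_spec = list(list(label = "a", size = 4, rho = 0.5)), seed = 3))
  net <- build_coactivation_network(x)
  mods <- stats::setNames(rep("a", 4), x$region_ids)
  res <- module_preservation(net, x, net, x, modules = mods,
                             n_permutations = 10, seed = 1)
  expect_true(all(res$table$degenerate | is.na(res$table$perm_sd) |
                    res$table$perm_sd > 0))
  expect_true(any(res$table$degenerate))
  expect_false(any(is.finite(res$table$Z[res$table$degenerate])))
})

test_that("random test-network modules give calibrated null Z values", {
  # one network pair; many random 'modules' are their own permutation null
  x1 <- simulate_counts(count_sim_config(30, 25, "A", seed = 11))
  x2 <- simulate_counts(count_sim_config(30, 25, "B", seed = 12))
  n1 <- build_coactivation_network(x1)
  n2 <- build_coactivation_network(x2, modules = n1$modules)
  zs <- sapply(1:40, function(i) {
    set.seed(900 + i)
    mods <- stats::setNames(rep("m", 6), sample(x1$region_ids, 6))
    res <- module_preservation(n1, x1, n2, x2, modules = mods,
                               n_permutations = 80, seed = 900 + i)
    res$table$Z[res$table$statistic == "meanAdj"]
  })
  expect_lt(abs(mean(zs)), 0.35)
  expect_gt(stats::sd(zs), 0.6)
  expect_lt(stats::sd(zs), 1.4)
})

test_that("preservation Z rises with planted test-group correlation", {
  med_z <- sapply(c(0, 0.35, 0.7), function(rho) {
    ms <- list(list(label = "pink", size = 10, rho = rho))
    ref <- simulate_counts(count_sim_config(40, 25, "R",
      module_spec = list(list(label = "pink", size = 10, rho = 0.7)),
      seed = 41))
    test <- simulate_counts(count_sim_config(40, 25, "T",
      module_spec = ms, seed = 42))
    nr <- build_coactivation_network(ref)
    nt <- build_coactivation_network(test, modules = nr$modules)
    pm <- attr(ref, "planted_modules")
    res <- module_preservation(nr, ref, nt, test,
                               modules = pm[pm == "pink"],
                               n_permutations = 80, seed = 7)
    stats::median(res$table$Z[res$table$type == "density"])
  })
  expect_true(all(diff(med_z) > 0))
})

test_that("preservation runs pair up metric by metric", {
  pair <- preservation_pair(105, n_regions = 30)
  nr <- build_coactivation_network(pair$ref)
  nt <- build_coactivation_network(pair$test, modules = nr$modules)
  pm <- attr(pair$ref, "planted_modules")
  mods <- pm[pm == "pink"]
  a <- module_preservation(nr, pair$ref, nt, pair$test, modules = mods,
                           n_permutations = 40, seed = 1)
  cmp <- compare_preservation(a, a)
  expect_true(all(cmp$diff[is.finite(cmp$diff)] == 0))
  b <- a
  b$table <- b$table[b$table$statistic != "cor.MAR", ]
  expect_error(compare_preservation(a, b), "mismatched")
  c1 <- a; c1$table <- c1$table[1, , drop = FALSE]
  expect_equal(nrow(compare_preservation(c1, c1)), 1)
  # long-format export carries permutation metadata
  f <- withr::local_tempfile(fileext = ".tsv")
  write_preservation(a, f)
  tab <- utils::read.delim(f)
  expect_equal(unique(tab$n_perm), 40)
  expect_equal(nrow(tab), 9)
})
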