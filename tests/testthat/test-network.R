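test_that("correlation matrix matches the pairwise formula", {
  counts <- matrix(c(5, 9, 14, 20,
                     5, 9, 14, 20,
                     19, 15, 10, 4,
                     7, 3, 11, 2,
                     1, 8, 2, 12), 5, 4, byrow = TRUE,
                   dimnames = list(paste0("r", 1:5), paste0("s", 1:4)))
  x <- count_matrix(counts, data.frame(id = paste0("s", 1:4)))
  S <- correlation_matrix(x)
  expect_equal(unname(S["r1", "r2"]), 1)
  expect_equal(unname(S["r1", "r3"]), -1)
  expect_equal(unname(diag(S)), rep(1, 5))
  brute <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(unname(S[i, j]), brute(counts[i, ], counts[j, ]),
                 tolerance = 1e-12)
})

test_that("zero-variance regions are dropped or zeroed as configured", {
  counts <- rbind(r1 = c(3, 3, 3, 3), r2 = c(1, 5, 2, 9), r3 = c(4, 1, 7, 2))
  colnames(counts) <- paste0("s", 1:4)
  x <- count_matrix(counts, data.frame(id = paste0("s", 1:4)))
  expect_warning(S <- correlation_matrix(x), "zero-variance")
  expect_equal(rownames(S), c("r2", "r3"))
  S0 <- correlation_matrix(x, zero_variance = "zero")
  expect_equal(nrow(S0), 3)
  expect_equal(unname(S0["r1", "r2"]), 0)
})

test_that("soft power selection honours its contract", {
  expect_error(pick_soft_power(diag(3), numeric(0)), "non-empty")
  # independent noise: no scale-free structure, fall back with warning
  set.seed(7)
  m <- matrix(rpois(15 * 60, 50), 15)
  rownames(m) <- sprintf("R%03d", 1:15); colnames(m) <- paste0("s", 1:60)
  x <- count_matrix(m, data.frame(id = colnames(m)))
  S <- correlation_matrix(x)
  expect_warning(p <- pick_soft_power(S, default_power = 6),
                 "falling back")
  expect_equal(as.numeric(p), 6)
  # single candidate equal to the fallback is returned unconditionally
  expect_equal(as.numeric(suppressWarnings(
    pick_soft_power(S, candidates = 4, default_power = 4))), 4)
  # strongly modular network: a qualifying power exists and is small
  xm <- simulate_counts(four_module_config(31))
  Sm <- correlation_matrix(xm)
  pm <- pick_soft_power(Sm)
  expect_lte(as.numeric(pm), 12)
  tab <- attr(pm, "fit_table")
  expect_gt(tab$r2[tab$power == as.numeric(pm)], 0.8)
})

test_that("power adjacency implements both sign modes", {
  S <- matrix(c(1, 0.5, -0.5, 0.5, 1, 1, -0.5, 1, 1), 3, 3)
  A <- adjacency_power(S, 2)
  expect_equal(A[1, 2], 0.25)
  expect_equal(A[1, 3], 0.25)  # unsigned: |-0.5|^2
  expect_equal(A[2, 3], 1)
  expect_equal(diag(A), rep(0, 3))
  Ah <- adjacency_power(S, 2, mode = "signed-hybrid")
  expect_equal(Ah[1, 3], 0)   # negative correlations drop to zero
  # raising the power weakly decreases every off-diagonal entry
  A6 <- adjacency_power(S, 6)
  expect_true(all(A6[upper.tri(A6)] <= A[upper.tri(A)] + 1e-12))
})

test_that("topological overlap matches hand and brute-force computation", {
  z <- matrix(0, 4, 4)
  expect_equal(topological_overlap(z), diag(4))
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  # complete graph: l = 2, k = 3 -> (2 + 1) / (3 + 1 - 1) = 1
  expect_equal(topological_overlap(ones), matrix(1, 4, 4))
  set.seed(4)
  A <- random_adjacency(10)
  expect_equal(topological_overlap(A), tom_brute(A), tolerance = 1e-10)
  expect_error(topological_overlap(A * 2), "\\[0, 1\\]")
})

test_that("TOM entries always lie in [0, 1]", {
  set.seed(8)
  for (i in 1:20) {
    A <- random_adjacency(sample(3:15, 1))
    TOM <- topological_overlap(A)
    expect_true(all(TOM >= -1e-12 & TOM <= 1 + 1e-12))
    expect_equal(TOM, t(TOM), tolerance = 1e-12)
  }
})

test_that("network construction is equivariant to region permutation", {
  x <- simulate_counts(count_sim_config(12, 20, "G",
    module_spec = list(list(label = "a", size = 6, rho = 0.7)), seed = 6))
  net <- build_coactivation_network(x, beta_power = 6)
  perm <- sample(x$region_ids)
  xp <- subset_counts(x, regions = perm)
  netp <- build_coactivation_network(xp, beta_power = 6)
  expect_equal(netp$S[x$region_ids, x$region_ids], net$S)
  expect_equal(netp$TOM[x$region_ids, x$region_ids], net$TOM)
  expect_equal(netp$modules[x$region_ids], net$modules)
})

test_that("module detection separates perfect blocks and honours min size", {
  b <- matrix(0, 6, 6)
  b[1:3, 1:3] <- 1; b[4:6, 4:6] <- 1; diag(b) <- 1
  lab <- detect_modules(b, min_module_size = 3)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_false(unassigned_label() %in% lab)
  # min size above every block: everything unassigned
  lab2 <- detect_modules(b, min_module_size = 4)
  expect_true(all(lab2 == unassigned_label()))
  # identical rows collapse into a single module
  u <- matrix(0.5, 4, 4); diag(u) <- 1
  expect_message(lab3 <- detect_modules(u), "single module")
  expect_equal(length(unique(lab3)), 1)
  expect_false(unassigned_label() %in% lab3)
})

test_that("planted modules are recovered from simulated counts", {
  x <- simulate_counts(four_module_config(9001))
  net <- build_coactivation_network(x)
  expect_gte(ari(attr(x, "planted_modules"), net$modules), 0.9)
  # detection runs entirely on the TOM, reproducibly
  lab1 <- detect_modules(net$TOM)
  lab2 <- detect_modules(net$TOM)
  expect_identical(lab1, lab2)
})

test_that("networks serialise to delimited text", {
  x <- simulate_counts(count_sim_config(10, 10, "G",
    module_spec = list(list(label = "a", size = 5, rho = 0.7)), seed = 2))
  net <- build_coactivation_network(x)
  dir <- withr::local_tempdir()
  files <- write_network(net, file.path(dir, "net"))
  expect_true(all(file.exists(file.path(dir, paste0("net", c(
    "_correlation.tsv", "_adjacency.tsv", "_tom.tsv", "_modules.tsv",
    "_edges.tsv"))))))
  tom <- utils::read.delim(file.path(dir, "net_tom.tsv"),
                           check.names = FALSE)
  expect_equal(as.matrix(tom[, -1]), net$TOM, tolerance = 1e-6,
               ignore_attr = TRUE)
})
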