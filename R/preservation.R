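connectivity_stat_names <- function()
  c("cor.kIM", "cor.kME", "cor.kMEall", "cor.cor", "cor.MAR")

density_stat_names <- function()
  c("propVarExplained", "meanSignAwareCorDat", "meanAdj", "meanMAR")

safe_cor <- function(a, b) {
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Base module preservation statistics
#'
#' Computes, for one module (a region set defined in the reference network),
#' the unpermuted connectivity and density statistics compared between a
#' reference and a test network built on the same region universe:
#'
#' * `cor.kIM`: correlation over module regions of intramodular connectivity
#'   in reference vs test.
#' * `cor.kME`: the same for module membership (kME).
#' * `cor.kMEall`: correlation over ALL regions of kME against this module.
#' * `cor.cor`: correlation of the vectorized off-diagonal within-module
#'   correlation submatrices.
#' * `cor.MAR`: correlation of maximum adjacency ratios.
#' * `propVarExplained`: variance share of the module's leading singular
#'   pair computed in the TEST data with reference membership.
#' * `meanSignAwareCorDat`: mean over module pairs of sign(s_ref) * s_test.
#' * `meanAdj`: mean off-diagonal test adjacency within the module.
#' * `meanMAR`: mean test MAR over module regions.
#'
#' @param ref_network,test_network `coactivation_network` objects sharing
#'   region identifiers.
#' @param ref_x,test_x the corresponding [count_matrix()] objects.
#' @param module_regions member region ids (>= 3) present in both networks.
#' @return Named numeric vector of the nine base statistics.
#' @export
preservation_base_statistics <- function(ref_network, ref_x,
                                         test_network, test_x,
                                         module_regions) {
  if (length(module_regions) < 3)
    stop("module must have at least 3 regions")
  for (nw in list(ref_network, test_network))
    if (!all(module_regions %in% nw$region_ids))
      stop("module regions must be present in both networks")
  pr_ref <- connectivity_profile(ref_network, ref_x,
                                 module_regions = module_regions)
  pr_test <- connectivity_profile(test_network, test_x,
                                  module_regions = module_regions)
  common <- intersect(ref_network$region_ids, test_network$region_ids)
  kmeall_ref <- attr(pr_ref, "kMEall")[common]
  kmeall_test <- attr(pr_test, "kMEall")[common]
  s_ref <- ref_network$S[module_regions, module_regions]
  s_test <- test_network$S[module_regions, module_regions]
  ut <- upper.tri(s_ref)
  a_test <- test_network$A[module_regions, module_regions]
  c(cor.kIM = safe_cor(pr_ref$kIM, pr_test$kIM),
    cor.kME = safe_cor(pr_ref$kME, pr_test$kME),
    cor.kMEall = safe_cor(kmeall_ref, kmeall_test),
    cor.cor = safe_cor(s_ref[ut], s_test[ut]),
    cor.MAR = safe_cor(pr_ref$MAR, pr_test$MAR),
    propVarExplained = attr(pr_test, "scores")$prop_var_explained,
    meanSignAwareCorDat = mean(sign(s_ref[ut]) * s_test[ut]),
    meanAdj = mean(a_test[ut]),
    meanMAR = mean(pr_test$MAR))
}

#' Permutation Z statistics for module preservation
#'
#' For every module defined in the reference network, the observed base
#' statistics are compared against a permutation null obtained by redrawing
#' the module's label set uniformly at random over all test-network regions
#' (module size preserved) and recomputing ALL base statistics jointly per
#' draw. Each Z is (observed - permutation mean) / permutation SD. A
#' degenerate permutation distribution (SD = 0) yields a flagged +/-Inf
#' rather than a silent number.
#'
#' @param ref_network,ref_x,test_network,test_x as in
#'   [preservation_base_statistics()].
#' @param modules named character vector region -> label (default: the
#'   reference network's modules, excluding the unassigned label).
#' @param n_permutations number of label permutations (>= 2; >= 50 for
#'   stable Z estimates).
#' @param seed integer seed making the permutation draws reproducible.
#' @return Object of class `preservation_result`: list with `table` (long
#'   data.frame: module, statistic, type, observed, perm_mean, perm_sd, Z,
#'   degenerate), `n_permutations`, `seed`, `module_sizes`.
#' @export
module_preservation <- function(ref_network, ref_x, test_network, test_x,
                                modules = NULL, n_permutations = 200L,
                                seed = 1L) {
  if (n_permutations < 2) stop("need at least 2 permutations")
  modules <- modules %||% ref_network$modules
  modules <- modules[modules != unassigned_label()]
  labels <- unique(modules)
  if (!length(labels)) stop("no modules to test")
  universe <- test_network$region_ids
  all_stats <- c(connectivity_stat_names(), density_stat_names())

  rows <- list()
  sizes <- integer(0)
  for (lab in labels) {
    members <- names(modules)[modules == lab]
    obs <- preservation_base_statistics(ref_network, ref_x,
                                        test_network, test_x, members)
    perm <- with_seed(seed + match(lab, labels) - 1L, {
      vapply(seq_len(n_permutations), function(i) {
        perm_members <- sample(universe, length(members))
        preservation_base_statistics(ref_network, ref_x,
                                     test_network, test_x, perm_members)
      }, obs)
    })
    pm <- apply(perm, 1, mean, na.rm = TRUE)
    psd <- apply(perm, 1, stats::sd, na.rm = TRUE)
    degenerate <- !is.na(psd) & psd == 0
    Z <- ifelse(degenerate, sign(obs - pm) * Inf, (obs - pm) / psd)
    rows[[lab]] <- data.frame(
      module = lab, statistic = all_stats,
      type = rep(c("connectivity", "density"),
                 c(length(connectivity_stat_names()),
                   length(density_stat_names()))),
      observed = unname(obs), perm_mean = unname(pm),
      perm_sd = unname(psd), Z = unname(Z),
      degenerate = unname(degenerate),
      stringsAsFactors = FALSE)
    sizes[lab] <- length(members)
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed),
         module_sizes = sizes),
    class = "preservation_result")
}

#' @export
print.preservation_result <- function(x, ...) {
  cat(sprintf("preservation_result: %d module(s), %d permutations, seed %d\n",
              length(x$module_sizes), x$n_permutations, x$seed))
  wide <- stats::reshape(x$table[, c("module", "statistic", "Z")],
                         idvar = "module", timevar = "statistic",
                         direction = "wide")
  names(wide) <- sub("^Z\\.", "Z.", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Median-of-Z preservation summary
#'
#' A convenience aggregate (median of the connectivity Z statistics, and of
#' the density Z statistics, per module). This is a summary convention of
#' this package, not a defined composite statistic.
#'
#' @param result a `preservation_result`.
#' @return data.frame (`module`, `median_Z_connectivity`, `median_Z_density`).
#' @export
preservation_summary <- function(result) {
  stopifnot(inherits(result, "preservation_result"))
  tab <- result$table
  agg <- function(type) {
    sub <- tab[tab$type == type & is.finite(tab$Z), ]
    stats::aggregate(Z ~ module, sub, stats::median)
  }
  conn <- agg("connectivity"); dens <- agg("density")
  out <- merge(conn, dens, by = "module", suffixes = c("", ".d"),
               all = TRUE)
  names(out) <- c("module", "median_Z_connectivity", "median_Z_density")
  out[order(out$module), ]
}

#' Pair preservation metrics across two runs
#'
#' Matches each (module, statistic) pair across two preservation results —
#' e.g. the same reference module tested against two different test networks
#' — and reports per-metric differences plus a paired rank test over the Z
#' values. No claim is made beyond the metric pairing.
#'
#' @param result_a,result_b `preservation_result` objects over the same
#'   modules and statistics.
#' @return data.frame (`module`, `statistic`, `type`, `Z_a`, `Z_b`, `diff`)
#'   with attribute `wilcoxon` (paired test over finite Z pairs; NULL when
#'   fewer than 2 pairs).
#' @export
compare_preservation <- function(result_a, result_b) {
  ta <- result_a$table; tb <- result_b$table
  key <- function(t) paste(t$module, t$statistic)
  if (!setequal(key(ta), key(tb)))
    stop("preservation results have mismatched module/statistic sets")
  tb <- tb[match(key(ta), key(tb)), ]
  out <- data.frame(module = ta$module, statistic = ta$statistic,
                    type = ta$type, Z_a = ta$Z, Z_b = tb$Z,
                    diff = ta$Z - tb$Z, stringsAsFactors = FALSE)
  ok <- is.finite(out$Z_a) & is.finite(out$Z_b)
  test <- NULL
  if (sum(ok) >= 2 && any(out$diff[ok] != 0))
    test <- stats::wilcox.test(out$Z_a[ok], out$Z_b[ok], paired = TRUE,
                               exact = FALSE)
  attr(out, "wilcoxon") <- test
  out
}

#' Write preservation results as a long-format table
#'
#' @param result a `preservation_result`.
#' @param file output path (tab-separated).
#' @return Invisibly, `result`.
#' @export
write_preservation <- function(result, file) {
  tab <- result$table
  tab$n_perm <- result$n_permutations
  tab$seed <- result$seed
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}
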