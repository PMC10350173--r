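#' Per-subject module expression by singular value decomposition
#'
#' The module's count submatrix is standardized per region (zero mean, unit
#' variance across subjects) and decomposed as X = U D V'; the leading left
#' singular vector gives one score per subject (the module eigengene), and
#' sigma_1^2 / sum(sigma_k^2) is the proportion of variance it explains.
#' Scores are oriented so that they correlate positively with the mean
#' standardized count profile, making the result invariant to the sign
#' indeterminacy of the SVD.
#'
#' With `input = "tom"` the decomposition is instead applied to the module's
#' topological overlap submatrix (a region x region variant retained for
#' fidelity audits); it yields a variance share but no per-subject scores.
#'
#' @param x a [count_matrix()].
#' @param module_regions character vector of member region ids (>= 2).
#' @param input `"counts"` (default, eigengene construction) or `"tom"`.
#' @param network required when `input = "tom"`: a `coactivation_network`.
#' @return Object of class `module_expression`: list with `module_regions`,
#'   `subject_scores` (named, unit norm; NULL for `"tom"`),
#'   `prop_var_explained`, `singular_values`, `sign_flipped`.
#' @export
module_expression <- function(x, module_regions,
                              input = c("counts", "tom"), network = NULL) {
  input <- match.arg(input)
  if (input == "tom") {
    stopifnot(inherits(network, "coactivation_network"))
    sub <- network$TOM[module_regions, module_regions, drop = FALSE]
    d <- svd(sub)$d
    return(structure(list(module_regions = module_regions,
                          subject_scores = NULL,
                          prop_var_explained = d[1]^2 / sum(d^2),
                          singular_values = d, sign_flipped = FALSE),
                     class = "module_expression"))
  }
  stopifnot(inherits(x, "count_matrix"))
  if (length(module_regions) < 2) stop("module must have >= 2 regions")
  if (!all(module_regions %in% x$region_ids)) stop("unknown module regions")
  m <- t(x$counts[module_regions, , drop = FALSE])  # subjects x regions
  if (nrow(m) < 3) stop("need at least 3 subjects")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance region(s) from module before SVD",
                    sum(sds == 0)))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2) stop("fewer than 2 regions with variance in module")
  }
  Z <- scale(m)
  sv <- svd(Z)
  scores <- sv$u[, 1]
  flipped <- FALSE
  ref <- rowMeans(Z)
  if (stats::sd(ref) > 0 && stats::cor(scores, ref) < 0) {
    scores <- -scores
    flipped <- TRUE
  }
  names(scores) <- rownames(m)
  structure(
    list(module_regions = colnames(m),
         subject_scores = scores,
         prop_var_explained = sv$d[1]^2 / sum(sv$d^2),
         singular_values = sv$d,
         sign_flipped = flipped),
    class = "module_expression")
}

#' Connectivity profile of a module's regions
#'
#' For every member region: kIM, the intramodular connectivity (sum of
#' adjacency to the other member regions); kME, the module membership
#' (Pearson correlation between the region's standardized count profile and
#' the module's subject scores); and MAR, the maximum adjacency ratio
#' sum_j a_ij^2 / sum_j a_ij over same-module partners, a density-sensitive
#' statistic that equals the mean edge weight under equal weights and
#' approaches the strongest weight under concentration.
#'
#' @param network a `coactivation_network`.
#' @param x the [count_matrix()] the network was built from (or the test
#'   group's counts when profiling a transferred module).
#' @param module_label module to profile; alternatively pass explicit
#'   `module_regions`.
#' @param module_regions optional explicit member set overriding the label
#'   lookup.
#' @return data.frame (`region_id`, `kIM`, `kME`, `MAR`) with attributes
#'   `kMEall` (kME of every network region against this module's scores) and
#'   `scores` (the module expression object).
#' @export
connectivity_profile <- function(network, x, module_label = NULL,
                                 module_regions = NULL) {
  stopifnot(inherits(network, "coactivation_network"))
  members <- module_regions %||% names(network$modules)[network$modules == module_label]
  if (length(members) < 2) stop("singleton or empty module")
  A <- network$A
  if (!all(members %in% rownames(A))) stop("module regions absent from network")
  me <- module_expression(x, members)
  scores <- me$subject_scores
  sub <- A[members, members, drop = FALSE]
  kIM <- rowSums(sub)
  MAR <- ifelse(kIM > 0, rowSums(sub^2) / kIM, 0)
  zmat <- scale(t(x$counts[rownames(A), names(scores), drop = FALSE]))
  kME_all <- suppressWarnings(as.vector(stats::cor(zmat, scores)))
  names(kME_all) <- rownames(A)
  kME_all[is.na(kME_all)] <- 0
  out <- data.frame(region_id = members,
                    kIM = unname(kIM),
                    kME = unname(kME_all[members]),
                    MAR = unname(MAR),
                    stringsAsFactors = FALSE)
  attr(out, "kMEall") <- kME_all
  attr(out, "scores") <- me
  out
}

#' Rank module regions by intramodular connectivity
#'
#' Orders a connectivity profile by kIM descending (ties broken
#' lexicographically by region id) and reports the mean within-module edge
#' weight per region — the display statistic of hub-ranking plots. The top
#' region is the module's hub candidate.
#'
#' @param profiles result of [connectivity_profile()].
#' @return The profile reordered, with an added `mean_edge_weight` column
#'   (kIM / (module size - 1)) and `rank`.
#' @export
rank_hubs <- function(profiles) {
  if (!nrow(profiles)) stop("empty connectivity profile")
  ord <- order(-profiles$kIM, profiles$region_id)
  out <- profiles[ord, , drop = FALSE]
  out$mean_edge_weight <- out$kIM / (nrow(out) - 1)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
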