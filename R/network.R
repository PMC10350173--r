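#' Inter-region correlation matrix
#'
#' Correlation of region count profiles across subjects, the similarity
#' matrix s_ij underlying the co-activation network.
#'
#' @param x a [count_matrix()].
#' @param subjects optional subject id subset (the network's group, e.g. all
#'   AGG animals).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param zero_variance what to do with constant regions: `"drop"` (default,
#'   logged via warning) or `"zero"` (keep, correlation 0 with everything).
#' @return Symmetric correlation matrix with unit diagonal, region ids as
#'   dimnames.
#' @export
correlation_matrix <- function(x, subjects = NULL,
                               method = c("pearson", "spearman"),
                               zero_variance = c("drop", "zero")) {
  stopifnot(inherits(x, "count_matrix"))
  method <- match.arg(method)
  zero_variance <- match.arg(zero_variance)
  if (!is.null(subjects)) x <- subset_counts(x, subjects = subjects)
  if (ncol(x$counts) < 3) stop("need at least 3 subjects")
  m <- t(x$counts)  # subjects x regions
  sds <- apply(m, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    if (zero_variance == "drop") {
      warning(sprintf("dropping %d zero-variance region(s): %s",
                      sum(flat), paste(colnames(m)[flat], collapse = ", ")))
      m <- m[, !flat, drop = FALSE]
    }
  }
  S <- suppressWarnings(stats::cor(m, method = method))
  S[is.na(S)] <- 0
  diag(S) <- 1
  S
}

# Scale-free topology fit: R^2 of the log-log regression of the binned
# connectivity distribution, with the sign of the slope retained.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(r2 = 0, slope = 0))
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmid <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(c(r2 = 0, slope = 0))
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmid[ok]))
  c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Choose the soft-threshold power
#'
#' Raising correlations to a power suppresses weak, potentially spurious
#' correlations; the power is chosen as the smallest candidate whose
#' resulting connectivity distribution is approximately scale free
#' (log-log regression R^2 above `r2_threshold` with negative slope).
#' If no candidate qualifies, a configured default is returned with a
#' warning.
#'
#' @param S correlation matrix.
#' @param candidates positive candidate powers, tried in increasing order.
#' @param r2_threshold scale-free fit threshold (default 0.8).
#' @param default_power fallback when no candidate qualifies.
#' @param mode adjacency mode passed to [adjacency_power()].
#' @param n_bins connectivity histogram bins for the fit.
#' @return The selected power, with attribute `fit_table` (power, r2, slope).
#' @export
pick_soft_power <- function(S, candidates = 1:12, r2_threshold = 0.8,
                            default_power = 6,
                            mode = c("unsigned", "signed-hybrid"),
                            n_bins = 10L) {
  mode <- match.arg(mode)
  if (!length(candidates) || any(candidates <= 0))
    stop("`candidates` must be non-empty positive powers")
  candidates <- sort(candidates)
  tab <- t(vapply(candidates, function(b) {
    A <- adjacency_power(S, b, mode)
    scale_free_fit(rowSums(A), n_bins)
  }, c(r2 = 0, slope = 0)))
  fit_table <- data.frame(power = candidates, r2 = tab[, "r2"],
                          slope = tab[, "slope"])
  hit <- which(fit_table$r2 > r2_threshold & fit_table$slope < 0)
  if (length(hit)) {
    power <- candidates[hit[1]]
  } else {
    warning(sprintf("no candidate power reached scale-free fit R^2 > %g; falling back to %g",
                    r2_threshold, default_power))
    power <- default_power
  }
  attr(power, "fit_table") <- fit_table
  power
}

#' Power adjacency function
#'
#' Maps correlations to \[0, 1\] edge weights: unsigned mode a_ij = |s_ij|^beta
#' (default); signed-hybrid mode a_ij = s_ij^beta for positive s_ij, else 0.
#' The diagonal is set to 0 so that connectivity and topological overlap sums
#' exclude self-edges.
#'
#' @param S correlation matrix.
#' @param beta_power positive soft-threshold exponent.
#' @param mode `"unsigned"` or `"signed-hybrid"`.
#' @return Symmetric adjacency matrix with zero diagonal, entries in \[0, 1\].
#' @export
adjacency_power <- function(S, beta_power = 6,
                            mode = c("unsigned", "signed-hybrid")) {
  mode <- match.arg(mode)
  stopifnot_scalar_pos(beta_power, "beta_power")
  A <- if (mode == "unsigned") abs(S)^beta_power
       else ifelse(S > 0, S^beta_power, 0)
  diag(A) <- 0
  A
}

#' Topological overlap matrix
#'
#' Pairwise similarity combining the direct connection between two regions
#' with their shared neighbourhood:
#' omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' l_ij = sum_u a_iu a_uj (u outside \{i, j\}) and k_i = sum_j a_ij. The
#' diagonal is 1 and all entries lie in \[0, 1\].
#'
#' @param A symmetric adjacency with zero diagonal and entries in \[0, 1\].
#' @return The TOM matrix, same dimnames as `A`.
#' @export
topological_overlap <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("adjacency must be symmetric")
  if (any(A < 0) || any(A > 1)) stop("adjacency entries must lie in [0, 1]")
  diag(A) <- 0
  L <- A %*% A  # zero diagonal makes u = i, j terms vanish
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Detect modules on a topological overlap matrix
#'
#' Dynamic height cut of an average-linkage dendrogram built on the
#' log-scale overlap dissimilarity `-log(TOM)`. On the log scale the soft
#' power acts approximately as a multiplicative constant, so a cut placed at
#' `cut_height` of the way between the lowest and highest merge
#' (`cut = "relative"`, the default) behaves consistently whatever power
#' produced the adjacency. Two refinement passes make the cut robust on
#' noisy networks: regions are iteratively reassigned to the module with the
#' smallest mean log-dissimilarity to its members provided that attachment
#' lies below the cut (re-adding genuine members split off by the cut, and
#' releasing weakly attached ones), and each module is then pruned above the
#' largest gap in its member-attachment profile when that gap exceeds
#' `gap_frac` of the dendrogram height range (loosely attached passenger
#' regions attach far above the genuine members). `cut = "absolute"` instead
#' performs a classic static cut of 1 - TOM at `cut_height` with no
#' refinement. Clusters smaller than `min_module_size` end in the reserved
#' `"unassigned"` label. Surviving modules are named by colour in decreasing
#' size order (ties broken by the lexicographically smallest member region),
#' so labelling is deterministic.
#'
#' @param TOM topological overlap matrix.
#' @param min_module_size smallest cluster kept as a module (>= 2).
#' @param cut_height relative mode: fraction of the log-scale merge-height
#'   range at which to cut (default 0.4); absolute mode: raw height on
#'   1 - TOM.
#' @param cut `"relative"` (default) or `"absolute"`.
#' @param gap_frac attachment-gap threshold for the pruning pass, as a
#'   fraction of the height range (default 0.08; 0 disables).
#' @param passes maximum reassignment iterations (default 3; 0 disables).
#' @return Named character vector region -> module label.
#' @export
detect_modules <- function(TOM, min_module_size = 3L, cut_height = 0.4,
                           cut = c("relative", "absolute"),
                           gap_frac = 0.08, passes = 3L) {
  cut <- match.arg(cut)
  if (min_module_size < 2) stop("`min_module_size` must be >= 2")
  n <- nrow(TOM)
  ids <- rownames(TOM) %||% sprintf("R%03d", seq_len(n))
  dimnames(TOM) <- list(ids, ids)

  size_filter <- function(cl) {
    tab <- table(cl[cl != 0L])
    cl[cl %in% as.integer(names(tab)[tab < min_module_size])] <- 0L
    cl
  }

  if (cut == "absolute") {
    hc <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
    cl <- size_filter(stats::cutree(hc, h = cut_height))
  } else {
    D <- -log(pmax(TOM, 1e-12))
    diag(D) <- 0
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    hmin <- min(hc$height)
    rng <- max(hc$height) - hmin
    h_cut <- hmin + cut_height * rng
    cl <- size_filter(stats::cutree(hc, h = h_cut))
    if (rng == 0) passes <- gap_frac <- 0  # no structure to refine
    for (pass in seq_len(passes)) {
      mods <- setdiff(unique(cl), 0L)
      if (!length(mods)) break
      new_cl <- cl
      for (r in seq_len(n)) {
        att <- vapply(mods, function(cc)
          mean(D[r, setdiff(which(cl == cc), r)]), 0)
        best <- which.min(att)
        new_cl[r] <- if (att[best] < h_cut) mods[best] else 0L
      }
      new_cl <- size_filter(new_cl)
      if (identical(new_cl, cl)) break
      cl <- new_cl
    }
    if (gap_frac > 0) {
      for (cc in setdiff(unique(cl), 0L)) {
        M <- which(cl == cc)
        if (length(M) < 4) next
        att <- vapply(M, function(r) mean(D[r, setdiff(M, r)]), 0)
        o <- order(att)
        gaps <- diff(att[o])
        j <- which.max(gaps)
        if (gaps[j] > gap_frac * rng && j > length(M) / 2)
          cl[M[o[(j + 1):length(M)]]] <- 0L
      }
      cl <- size_filter(cl)
    }
  }

  labels <- rep(unassigned_label(), n)
  names(labels) <- ids
  sizes <- table(cl[cl != 0L])
  accepted <- names(sizes)
  if (length(accepted)) {
    first_member <- vapply(accepted, function(m)
      min(ids[cl == as.integer(m)]), "")
    ord <- accepted[order(-sizes[accepted], first_member)]
    cols <- module_palette(length(ord))
    for (i in seq_along(ord)) labels[cl == as.integer(ord[i])] <- cols[i]
    if (length(ord) == 1L && all(labels == cols[1]))
      message("all regions fall into a single module")
  }
  labels
}

#' Build a co-activation network for one group of subjects
#'
#' Runs correlation -> soft power selection -> power adjacency -> topological
#' overlap -> module detection, returning all intermediate matrices.
#'
#' @param x a [count_matrix()].
#' @param subjects optional subject id subset defining the group.
#' @param beta_power soft-threshold power (default 6, the customary unsigned
#'   network default); NULL selects the power via [pick_soft_power()] over
#'   `candidates`.
#' @param candidates candidate powers when `beta_power` is NULL.
#' @param mode adjacency mode (see [adjacency_power()]).
#' @param correlation `"pearson"` or `"spearman"`.
#' @param min_module_size,cut_height module detection parameters.
#' @param modules optional precomputed region -> label map (e.g. transferred
#'   from a reference network); skips detection.
#' @return An object of class `coactivation_network`: list with
#'   `region_ids`, `S`, `beta_power`, `A`, `k`, `TOM`, `modules`.
#' @export
build_coactivation_network <- function(x, subjects = NULL, beta_power = 6,
                                       candidates = 1:12,
                                       mode = c("unsigned", "signed-hybrid"),
                                       correlation = c("pearson", "spearman"),
                                       min_module_size = 3L,
                                       cut_height = 0.4,
                                       modules = NULL) {
  mode <- match.arg(mode)
  correlation <- match.arg(correlation)
  S <- correlation_matrix(x, subjects, method = correlation)
  if (is.null(beta_power))
    beta_power <- suppressWarnings(pick_soft_power(S, candidates, mode = mode))
  A <- adjacency_power(S, beta_power, mode)
  TOM <- topological_overlap(A)
  if (is.null(modules)) {
    modules <- detect_modules(TOM, min_module_size, cut_height)
  } else {
    modules <- modules[rownames(S)]
    names(modules) <- rownames(S)
    modules[is.na(modules)] <- unassigned_label()
  }
  structure(
    list(region_ids = rownames(S), S = S,
         beta_power = as.numeric(beta_power), A = A, k = rowSums(A),
         TOM = TOM, modules = modules),
    class = "coactivation_network")
}

#' @export
print.coactivation_network <- function(x, ...) {
  tab <- table(x$modules)
  cat(sprintf("coactivation_network: %d regions, power %g, %d module(s)\n",
              length(x$region_ids), x$beta_power,
              sum(names(tab) != unassigned_label())))
  print(sort(tab, decreasing = TRUE))
  invisible(x)
}

#' Serialise a network to delimited text
#'
#' Writes the correlation, adjacency and TOM matrices, the module map and an
#' edge list under a common file prefix.
#'
#' @param network a `coactivation_network`.
#' @param prefix path prefix for the output files.
#' @param edge_threshold minimum adjacency for the edge-list export.
#' @return Invisibly, the vector of files written.
#' @export
write_network <- function(network, prefix, edge_threshold = 0) {
  wr <- function(m, suffix) {
    f <- paste0(prefix, suffix)
    utils::write.table(data.frame(region = rownames(m), m,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(wr(network$S, "_correlation.tsv"),
             wr(network$A, "_adjacency.tsv"),
             wr(network$TOM, "_tom.tsv"))
  f <- paste0(prefix, "_modules.tsv")
  utils::write.table(data.frame(region = names(network$modules),
                                module = unname(network$modules)),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  ut <- upper.tri(network$A)
  keep <- ut & network$A > edge_threshold
  idx <- which(keep, arr.ind = TRUE)
  el <- data.frame(region_i = rownames(network$A)[idx[, 1]],
                   region_j = colnames(network$A)[idx[, 2]],
                   weight = network$A[keep])
  f <- paste0(prefix, "_edges.tsv")
  utils::write.table(el[order(el$region_i, el$region_j), ], f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(files, f))
}
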