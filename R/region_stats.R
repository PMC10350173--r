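# Negative binomial log-likelihood for counts y with means mu and size theta
# (variance mu + mu^2/theta).
nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# ML dispersion for fixed means, maximised on the log scale.
nb_theta_ml <- function(y, mu, lower = 1e-3, upper = 1e7) {
  opt <- stats::optimize(function(lt) nb_loglik(y, mu, exp(lt)),
                         c(log(lower), log(upper)), maximum = TRUE,
                         tol = 1e-10)
  exp(opt$maximum)
}

#' Negative binomial regression of one region's counts on group
#'
#' Fits counts ~ group with a log link and negative binomial errors
#' (variance mu + mu^2/theta), jointly maximising the likelihood over the
#' intercept, the group coefficient and the dispersion: iteratively
#' reweighted least squares for the coefficients (Fisher scoring with
#' weights mu/(1 + mu/theta)) alternated with maximum-likelihood dispersion
#' updates until the log-likelihood stabilises. The reported z is the group
#' coefficient divided by its standard error from the expected information;
#' p is two-sided normal. Degenerate inputs (a group with all-zero counts, or
#' non-convergence) return a sentinel row with `converged = FALSE` and NA
#' statistics rather than an error.
#'
#' @param y vector of non-negative integer counts.
#' @param group dummy-coded 0/1 group indicator (0 = reference level), same
#'   length as `y`.
#' @param max_iter maximum outer iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @return A one-row data.frame: `beta` (group log fold change), `se_beta`,
#'   `z`, `dispersion` (theta), `p`, `loglik`, `converged`.
#' @export
fit_region_nb <- function(y, group, max_iter = 50L, tol = 1e-10) {
  y <- as.numeric(y)
  group <- as.numeric(group)
  if (length(y) != length(group)) stop("`y` and `group` lengths differ")
  if (!all(group %in% c(0, 1))) stop("`group` must be dummy coded 0/1")
  if (sum(group == 0) < 2 || sum(group == 1) < 2)
    stop("need at least 2 subjects per group")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  sentinel <- data.frame(beta = NA_real_, se_beta = NA_real_, z = NA_real_,
                         dispersion = NA_real_, p = NA_real_,
                         loglik = NA_real_, converged = FALSE)
  if (sum(y) == 0 || sum(y[group == 0]) == 0 || sum(y[group == 1]) == 0)
    return(sentinel)  # log-link group effect diverges: flagged, not raised

  X <- cbind(1, group)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  m <- mean(y); v <- stats::var(y)
  theta <- if (v > m) min(max(m^2 / (v - m), 1e-3), 1e7) else 1e4
  ll_old <- -Inf
  converged <- FALSE
  beta_hat <- c(NA_real_, NA_real_)
  for (it in seq_len(max_iter)) {
    # IRLS for the coefficients at fixed theta
    for (j in 1:25) {
      w <- mu / (1 + mu / theta)
      zz <- eta + (y - mu) / mu
      fit <- tryCatch(
        solve(crossprod(X, w * X), crossprod(X, w * zz)),
        error = function(e) NULL)
      if (is.null(fit)) return(sentinel)
      delta <- max(abs(fit - if (j == 1) fit + 1 else beta_hat))
      beta_hat <- drop(fit)
      eta <- drop(X %*% beta_hat)
      eta <- pmin(pmax(eta, -30), 30)
      mu <- exp(eta)
      if (delta < 1e-12) break
    }
    theta <- nb_theta_ml(y, mu)
    ll <- nb_loglik(y, mu, theta)
    if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  w <- mu / (1 + mu / theta)
  info <- crossprod(X, w * X)
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vcov)) return(sentinel)
  se <- sqrt(vcov[2, 2])
  beta <- beta_hat[2]
  z <- beta / se
  data.frame(beta = beta, se_beta = se, z = z, dispersion = theta,
             p = 2 * stats::pnorm(-abs(z)),
             loglik = nb_loglik(y, mu, theta), converged = converged)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate control with enforced monotonicity. The
#' significance threshold (q < 0.05 in typical use) is the caller's choice,
#' not baked in.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; NAs pass through.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Region-wise negative binomial screen between two groups
#'
#' Runs [fit_region_nb()] for every region of a count matrix with the
#' requested contrast dummy coded (0 = `level0`, 1 = `level1`), then adjusts
#' p-values across all converged regions with [bh_adjust()]. Sentinel
#' (non-converged or degenerate) regions keep NA statistics and are excluded
#' from the adjustment, with a warning naming how many.
#'
#' @param x a [count_matrix()].
#' @param group_field subject metadata column holding the contrast (e.g.
#'   `"phenotype"` or `"virus_group"`).
#' @param level0,level1 the reference and comparison levels.
#' @return data.frame sorted by `region_id` with columns `region_id`, `beta`,
#'   `se_beta`, `z`, `dispersion`, `p`, `q`, `converged`.
#' @export
run_region_screen <- function(x, group_field, level0, level1) {
  stopifnot(inherits(x, "count_matrix"))
  if (!group_field %in% names(x$subjects))
    stop(sprintf("unknown subject metadata field `%s`", group_field))
  g <- x$subjects[[group_field]]
  keep <- g %in% c(level0, level1)
  if (sum(g == level0) < 2 || sum(g == level1) < 2)
    stop("each contrast level needs at least 2 subjects")
  sub <- x$counts[, keep, drop = FALSE]
  dummy <- as.numeric(g[keep] == level1)
  res <- do.call(rbind, lapply(x$region_ids, function(r) {
    out <- fit_region_nb(sub[r, ], dummy)
    cbind(data.frame(region_id = r, stringsAsFactors = FALSE), out)
  }))
  res <- res[order(res$region_id), , drop = FALSE]
  n_bad <- sum(!res$converged)
  if (n_bad > 0)
    warning(sprintf("%d region(s) had degenerate or non-converged fits; excluded from BH adjustment", n_bad))
  res$q <- NA_real_
  res$q[res$converged] <- bh_adjust(res$p[res$converged])
  rownames(res) <- NULL
  res
}

#' Write a region screen result table
#'
#' @param screen result of [run_region_screen()].
#' @param file output path (tab-separated, header).
#' @return Invisibly, `screen`.
#' @export
write_region_screen <- function(screen, file) {
  utils::write.table(screen, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(screen)
}
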