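#' Configuration for the synthetic c-Fos count generator
#'
#' Describes a region-by-subject count simulation with planted modular
#' correlation structure: a Gaussian copula over a latent one-factor-per-module
#' normal model, with marginals mapped to negative binomial quantiles
#' (variance = mu + mu^2/dispersion). Regions not claimed by any module are
#' background noise with zero planted correlation. Group-by-module effects
#' multiply the negative binomial mean for member regions of the named group,
#' emulating phenotype differences in module activity.
#'
#' @param n_regions total number of regions.
#' @param n_subjects_per_group subjects per group label.
#' @param groups character vector of group labels. Tokens separated by `.`
#'   are interpreted as phenotype, sex and virus group in that order (e.g.
#'   `"AGG.male"`), and surface as metadata columns.
#' @param module_spec list of modules, each a list with `label`, `size`
#'   (region count), `rho` (latent within-module correlation in \[0, 1)), and
#'   optionally `hub_multiplier`: a factor applied to the first member
#'   region's latent factor loading (loadings are sqrt(rho), capped at 0.99),
#'   planting a hub. A length-2 `rho = c(lo, hi)` spreads the member
#'   loadings linearly over `sqrt(lo)..sqrt(hi)` (first member strongest),
#'   giving the module a connectivity gradient as real co-activation modules
#'   have; the pairwise latent correlation is then the product of the two
#'   members' loadings.
#' @param group_module_effects list of lists with `group`, `module`, `effect`
#'   (> 0): the multiplicative mean shift for member regions in that group.
#' @param background_rho brain-wide shared covariation: a latent global
#'   factor (arousal/state-like) loading on every region. A scalar r gives
#'   every region latent global correlation r; a length-2 `c(lo, hi)`
#'   spreads the per-region global variance share linearly from `hi` (first
#'   region) to `lo` (last). Default 0 (off). Global and module factors are
#'   orthogonal; a region's module loading is trimmed if needed so the total
#'   latent variance stays 1.
#' @param nb_mean baseline negative binomial mean count per region.
#' @param nb_dispersion negative binomial dispersion (size); variance is
#'   `mu + mu^2 / nb_dispersion`.
#' @param seed integer RNG seed; generation is fully reproducible from it.
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(n_regions, n_subjects_per_group, groups,
                             module_spec = list(),
                             group_module_effects = list(),
                             background_rho = 0,
                             nb_mean = 100, nb_dispersion = 10, seed = 1L) {
  stopifnot_scalar_pos(n_regions, "n_regions")
  stopifnot_scalar_pos(n_subjects_per_group, "n_subjects_per_group")
  stopifnot_scalar_pos(nb_mean, "nb_mean")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop("`nb_dispersion` must be positive")
  groups <- as.character(groups)
  if (!length(groups) || anyDuplicated(groups)) stop("invalid `groups`")
  labels <- vapply(module_spec, function(m) as.character(m$label), "")
  if (anyDuplicated(labels)) stop("duplicate module labels in `module_spec`")
  sizes <- vapply(module_spec, function(m) as.numeric(m$size), 0)
  rhos <- unlist(lapply(module_spec, function(m) as.numeric(m$rho)))
  if (any(sizes < 1)) stop("module sizes must be >= 1")
  if (sum(sizes) > n_regions)
    stop("sum of module region counts exceeds `n_regions`")
  if (length(rhos) && any(rhos < 0 | rhos >= 1))
    stop("within-module correlation must be in [0, 1)")
  background_rho <- as.numeric(background_rho)
  if (any(background_rho < 0 | background_rho >= 1) ||
      !length(background_rho) %in% 1:2)
    stop("`background_rho` must be one or two values in [0, 1)")
  for (ef in group_module_effects) {
    if (!ef$group %in% groups) stop("effect refers to unknown group")
    if (!ef$module %in% labels) stop("effect refers to unknown module")
    if (!is.numeric(ef$effect) || ef$effect <= 0)
      stop("group-module effects must be positive multipliers")
  }
  structure(
    list(n_regions = as.integer(n_regions),
         n_subjects_per_group = as.integer(n_subjects_per_group),
         groups = groups, module_spec = module_spec,
         group_module_effects = group_module_effects,
         background_rho = background_rho,
         nb_mean = nb_mean, nb_dispersion = nb_dispersion,
         seed = as.integer(seed)),
    class = "count_sim_config")
}

#' Simulate a c-Fos count matrix with planted modules
#'
#' Draws, per subject, a latent standard normal vector with a one-factor
#' block correlation structure (members of module m: z_i = lambda_i f_m +
#' sqrt(1 - lambda_i^2) e_i with lambda_i = sqrt(rho), so cor(z_i, z_j) = rho;
#' background regions independent), maps it through the normal CDF, and takes
#' negative binomial quantiles at the region's group-specific mean. Counts are
#' therefore marginally NB(mu, dispersion) with latent (copula) within-module
#' correlation equal to the configured rho.
#'
#' @param config a [count_sim_config()].
#' @return A [count_matrix()] with attributes `planted_modules` (named
#'   character vector, region -> module label or `"background"`) and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  n_reg <- config$n_regions
  n_per <- config$n_subjects_per_group
  groups <- config$groups
  n_sub <- n_per * length(groups)
  region_ids <- sprintf("R%03d", seq_len(n_reg))

  planted <- rep("background", n_reg)
  lambda <- rep(0, n_reg)
  pos <- 1L
  for (m in config$module_spec) {
    idx <- seq.int(pos, pos + m$size - 1L)
    planted[idx] <- m$label
    rho <- as.numeric(m$rho)
    lam <- if (length(rho) == 2L)
      sqrt(seq(rho[2], rho[1], length.out = m$size))
    else rep(sqrt(rho), m$size)
    if (!is.null(m$hub_multiplier))
      lam[1L] <- min(lam[1L] * m$hub_multiplier, 0.99)
    lambda[idx] <- lam
    pos <- pos + as.integer(m$size)
  }
  names(planted) <- region_ids

  # global (brain-state-like) factor loadings, graded across regions
  br <- config$background_rho
  lambda_g <- if (length(br) == 2L)
    sqrt(seq(br[2], br[1], length.out = n_reg))
  else rep(sqrt(br), n_reg)
  # keep total latent variance at 1: trim module loadings if necessary
  over <- lambda^2 + lambda_g^2 > 0.98
  lambda[over] <- sqrt(0.98 - lambda_g[over]^2)

  subj_group <- rep(groups, each = n_per)
  subj_ids <- paste0(subj_group, "_", sprintf("%02d", rep(seq_len(n_per),
                                                          length(groups))))
  tokens <- strsplit(subj_group, ".", fixed = TRUE)
  subjects <- data.frame(
    id = subj_ids,
    group = subj_group,
    phenotype = vapply(tokens, `[`, "", 1L),
    sex = vapply(tokens, function(t) if (length(t) >= 2) t[2] else NA_character_, ""),
    virus_group = vapply(tokens, function(t) if (length(t) >= 3) t[3] else NA_character_, ""),
    stringsAsFactors = FALSE)

  # mean multiplier per (region, group)
  mu <- matrix(config$nb_mean, n_reg, n_sub)
  for (ef in config$group_module_effects) {
    rows <- planted == ef$module
    cols <- subj_group == ef$group
    mu[rows, cols] <- mu[rows, cols] * ef$effect
  }

  counts <- with_seed(config$seed, {
    e <- matrix(stats::rnorm(n_reg * n_sub), n_reg, n_sub)
    g <- stats::rnorm(n_sub)
    resid <- sqrt(1 - lambda^2 - lambda_g^2)
    z <- outer(lambda_g, g) + resid * e
    for (m in config$module_spec) {
      idx <- which(planted == m$label)
      f <- stats::rnorm(n_sub)
      z[idx, ] <- z[idx, , drop = FALSE] + outer(lambda[idx], f)
    }
    u <- stats::pnorm(z)
    cnt <- matrix(stats::qnbinom(u, size = config$nb_dispersion, mu = mu),
                  n_reg, n_sub)
    storage.mode(cnt) <- "integer"
    cnt
  })
  dimnames(counts) <- list(region_ids, subj_ids)
  out <- count_matrix(counts, subjects)
  attr(out, "planted_modules") <- planted
  attr(out, "config") <- config
  out
}
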