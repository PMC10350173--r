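# shared fixture builders for the test suite

# four planted modules over a 60-region brain, the recovery benchmark layout
four_module_config <- function(seed, n_subjects = 40) {
  count_sim_config(
    n_regions = 60, n_subjects_per_group = n_subjects, groups = "G",
    module_spec = list(list(label = "m1", size = 8, rho = 0.6),
                       list(label = "m2", size = 10, rho = 0.6),
                       list(label = "m3", size = 12, rho = 0.6),
                       list(label = "m4", size = 15, rho = 0.6)),
    seed = seed)
}

# reference/test count matrices for preservation checks: one 15-region
# module with graded loadings; `disrupted` regenerates the test group with
# the module correlation ablated
preservation_pair <- function(seed, disrupted = FALSE, n_regions = 200,
                              n_subjects = 30) {
  ms <- function(rho) list(list(label = "pink", size = 15, rho = rho))
  ref <- simulate_counts(count_sim_config(
    n_regions, n_subjects, "R", module_spec = ms(c(0.35, 0.85)), seed = seed))
  test <- simulate_counts(count_sim_config(
    n_regions, n_subjects, "T",
    module_spec = ms(if (disrupted) 0 else c(0.35, 0.85)),
    seed = seed + 50000))
  list(ref = ref, test = test)
}

# adjusted Rand index between two label vectors (mclust implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force TOM evaluation by explicit triple loop
tom_brute <- function(A) {
  n <- nrow(A)
  out <- diag(n)
  k <- rowSums(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    out[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

# random valid adjacency: symmetric, zero diagonal, entries in [0, 1]
random_adjacency <- function(n) {
  A <- matrix(stats::runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# joint NB log-likelihood maximisation by general-purpose optimisation,
# the independent oracle for the IRLS fitter
nb_brute_force <- function(y, g) {
  nll <- function(p)
    -sum(stats::dnbinom(y, size = exp(p[3]), mu = exp(p[1] + p[2] * g),
                        log = TRUE))
  start <- c(log(mean(y[g == 0]) + 0.5),
             log((mean(y[g == 1]) + 0.5) / (mean(y[g == 0]) + 0.5)), 0)
  o <- stats::optim(start, nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, nll, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  list(beta = o$par[2], theta = exp(o$par[3]), loglik = -o$value)
}

# photometry session with transients only after "preceding-attack"
# investigations: n_per_class bouts of each investigation class
two_class_session <- function(seed, n_per_class = 20, amplitude = 2,
                              noise_sd = 0.3) {
  inv_len <- 1.5
  starts <- 130 + (seq_len(2 * n_per_class) - 1) * 11
  preceding <- rep(c(TRUE, FALSE), n_per_class)
  events <- do.call(rbind, lapply(seq_along(starts), function(i) {
    t <- starts[i]
    ev <- data.frame(label = "investigation", start_s = t,
                     stop_s = t + inv_len)
    if (preceding[i])
      ev <- rbind(ev, data.frame(label = "attack", start_s = t + inv_len + 1,
                                 stop_s = t + inv_len + 3))
    ev
  }))
  cfg <- photom_sim_config(
    duration_s = max(starts) + 30, transient_amplitude = amplitude,
    noise_sd = noise_sd,
    event_times_s = starts[preceding] + inv_len, seed = seed)
  simulate_photometry(cfg, events = events)
}
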