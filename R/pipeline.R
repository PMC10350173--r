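#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input paths, the
#' subject filters defining the reference and test networks, network
#' settings, preservation settings, the region-screen contrast, and
#' photometry settings. Every output is stamped with the seed.
#'
#' @param counts_file,metadata_file count matrix input paths (see
#'   [read_count_matrix()]); alternatively pass a ready `count_matrix` via
#'   `counts`.
#' @param counts optional in-memory [count_matrix()] overriding the paths.
#' @param reference_group,test_group lists `list(field =, level =)` selecting
#'   the subjects of each network (e.g. `list(field = "phenotype",
#'   level = "AGG")`). `test_group = NULL` skips preservation.
#' @param correlation,mode,beta_power,candidates,cut_height,min_module_size
#'   network settings (see [build_coactivation_network()]).
#' @param n_permutations,seed preservation permutations and the top-level
#'   seed from which all stage seeds derive.
#' @param screen_contrast list `list(field =, level0 =, level1 =)` for
#'   [run_region_screen()]; NULL skips the screen.
#' @param photometry_sessions list of `photometry_session` objects or of
#'   `list(trace =, events =)` file paths; NULL skips the photometry arm.
#' @param window_s,gap_s,baseline_s photometry settings.
#' @param output_dir directory for delimited-text outputs; NULL keeps
#'   results in memory only.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_file = NULL, metadata_file = NULL,
                            counts = NULL,
                            reference_group, test_group = NULL,
                            correlation = "pearson", mode = "unsigned",
                            beta_power = 6, candidates = 1:12,
                            cut_height = 0.4, min_module_size = 3L,
                            n_permutations = 200L, seed = 1L,
                            screen_contrast = NULL,
                            photometry_sessions = NULL,
                            window_s = c(4, 4), gap_s = 2, baseline_s = 60,
                            output_dir = NULL) {
  if (is.null(counts) && (is.null(counts_file) || is.null(metadata_file)) &&
      is.null(photometry_sessions))
    stop("either `counts`, both input paths, or photometry sessions must be given")
  structure(as.list(environment()), class = "pipeline_config")
}

pick_subjects <- function(x, sel) {
  if (is.null(sel)) return(NULL)
  x$subjects$id[x$subjects[[sel$field]] == sel$level]
}

#' Run the network arm of the pipeline
#'
#' Builds the reference-group network (correlation, soft power, adjacency,
#' TOM, modules), transfers the reference module labels onto the test
#' group's network by region identity, computes module expression and hub
#' rankings, runs the permutation preservation analysis, and screens
#' individual regions with the negative binomial contrast. Stages log as
#' they complete; a failing stage aborts with its name.
#'
#' @param config a [pipeline_config()].
#' @return A bundle list: `ref_network`, `test_network`, `expression`
#'   (per-module expression objects), `hubs` (per-module hub rankings),
#'   `preservation`, `screen`, `seed`.
#' @export
run_network_arm <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  x <- stage("load", config$counts %||%
               read_count_matrix(config$counts_file, config$metadata_file))
  ref_ids <- pick_subjects(x, config$reference_group)
  message("stage network(reference): ", length(ref_ids), " subjects")
  ref_net <- stage("network(reference)", build_coactivation_network(
    x, subjects = ref_ids, beta_power = config$beta_power,
    candidates = config$candidates, mode = config$mode,
    correlation = config$correlation,
    min_module_size = config$min_module_size,
    cut_height = config$cut_height))
  mods <- ref_net$modules[ref_net$modules != unassigned_label()]
  labels <- unique(mods)
  ref_x <- subset_counts(x, subjects = ref_ids)

  expression <- stage("expression", {
    out <- lapply(labels, function(lab)
      module_expression(ref_x, names(mods)[mods == lab]))
    names(out) <- labels
    out
  })
  hubs <- stage("hubs", {
    out <- lapply(labels, function(lab)
      rank_hubs(connectivity_profile(ref_net, ref_x, lab)))
    names(out) <- labels
    out
  })

  test_net <- NULL; preservation <- NULL; test_x <- NULL
  if (!is.null(config$test_group)) {
    test_ids <- pick_subjects(x, config$test_group)
    message("stage network(test): ", length(test_ids), " subjects")
    test_net <- stage("network(test)", build_coactivation_network(
      x, subjects = test_ids, beta_power = ref_net$beta_power,
      mode = config$mode, correlation = config$correlation,
      modules = ref_net$modules))
    test_x <- subset_counts(x, subjects = test_ids)
    message("stage preservation: ", config$n_permutations, " permutations")
    preservation <- stage("preservation", module_preservation(
      ref_net, ref_x, test_net, test_x,
      n_permutations = config$n_permutations, seed = config$seed))
  } else {
    message("no test group configured; preservation skipped")
  }

  screen <- NULL
  if (!is.null(config$screen_contrast)) {
    sc <- config$screen_contrast
    message(sprintf("stage screen: %s %s vs %s", sc$field, sc$level0,
                    sc$level1))
    screen <- stage("screen", suppressWarnings(
      run_region_screen(x, sc$field, sc$level0, sc$level1)))
  }

  bundle <- list(ref_network = ref_net, test_network = test_net,
                 expression = expression, hubs = hubs,
                 preservation = preservation, screen = screen,
                 seed = config$seed)
  if (!is.null(config$output_dir))
    write_network_bundle(bundle, config$output_dir)
  bundle
}

write_network_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(bundle$ref_network, file.path(dir, "reference"))
  if (!is.null(bundle$test_network))
    write_network(bundle$test_network, file.path(dir, "test"))
  expr <- do.call(rbind, lapply(names(bundle$expression), function(lab) {
    sc <- bundle$expression[[lab]]$subject_scores
    data.frame(subject = names(sc), module = lab, score = unname(sc),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(expr))
    utils::write.table(expr, file.path(dir, "module_expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  hubs <- do.call(rbind, lapply(names(bundle$hubs), function(lab)
    cbind(module = lab, bundle$hubs[[lab]])))
  if (!is.null(hubs))
    utils::write.table(hubs, file.path(dir, "connectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$preservation))
    write_preservation(bundle$preservation, file.path(dir, "preservation.tsv"))
  if (!is.null(bundle$screen))
    write_region_screen(bundle$screen, file.path(dir, "region_screen.tsv"))
  utils::write.table(data.frame(key = "seed", value = bundle$seed),
                     file.path(dir, "run_info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the photometry arm of the pipeline
#'
#' Preprocesses every session, classifies bouts, extracts peri-event sets
#' and pools per-class pre/post summaries across sessions. Unreadable or
#' degenerate sessions are skipped with a logged error; the run fails only
#' if every session fails.
#'
#' @param config a [pipeline_config()] with `photometry_sessions` set.
#' @return List with `per_session` (peri-event sets and summaries) and
#'   `pooled` (per-class pooled post-pre differences and trial counts).
#' @export
run_photometry_arm <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sessions <- config$photometry_sessions
  if (!length(sessions)) stop("no photometry sessions configured")
  per_session <- list()
  for (i in seq_along(sessions)) {
    res <- tryCatch({
      s <- sessions[[i]]
      if (!inherits(s, "photometry_session"))
        s <- read_photometry_session(s$trace, s$events)
      tr <- preprocess(s, baseline_s = config$baseline_s)
      ev <- classify_bouts(s$events, gap_s = config$gap_s)
      sets <- peri_event(tr, ev, window_s = config$window_s)
      list(sets = sets, summaries = lapply(sets, pre_post_stats),
           session_class = attr(ev, "session_class"))
    }, error = function(e) {
      message(sprintf("session %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    per_session[[i]] <- res
  }
  ok <- !vapply(per_session, is.null, TRUE)
  if (!any(ok)) stop("all photometry sessions failed")
  classes <- unique(unlist(lapply(per_session[ok], function(r) names(r$sets))))
  pooled <- lapply(classes, function(cl) {
    diffs <- unlist(lapply(per_session[ok], function(r) {
      if (is.null(r$sets[[cl]])) return(numeric(0))
      pre_post_stats(r$sets[[cl]])$per_trial$diff
    }))
    list(event_class = cl, n_trials = length(diffs),
         mean_diff = if (length(diffs)) mean(diffs) else NA_real_)
  })
  names(pooled) <- classes
  list(per_session = per_session, pooled = pooled)
}

#' Run the full pipeline
#'
#' Executes the network arm and, when sessions are configured, the
#' photometry arm. With `output_dir` set, all tables are written as
#' delimited text; reruns with an identical config and seed produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return List with `network` and `photometry` results.
#' @export
run_pipeline <- function(config) {
  has_counts <- !is.null(config$counts) || !is.null(config$counts_file)
  net <- if (has_counts) run_network_arm(config) else NULL
  phot <- if (!is.null(config$photometry_sessions))
    run_photometry_arm(config) else NULL
  if (!is.null(config$output_dir) && !is.null(phot)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    pooled <- do.call(rbind, lapply(phot$pooled, function(p)
      data.frame(event_class = p$event_class, n_trials = p$n_trials,
                 mean_post_minus_pre = p$mean_diff)))
    utils::write.table(pooled,
                       file.path(config$output_dir, "photometry_pooled.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(network = net, photometry = phot)
}
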