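#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the input (a cohort CSV
#' path or a [synth_config] to simulate from), which duration group to
#' analyse, the linkage method, the membership severity levels, the
#' overall alpha and the output directory.
#'
#' @param input Path to a cohort CSV, or a [synth_config].
#' @param group "prolonged" (default), "early" or "all".
#' @param linkage Linkage method for [upgma()].
#' @param thresholds Severity levels for the membership analysis.
#' @param alpha Overall family-wise error rate.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed used for any simulation.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, group = c("prolonged", "early", "all"),
                            linkage = "average",
                            thresholds = c("mild", "moderate"),
                            alpha = 0.05, out_dir = "rpq_results",
                            seed = 1L) {
  group <- match.arg(group)
  stopifnot(alpha > 0, alpha < 1)
  if (is.character(input) && !file.exists(input))
    stop("input file does not exist: ", input)
  if (!is.character(input) && !inherits(input, "synth_config"))
    stop("input must be a file path or a synth_config")
  structure(list(input = input, group = group, linkage = linkage,
                 thresholds = thresholds, alpha = alpha,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full symptom-cluster analysis pipeline
#'
#' Orchestrates every stage on one cohort: load or simulate, score
#' (corrected scores, totals, >= 16 flag), select the duration group, fit
#' the symptom clustering, assign memberships under every criteria
#' combination, and run both association analyses plus the Cramer's V
#' screen of impairment categories. Writes nine artifacts plus a run log
#' to the output directory and is deterministic given (input, config,
#' seed).
#'
#' Artifacts: `scored_cohort.csv`, `correlation_matrix.csv`,
#' `dendrogram.nwk`, `clusters.json`, `membership.csv`,
#' `associations.csv`, `associations.json`, `severity_by_impairment.csv`,
#' `cramers_v.csv`, and `run_log.txt`.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory results (`cohort`, `fit`,
#'   `associations`, `severity`, `cramers_v`) and `paths` to the artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir, c(
    scored = "scored_cohort.csv", corr = "correlation_matrix.csv",
    newick = "dendrogram.nwk", clusters = "clusters.json",
    membership = "membership.csv", assoc_csv = "associations.csv",
    assoc_json = "associations.json", severity = "severity_by_impairment.csv",
    cramer = "cramers_v.csv", log = "run_log.txt"))
  names(paths) <- c("scored", "corr", "newick", "clusters", "membership",
                    "assoc_csv", "assoc_json", "severity", "cramer", "log")
  log_lines <- c(
    sprintf("rpqcluster %s | R %s.%s", as.character(utils::packageVersion("rpqcluster")),
            R.version$major, R.version$minor),
    sprintf("seed: %d | group: %s | linkage: %s | alpha: %g",
            config$seed, config$group, config$linkage, config$alpha))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  cohort <- if (is.character(config$input)) {
    note("input: %s", config$input)
    read_cohort_csv(config$input)
  } else {
    note("input: simulated cohort (n = %d)", config$input$n_participants)
    generate_cohort(config$input, seed = config$seed)
  }

  groups <- split_by_duration(cohort)
  note("duration split: %d early, %d prolonged", nrow(groups$early),
       nrow(groups$prolonged))
  sel <- switch(config$group, prolonged = groups$prolonged,
                early = groups$early, all = cohort)

  withCallingHandlers({
    fit <- rpq_cluster(sel, linkage = config$linkage)
  }, warning = function(w) {
    note("warning: %s", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  clusters <- fit$clusters
  scored <- score_cohort(sel, clusters)
  note("clusters formed: %d (formation level %d)", length(clusters),
       fit$formation_level)

  utils::write.csv(scored, paths["scored"], row.names = FALSE)
  utils::write.csv(round(fit$corr, 10), paths["corr"])
  to_newick(fit$tree, file = paths["newick"])
  jsonlite::write_json(list(
    clusters = lapply(clusters, function(g) rpq_items()$item[g]),
    formation_level = attr(clusters, "formation_level"),
    superclusters = attr(clusters, "superclusters")
  ), paths["clusters"], auto_unbox = TRUE, pretty = TRUE)

  mem_long <- NULL
  for (agg in c("mean", "any", "all")) for (thr in config$thresholds) {
    mm <- assign_membership(scored, clusters, membership_criteria(agg, thr))
    mem_long <- rbind(mem_long, data.frame(
      id = rep(scored$id, length(clusters)),
      cluster = rep(names(clusters), each = nrow(scored)),
      aggregation = agg, threshold = attr(mm, "threshold"),
      member = as.integer(as.matrix(mm))))
  }
  utils::write.csv(mem_long, paths["membership"], row.names = FALSE)

  assoc <- NULL
  for (thr in config$thresholds) {
    a <- membership_association(scored, clusters, threshold = thr,
                                alpha = config$alpha)
    a$severity_level <- thr
    note("membership family (%s): %d tests, Bonferroni alpha %.6f",
         thr, nrow(a), a$bonferroni_alpha[1])
    assoc <- rbind(assoc, as.data.frame(a))
  }
  utils::write.csv(assoc, paths["assoc_csv"], row.names = FALSE)
  jsonlite::write_json(assoc, paths["assoc_json"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")

  sev <- severity_by_impairment(scored, clusters, alpha = config$alpha)
  note("severity family: %d comparisons, Bonferroni alpha %.6f",
       sum(!is.na(sev$bonferroni_alpha)), attr(sev, "family_size")^-1 * config$alpha)
  utils::write.csv(sev, paths["severity"], row.names = FALSE)

  imp <- impairment_indicators(scored)
  cv <- cramers_v_matrix(imp[impairment_names()])
  utils::write.csv(round(cv, 10), paths["cramer"])
  note("impairment completers: %d", nrow(imp))

  writeLines(log_lines, paths["log"])
  invisible(list(cohort = cohort, fit = fit, associations = assoc,
                 severity = sev, cramers_v = cv, paths = paths))
}

#' Read and write cohort CSV files
#'
#' `write_cohort_csv()` writes a cohort table in the fixed dialect (comma
#' separator, UTF-8, header row, "." decimal); `read_cohort_csv()` reads
#' one back with strict validation: required columns present, RPQ scores
#' integers in 0..4 (first offending row/column named), unique ids. A file
#' without impairment columns is accepted with
#' `impairment_data_available = 0` for all rows and a warning.
#'
#' @param path File path.
#' @param cohort A cohort data frame.
#' @return `read_cohort_csv()`: the validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "months_since_concussion", rpq_score_cols())
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$id)) stop("duplicate participant id: ",
                                d$id[duplicated(d$id)][1])
  for (col in rpq_score_cols()) {
    v <- d[[col]]
    bad <- which(!is.na(v) & (!(v %in% 0:4)))
    if (length(bad))
      stop(sprintf("invalid raw score in column %s, row %d (value %s): must be in 0..4",
                   col, bad[1], as.character(v[bad[1]])))
  }
  if (!all(impairment_cols() %in% names(d))) {
    warning("impairment columns missing: cohort accepted with impairment_data_available = 0")
    for (col in impairment_cols()) d[[col]] <- NA_integer_
    d$impairment_data_available <- 0L
  } else if (is.null(d$impairment_data_available)) {
    d$impairment_data_available <- as.integer(!is.na(d$imp_none))
  }
  d
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Save or load a synthetic configuration as a key-value (JSON) file
#'
#' @param config A [synth_config].
#' @param path File path.
#' @return `load_synth_config()`: the reconstructed [synth_config].
#' @export
save_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  jsonlite::write_json(list(
    n_participants = config$n_participants,
    prolonged_fraction = config$prolonged_fraction,
    blocks = lapply(unclass(config$blocks), as.integer),
    rho_within = config$rho_within, rho_between = config$rho_between,
    cutpoints = config$cutpoints,
    impairment_intercepts = as.list(config$impairment_intercepts),
    impairment_slopes = config$impairment_slopes,
    p_other = config$p_other,
    p_impairment_data = config$p_impairment_data
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_synth_config
#' @export
load_synth_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth_config(
    n_participants = x$n_participants,
    prolonged_fraction = x$prolonged_fraction,
    blocks = rpq_partition(lapply(x$blocks, as.integer)),
    rho_within = x$rho_within, rho_between = x$rho_between,
    cutpoints = x$cutpoints,
    impairment_intercepts = unlist(x$impairment_intercepts),
    impairment_slopes = x$impairment_slopes,
    p_other = x$p_other,
    p_impairment_data = x$p_impairment_data
  )
}
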