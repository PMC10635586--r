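#' RPQ-16 item schema
#'
#' The 16 symptoms of the Rivermead Post-Concussion Symptoms Questionnaire in
#' the standard published order. Each symptom is rated 0-4 relative to
#' pre-injury levels. The first three items form the RPQ-3 subscale, the
#' remaining thirteen the RPQ-13.
#'
#' @return A data frame with columns `index`, `item` (short machine-friendly
#'   label) and `label` (full symptom description).
#' @export
#' @examples
#' rpq_items()
rpq_items <- function() {
  data.frame(
    index = 1:16,
    item = c(
      "headache", "dizziness", "nausea", "noise_sensitivity",
      "sleep_disturbance", "fatigue", "irritability", "depression",
      "frustration", "forgetfulness", "poor_concentration",
      "longer_to_think", "blurred_vision", "light_sensitivity",
      "double_vision", "restlessness"
    ),
    label = c(
      "Headaches", "Feelings of dizziness", "Nausea and/or vomiting",
      "Noise sensitivity", "Sleep disturbance", "Fatigue, tiring more easily",
      "Being irritable, easily angered", "Feeling depressed or tearful",
      "Feeling frustrated or impatient", "Forgetfulness, poor memory",
      "Poor concentration", "Taking longer to think",
      "Blurred vision", "Light sensitivity", "Double vision", "Restlessness"
    ),
    stringsAsFactors = FALSE
  )
}

#' Severity labels of the RPQ response scale
#'
#' Labels for the five ordered response levels 0-4.
#'
#' @return A named character vector of length 5 (names "0".."4").
#' @export
rpq_severity_labels <- function() {
  c(`0` = "not experienced at all",
    `1` = "present but no more of a problem",
    `2` = "mild problem",
    `3` = "moderate problem",
    `4` = "severe problem")
}

#' Column names of the raw RPQ score block in a cohort table
#' @keywords internal
rpq_score_cols <- function() paste0("rpq_", sprintf("%02d", 1:16))

#' Analysis impairment categories
#'
#' The six everyday-function domains retained for association analyses.
#' "other" is recorded by the questionnaire but dropped from analyses; "none"
#' is used only for the any-impairment-vs-none severity comparison.
#'
#' @return Character vector of the six impairment names.
#' @export
impairment_names <- function() {
  c("appointments", "conversations", "driving", "math", "paperwork",
    "planning")
}

#' @keywords internal
impairment_cols <- function() paste0("imp_", c(impairment_names(), "other", "none"))

#' Symptom-cluster partitions
#'
#' `rpq_partition()` builds a named partition of the 16 RPQ items into
#' symptom clusters; `rpq_default_clusters()` returns the five-cluster
#' structure recovered from prolonged post-concussion cohorts
#' (headache-related, sensitivity, sleep-fatigue, cognitive, emotional).
#'
#' @param groups Named list of integer vectors of item indices (1-16).
#' @return An object of class `rpq_partition`: a named list of integer item
#'   index vectors covering 1:16 exactly once.
#' @export
#' @examples
#' rpq_default_clusters()
rpq_partition <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("cluster_", seq_along(groups))
  idx <- sort(unlist(groups, use.names = FALSE))
  if (!identical(as.integer(idx), 1:16))
    stop("partition must cover item indices 1:16 exactly once")
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  structure(groups, class = "rpq_partition")
}

#' @rdname rpq_partition
#' @export
rpq_default_clusters <- function() {
  rpq_partition(list(
    headache   = c(1L, 2L, 3L, 13L, 15L),
    sensitivity = c(4L, 14L),
    sleep_fatigue = c(5L, 6L),
    cognitive  = c(10L, 11L, 12L),
    emotional  = c(7L, 8L, 9L, 16L)
  ))
}

#' @export
print.rpq_partition <- function(x, ...) {
  items <- rpq_items()$item
  cat("RPQ symptom-cluster partition (", length(x), " clusters)\n", sep = "")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(items[x[[nm]]], collapse = ", "), "\n", sep = "")
  }
  fl <- attr(x, "formation_level")
  if (!is.null(fl)) cat("  formed after merge ", fl, "\n", sep = "")
  sc <- attr(x, "superclusters")
  if (length(sc)) {
    cat("  superclusters (merge order above the cut):\n")
    for (s in sc) cat("    {", paste(s, collapse = " + "), "}\n", sep = "")
  }
  invisible(x)
}

# match recovered groups against the canonical five-cluster composition;
# unmatched groups keep a positional name
name_clusters <- function(groups) {
  canon <- rpq_default_clusters()
  nms <- character(length(groups))
  for (i in seq_along(groups)) {
    hit <- which(vapply(canon, function(g) identical(g, sort(as.integer(groups[[i]]))),
                        logical(1)))
    nms[i] <- if (length(hit) == 1) names(canon)[hit] else paste0("cluster_", i)
  }
  # disambiguate duplicates defensively
  nms <- make.unique(nms, sep = "_")
  stats::setNames(groups, nms)
}
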