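#' Corrected RPQ scoring
#'
#' Applies the standard response correction to raw RPQ-16 scores: level 1
#' ("present but no more of a problem") is recoded to 0, collapsing the two
#' lowest response levels; all other levels are unchanged. Corrected scores
#' therefore take values in \{0, 2, 3, 4\} and feed every downstream
#' analysis. The map is idempotent.
#'
#' @param raw Integer vector of length 16, or an n x 16 matrix/data frame,
#'   of raw scores in 0..4.
#' @return Corrected scores with the same shape as `raw`.
#' @export
#' @examples
#' correct_scores(c(0, 1, 2, 3, 4, rep(0, 11)))
correct_scores <- function(raw) {
  m <- as.matrix(raw)
  if (is.vector(raw)) m <- matrix(raw, nrow = 1)
  if (ncol(m) != 16) stop("expected 16 RPQ item scores")
  bad <- which(!(m %in% 0:4) | is.na(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid raw score at participant row %d, item %d (value %s): must be an integer in 0..4",
      bad[1, 1], bad[1, 2], as.character(m[bad[1, 1], bad[1, 2]])))
  }
  m[m == 1L] <- 0L
  storage.mode(m) <- "integer"
  if (is.vector(raw)) as.integer(m[1, ]) else m
}

#' Totals, threshold flag and subscales from corrected scores
#'
#' Computes the corrected RPQ-16 total (0-64), the significant-symptom flag
#' (total >= 16, inclusive), the RPQ-3 subscale (items 1-3) and RPQ-13
#' subscale (items 4-16), and optionally the mean corrected severity of each
#' symptom cluster.
#'
#' @param corrected n x 16 matrix of corrected scores (values in 0,2,3,4).
#' @param clusters Optional [rpq_partition]; if supplied, a `mean_<name>`
#'   column per cluster is appended.
#' @return A data frame with columns `total`, `significant_symptoms`,
#'   `rpq3_total`, `rpq13_total` and any cluster means.
#' @export
total_and_flags <- function(corrected, clusters = NULL) {
  m <- as.matrix(corrected)
  if (is.vector(corrected)) m <- matrix(corrected, nrow = 1)
  if (ncol(m) != 16) stop("expected 16 corrected item scores")
  if (any(m == 1L)) stop("corrected scores may never equal 1")
  out <- data.frame(
    total = as.integer(rowSums(m)),
    significant_symptoms = as.integer(rowSums(m) >= 16),
    rpq3_total = as.integer(rowSums(m[, 1:3, drop = FALSE])),
    rpq13_total = as.integer(rowSums(m[, 4:16, drop = FALSE]))
  )
  if (!is.null(clusters)) {
    if (!inherits(clusters, "rpq_partition")) clusters <- rpq_partition(clusters)
    for (nm in names(clusters))
      out[[paste0("mean_", nm)]] <- rowMeans(m[, clusters[[nm]], drop = FALSE])
  }
  out
}

#' Score a cohort table
#'
#' Validates and corrects the raw score block of a cohort table and appends
#' corrected columns (`cor_01`..`cor_16`), totals, the >= 16 flag, RPQ-3 /
#' RPQ-13 subscales and, when a partition is given, per-cluster mean
#' corrected severities. Rows with missing raw items are excluded
#' (complete-case) with a message reporting the count.
#'
#' @param cohort A cohort data frame with columns `rpq_01`..`rpq_16`.
#' @param clusters Optional [rpq_partition] for cluster means.
#' @return The scored cohort (possibly fewer rows).
#' @export
score_cohort <- function(cohort, clusters = NULL) {
  cols <- rpq_score_cols()
  if (!all(cols %in% names(cohort)))
    stop("cohort lacks RPQ score columns ", paste(setdiff(cols, names(cohort)), collapse = ", "))
  raw <- as.matrix(cohort[cols])
  miss <- rowSums(is.na(raw)) > 0
  if (any(miss)) {
    message(sum(miss), " participant(s) with missing RPQ items excluded (complete-case)")
    cohort <- cohort[!miss, , drop = FALSE]
    raw <- raw[!miss, , drop = FALSE]
  }
  corr <- correct_scores(raw)
  colnames(corr) <- sub("rpq_", "cor_", cols)
  cbind(cohort, as.data.frame(corr), total_and_flags(corr, clusters))
}

#' Split a cohort by time since concussion
#'
#' Dichotomises the cohort at 12 months: the prolonged group reported a
#' concussion 12 or more months before responding (the boundary belongs to
#' prolonged), the early group under 12 months. Rows with missing duration
#' are excluded with a message.
#'
#' @param cohort Data frame with a `months_since_concussion` column.
#' @return A list with elements `early` and `prolonged`; the two are
#'   disjoint and together contain every row with a valid duration.
#' @export
split_by_duration <- function(cohort) {
  d <- cohort$months_since_concussion
  if (is.null(d)) stop("cohort lacks months_since_concussion")
  miss <- is.na(d)
  if (any(miss))
    message(sum(miss), " row(s) with missing duration excluded")
  cohort <- cohort[!miss, , drop = FALSE]
  d <- d[!miss]
  list(early = cohort[d < 12, , drop = FALSE],
       prolonged = cohort[d >= 12, , drop = FALSE])
}
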