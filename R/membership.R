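#' Membership criteria for symptom clusters
#'
#' A participant belongs to a symptom cluster when the corrected severities
#' of the cluster's items satisfy the criterion: under `mean` aggregation
#' the mean severity must be at least the threshold (the main analysis),
#' under `any` at least one item, under `all` every item (the sensitivity
#' analyses). Thresholds are inclusive and named on the corrected scale:
#' mild = 2, moderate = 3. The mean comparison uses the exact rational
#' mean, no rounding.
#'
#' @param aggregation One of "mean", "any", "all".
#' @param threshold "mild" (2), "moderate" (3), or the numeric value.
#' @return An object of class `membership_criteria`.
#' @export
membership_criteria <- function(aggregation = c("mean", "any", "all"),
                                threshold = "mild") {
  aggregation <- match.arg(aggregation)
  if (is.character(threshold))
    threshold <- switch(match.arg(threshold, c("mild", "moderate")),
                        mild = 2, moderate = 3)
  if (!threshold %in% c(2, 3))
    stop("threshold must be mild (2) or moderate (3)")
  structure(list(aggregation = aggregation, threshold = threshold),
            class = "membership_criteria")
}

#' @export
print.membership_criteria <- function(x, ...) {
  cat("Cluster membership criterion: ", x$aggregation, " corrected severity >= ",
      x$threshold, " (", if (x$threshold == 2) "mild" else "moderate", ")\n",
      sep = "")
  invisible(x)
}

#' Assign participants to symptom clusters
#'
#' Evaluates one membership criterion for every participant and cluster.
#' Membership is not exclusive: a participant may belong to zero or many
#' clusters. The nesting invariant all-membership \eqn{\subseteq}
#' mean-membership \eqn{\subseteq} any-membership (min >= t implies
#' mean >= t implies max >= t) is asserted on every call.
#'
#' @param scored A scored cohort (from [score_cohort()]) or an n x 16
#'   corrected-score matrix.
#' @param clusters An [rpq_partition].
#' @param criteria A [membership_criteria].
#' @return Data frame of 0/1 membership indicators, one column per cluster,
#'   with the criteria recorded in attributes `aggregation`/`threshold`.
#' @export
assign_membership <- function(scored, clusters, criteria = membership_criteria()) {
  if (!inherits(clusters, "rpq_partition")) clusters <- rpq_partition(clusters)
  if (any(lengths(clusters) == 0)) stop("empty cluster")
  m <- corrected_block(scored)
  t <- criteria$threshold
  agg <- function(f) vapply(clusters, function(g)
    as.integer(apply(m[, g, drop = FALSE], 1, f) >= t), integer(nrow(m)))
  res <- switch(criteria$aggregation,
                mean = agg(mean), any = agg(max), all = agg(min))
  res <- matrix(res, nrow = nrow(m), dimnames = list(NULL, names(clusters)))

  # structural nesting check: all <= mean <= any, elementwise
  lo <- matrix(agg(min), nrow = nrow(m))
  mid <- matrix(agg(mean), nrow = nrow(m))
  hi <- matrix(agg(max), nrow = nrow(m))
  stopifnot(all(lo <= mid), all(mid <= hi))

  out <- as.data.frame(res)
  attr(out, "aggregation") <- criteria$aggregation
  attr(out, "threshold") <- t
  out
}

# extract the corrected-score block from whatever the caller passed
corrected_block <- function(scored) {
  if (is.data.frame(scored)) {
    cc <- sub("rpq_", "cor_", rpq_score_cols())
    if (all(cc %in% names(scored))) return(as.matrix(scored[cc]))
    if (all(rpq_score_cols() %in% names(scored)))
      return(correct_scores(as.matrix(scored[rpq_score_cols()])))
    stop("no corrected or raw RPQ score columns found")
  }
  m <- as.matrix(scored)
  if (ncol(m) != 16) stop("expected 16 score columns")
  if (any(m == 1)) stop("scores must be corrected (never 1)")
  m
}
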