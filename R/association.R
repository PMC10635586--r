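#' Analysis-ready functional-impairment indicators
#'
#' Restricts the cohort to participants who completed the impairment
#' questionnaire, keeps the six analysis impairments (appointments,
#' conversations, driving, math, paperwork, planning) plus the derived
#' "none" flag, and drops the low-frequency "other" category, which is
#' omitted from all analyses. Rows where "none" co-occurs with a specific
#' impairment are contradictory and excluded with a message.
#'
#' @param cohort Cohort data frame with `imp_*` columns and
#'   `impairment_data_available`.
#' @return Data frame of 0/1 indicators: the six impairments and `none`,
#'   with the surviving row indices of `cohort` in attribute `rows`.
#' @export
impairment_indicators <- function(cohort) {
  avail <- cohort$impairment_data_available
  if (is.null(avail)) avail <- as.integer(!is.na(cohort$imp_none))
  keep <- which(avail == 1L)
  six <- paste0("imp_", impairment_names())
  d <- cohort[keep, c(six, "imp_other", "imp_none")]
  specific <- rowSums(d[c(six, "imp_other")]) > 0
  bad <- d$imp_none == 1L & specific
  if (any(bad)) {
    message(sum(bad), " row(s) with contradictory 'none' flag excluded")
    keep <- keep[!bad]; d <- d[!bad, , drop = FALSE]
  }
  out <- d[c(six, "imp_none")]
  names(out) <- c(impairment_names(), "none")
  attr(out, "rows") <- keep
  out
}

#' Cramer's V association between two categorical variables
#'
#' \eqn{V = \sqrt{\chi^2 / (n \cdot \min(r-1, c-1))}} from the Pearson
#' chi-squared statistic without continuity correction. Undefined (returned
#' as `NA` with a warning) when either variable is constant.
#'
#' @param x,y Categorical vectors of equal length.
#' @return A value in `[0, 1]`, or `NA`.
#' @export
cramers_v <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant variable: Cramer's V undefined")
    return(NA_real_)
  }
  tab <- table(x, y)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  unname(sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1))))
}

#' @rdname cramers_v
#' @param d Data frame of categorical columns.
#' @return `cramers_v_matrix`: symmetric matrix of pairwise V values.
#' @export
cramers_v_matrix <- function(d) {
  k <- ncol(d)
  v <- matrix(1, k, k, dimnames = list(names(d), names(d)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    v[i, j] <- v[j, i] <- cramers_v(d[[i]], d[[j]])
  v
}

#' Two-by-two association test with odds ratio
#'
#' Pearson chi-squared with Yates continuity correction by default (the
#' reference default for 2 x 2 tables; set `yates = FALSE` for the
#' uncorrected statistic), or Fisher's exact test (two-sided,
#' hypergeometric) when any expected cell count is below
#' `fisher_threshold` — the classical rule of thumb. The odds ratio
#' is the cross-product `(a d)/(b c)` with a Wald 95% CI on the log scale;
#' when any cell is zero the Haldane-Anscombe correction (0.5 added to all
#' cells) is applied to the OR and CI and the result flagged `corrected`.
#'
#' @param tab 2 x 2 integer matrix: exposure rows x outcome columns, cell
#'   `[1,1]` = exposed with outcome.
#' @param fisher_threshold Expected-count threshold below which Fisher's
#'   exact test is used (default 5).
#' @param yates Use Yates continuity correction in the chi-squared test.
#' @return List of class `rpq_2x2`: `test` ("chi-squared" or "Fisher"),
#'   `statistic` (chi-squared statistic, `NA` for Fisher), `p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `corrected`, `table`.
#' @export
#' @examples
#' two_by_two_test(matrix(c(10, 5, 5, 10), 2, byrow = TRUE))
two_by_two_test <- function(tab, fisher_threshold = 5, yates = TRUE) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) stop("cell counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in 2x2 table")
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected < fisher_threshold)) {
    test <- "Fisher"
    p <- stats::fisher.test(tab)$p.value
    statistic <- NA_real_
  } else {
    test <- "chi-squared"
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    p <- ct$p.value
    statistic <- unname(ct$statistic)
  }
  cells <- c(tab)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; c_ <- cells[2]; b <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  structure(list(
    test = test, statistic = statistic, p_value = p,
    odds_ratio = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    corrected = corrected, table = matrix(as.integer(tab), 2, 2)
  ), class = "rpq_2x2")
}

#' @export
print.rpq_2x2 <- function(x, ...) {
  cat(x$test, " test: p = ", format(x$p_value, digits = 4),
      "; OR = ", sprintf("%.2f [%.2f, %.2f]", x$odds_ratio, x$ci_low, x$ci_high),
      if (x$corrected) " (Haldane-Anscombe corrected)", "\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' The U statistic of the first sample is computed from midranks. For
#' groups of at most 8 observations each, the two-sided p-value is exact:
#' the permutation distribution of U over all assignments of the pooled
#' values is enumerated (a generating-function recursion over doubled
#' midranks, valid under ties) and the probability of a deviation from
#' `n1 n2 / 2` at least as large as observed is returned. For larger
#' groups a normal approximation with tie correction (no continuity
#' correction) is used; it tracks the permutation distribution closely
#' at these sizes.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Per-group size up to which the exact enumeration is
#'   used (default 8).
#' @return List: `U` (first-sample convention), `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (nx <= exact_max && ny <= exact_max) {
    # counts of subsets of size k with doubled-rank sum s, over all
    # C(N, nx) assignments of the pooled midranks to the first group
    r2 <- as.integer(round(2 * r))
    smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
    dp <- matrix(0, nx + 1, smax + 1)
    dp[1, 1] <- 1
    for (v in r2) {
      for (k in nx:1) {
        shifted <- c(rep(0, v), dp[k, seq_len(smax + 1 - v)])
        dp[k + 1, ] <- dp[k + 1, ] + shifted
      }
    }
    s <- 0:smax
    u_vals <- s / 2 - nx * (nx + 1) / 2
    w <- dp[nx + 1, ]
    dev <- abs(u_vals - mu)
    p <- sum(w[dev >= abs(U - mu) - 1e-9]) / sum(w)
    return(list(U = U, p_value = p, method = "exact enumeration"))
  }

  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal approximation"))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Association between symptom-cluster membership and impairments
#'
#' The analysis by symptom-cluster membership: for every cluster x
#' impairment pair a 2x2 table of membership (mean corrected severity at
#' or above the threshold) against the impairment flag is tested with
#' [two_by_two_test()], under one Bonferroni family per severity level
#' (family size = clusters x impairments, e.g. 5 x 6 giving alpha
#' 0.05/30). Pairs significant after Bonferroni are re-analysed under the
#' "any single symptom" and "all symptoms" sensitivity criteria;
#' `sensitivity_robust` records whether both re-analyses stay significant
#' at the family alpha.
#'
#' @param scored Scored cohort (from [score_cohort()]) including `imp_*`
#'   columns and `impairment_data_available`.
#' @param clusters An [rpq_partition].
#' @param threshold "mild" or "moderate" severity level.
#' @param alpha Family-wise error rate before division (default 0.05).
#' @param sensitivity Run the any/all sensitivity re-analyses.
#' @return Data frame of class `rpq_assoc`, one row per cluster x
#'   impairment, with test, p-value, OR and CI, `bonferroni_alpha`,
#'   `significant` (p < family alpha), `significant_unadjusted`
#'   (p < 0.05), sensitivity ORs/p-values and `sensitivity_robust`.
#' @export
membership_association <- function(scored, clusters, threshold = "mild",
                                   alpha = 0.05, sensitivity = TRUE) {
  if (!inherits(clusters, "rpq_partition")) clusters <- rpq_partition(clusters)
  imp <- impairment_indicators(scored)
  rows <- attr(imp, "rows")
  sub <- scored[rows, , drop = FALSE]
  fam <- length(clusters) * length(impairment_names())
  b_alpha <- alpha / fam

  mem <- lapply(c("mean", "any", "all"), function(a)
    assign_membership(sub, clusters, membership_criteria(a, threshold)))
  names(mem) <- c("mean", "any", "all")

  one <- function(mvec, ivec) {
    tab <- matrix(c(sum(mvec == 1 & ivec == 1), sum(mvec == 1 & ivec == 0),
                    sum(mvec == 0 & ivec == 1), sum(mvec == 0 & ivec == 0)),
                  2, 2, byrow = TRUE)
    tryCatch(two_by_two_test(tab), error = function(e) {
      message("untestable 2x2 table (", conditionMessage(e), "); result set NA")
      list(test = NA_character_, statistic = NA_real_, p_value = NA_real_,
           odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           corrected = NA)
    })
  }

  out <- NULL
  for (cl in names(clusters)) for (k in impairment_names()) {
    t0 <- one(mem$mean[[cl]], imp[[k]])
    row <- data.frame(
      cluster = cl, impairment = k, aggregation = "mean",
      threshold = attr(mem$mean, "threshold"),
      test = t0$test, statistic = t0$statistic, p_value = t0$p_value,
      odds_ratio = t0$odds_ratio, ci_low = t0$ci_low, ci_high = t0$ci_high,
      or_corrected = t0$corrected,
      bonferroni_alpha = b_alpha,
      significant = t0$p_value < b_alpha,
      significant_unadjusted = t0$p_value < alpha,
      or_any = NA_real_, p_any = NA_real_,
      or_all = NA_real_, p_all = NA_real_,
      sensitivity_robust = NA
    )
    if (sensitivity && isTRUE(row$significant)) {
      ta <- one(mem$any[[cl]], imp[[k]])
      tl <- one(mem$all[[cl]], imp[[k]])
      row$or_any <- ta$odds_ratio; row$p_any <- ta$p_value
      row$or_all <- tl$odds_ratio; row$p_all <- tl$p_value
      row$sensitivity_robust <- ta$p_value < b_alpha && tl$p_value < b_alpha
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  attr(out, "n") <- nrow(sub)
  attr(out, "family_size") <- fam
  class(out) <- c("rpq_assoc", "data.frame")
  out
}

#' @export
print.rpq_assoc <- function(x, digits = 2, ...) {
  cat("Symptom-cluster membership associations (n = ", attr(x, "n"),
      ", Bonferroni alpha = ", format(x$bonferroni_alpha[1], digits = 2),
      ", family of ", attr(x, "family_size"), ")\n", sep = "")
  disp <- data.frame(
    cluster = x$cluster, impairment = x$impairment,
    result = ifelse(x$significant,
                    sprintf("%.*f [%.*f, %.*f]", digits, x$odds_ratio,
                            digits, x$ci_low, digits, x$ci_high),
                    ifelse(x$significant_unadjusted, "NS*", "NS")))
  print(disp, row.names = FALSE, ...)
  cat("NS = not significant after Bonferroni; * = p < 0.05 unadjusted\n")
  invisible(x)
}

#' Symptom severity by functional impairment
#'
#' The analysis by functional impairment. First, the corrected RPQ-16
#' total of participants reporting any of the six impairments is compared
#' with the "none" group (single Mann-Whitney comparison, no family).
#' Then, for each impairment x severity score (total plus the mean of each
#' symptom cluster), reporters are compared with non-reporters among
#' impairment-question completers; that family of 6 x (1 + clusters)
#' comparisons (6 x 6 = 36 with five clusters) is Bonferroni-corrected at
#' `alpha / 36`. Comparisons where either group has fewer than 2 members
#' are skipped with a message.
#'
#' @param scored Scored cohort including cluster mean columns (score with
#'   `score_cohort(cohort, clusters)`).
#' @param clusters The [rpq_partition] whose mean columns are compared.
#' @param alpha Family-wise error rate before division.
#' @return Data frame: `impairment`, `score`, group sizes and means, `U`,
#'   `p_value`, `bonferroni_alpha`, `significant`,
#'   `significant_unadjusted`. The any-vs-none row has `impairment =
#'   "any_vs_none"` and no family alpha.
#' @export
severity_by_impairment <- function(scored, clusters, alpha = 0.05) {
  if (!inherits(clusters, "rpq_partition")) clusters <- rpq_partition(clusters)
  imp <- impairment_indicators(scored)
  sub <- scored[attr(imp, "rows"), , drop = FALSE]
  score_cols <- c(total = "total",
                  stats::setNames(paste0("mean_", names(clusters)), names(clusters)))
  missing_cols <- setdiff(score_cols, names(sub))
  if (length(missing_cols))
    stop("scored cohort lacks columns ", paste(missing_cols, collapse = ", "),
         "; score with score_cohort(cohort, clusters)")
  fam <- length(impairment_names()) * length(score_cols)
  b_alpha <- alpha / fam

  rows <- list()
  any_imp <- rowSums(imp[impairment_names()]) > 0
  none <- imp$none == 1
  if (sum(any_imp) >= 2 && sum(none) >= 2) {
    mw <- mann_whitney(sub$total[any_imp], sub$total[none])
    rows[[1]] <- data.frame(
      impairment = "any_vs_none", score = "total",
      n_with = sum(any_imp), n_without = sum(none),
      mean_with = mean(sub$total[any_imp]), mean_without = mean(sub$total[none]),
      U = mw$U, p_value = mw$p_value,
      bonferroni_alpha = NA_real_, significant = NA,
      significant_unadjusted = mw$p_value < alpha)
  } else message("any-vs-none comparison skipped: a group has < 2 members")

  for (k in impairment_names()) for (s in names(score_cols)) {
    w <- imp[[k]] == 1
    v <- sub[[score_cols[[s]]]]
    if (sum(w) < 2 || sum(!w) < 2) {
      message("comparison ", k, " x ", s, " skipped: a group has < 2 members")
      next
    }
    mw <- mann_whitney(v[w], v[!w])
    rows[[length(rows) + 1]] <- data.frame(
      impairment = k, score = s,
      n_with = sum(w), n_without = sum(!w),
      mean_with = mean(v[w]), mean_without = mean(v[!w]),
      U = mw$U, p_value = mw$p_value,
      bonferroni_alpha = b_alpha,
      significant = mw$p_value < b_alpha,
      significant_unadjusted = mw$p_value < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "family_size") <- fam
  out
}

#' Per-symptom comparison of early and prolonged groups
#'
#' Compares symptom presence (corrected severity at or above
#' `presence_threshold`, default mild = 2) between the early (< 12 months)
#' and prolonged (>= 12 months) groups with a 2x2 chi-squared or Fisher
#' test per symptom. Reported descriptively: no multiplicity correction.
#'
#' @param early,prolonged Scored subcohorts (see [split_by_duration()],
#'   [score_cohort()]).
#' @param presence_threshold Corrected severity defining symptom presence.
#' @return Data frame with one row per RPQ item: presence counts, test,
#'   p-value, OR (early relative to prolonged) and CI.
#' @export
compare_early_prolonged <- function(early, prolonged, presence_threshold = 2) {
  me <- corrected_block(early); mp <- corrected_block(prolonged)
  items <- rpq_items()$item
  out <- NULL
  for (j in 1:16) {
    pe <- me[, j] >= presence_threshold
    pp <- mp[, j] >= presence_threshold
    tab <- matrix(c(sum(pe), sum(!pe), sum(pp), sum(!pp)), 2, 2, byrow = TRUE)
    t0 <- two_by_two_test(tab)
    out <- rbind(out, data.frame(
      item = items[j],
      n_early_present = sum(pe), n_early = length(pe),
      n_prolonged_present = sum(pp), n_prolonged = length(pp),
      test = t0$test, statistic = t0$statistic, p_value = t0$p_value,
      odds_ratio = t0$odds_ratio, ci_low = t0$ci_low, ci_high = t0$ci_high,
      or_corrected = t0$corrected))
  }
  rownames(out) <- NULL
  out
}
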