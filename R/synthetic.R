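#' Configuration for the synthetic RPQ cohort generator
#'
#' Defines a Gaussian-copula generative model for RPQ-16 cohorts: a latent
#' 16-dimensional normal vector with a block correlation structure (planted
#' symptom clusters) is discretised through per-item cutpoints into ordinal
#' 0-4 scores, and binary functional-impairment flags are drawn from a
#' logistic model on the mean corrected severity of each cluster.
#'
#' Defaults emulate the structure of a prolonged post-concussion cohort:
#' five planted clusters, 445/467 prolonged fraction, impairment baseline
#' prevalences at the observed 5.9-44.9% range, impairment-question
#' completion at 254/467, and a 4% "other" impairment rate. Severity slopes
#' default to zero (a null generator); plant effects explicitly via
#' `impairment_slopes` or [slope_for_target_or()].
#'
#' @param n_participants Number of participants (>= 2).
#' @param prolonged_fraction Probability a participant is in the prolonged
#'   (>= 12 months) group.
#' @param blocks An [rpq_partition] giving the planted correlation blocks.
#' @param rho_within,rho_between Latent correlations inside / across blocks;
#'   both in (-1, 1) and the implied matrix must be positive definite.
#' @param cutpoints 16 x 4 matrix of strictly increasing standard-normal
#'   thresholds mapping the latent value to scores 0-4; a single row is
#'   recycled. Default: shared cutpoints with category probabilities
#'   (0.50, 0.20, 0.14, 0.10, 0.06).
#' @param impairment_intercepts Named log-odds baselines for the six
#'   analysis impairments (at average symptom severity).
#' @param impairment_slopes Clusters x impairments matrix of log-odds
#'   increments per unit of (centred) mean corrected cluster severity.
#' @param p_other Base rate of the "other" impairment (independent).
#' @param p_impairment_data Probability the impairment questionnaire was
#'   completed.
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 200)
#' cohort <- generate_cohort(cfg, seed = 1)
synth_config <- function(n_participants = 467,
                         prolonged_fraction = 445 / 467,
                         blocks = rpq_default_clusters(),
                         rho_within = 0.6,
                         rho_between = 0.15,
                         cutpoints = NULL,
                         impairment_intercepts = NULL,
                         impairment_slopes = NULL,
                         p_other = 0.04,
                         p_impairment_data = 254 / 467) {
  if (!inherits(blocks, "rpq_partition")) blocks <- rpq_partition(blocks)
  if (n_participants < 2) stop("n_participants must be at least 2")
  stopifnot(prolonged_fraction >= 0, prolonged_fraction <= 1)
  if (abs(rho_within) >= 1 || abs(rho_between) >= 1)
    stop("rho_within and rho_between must lie in (-1, 1)")

  if (is.null(cutpoints)) {
    # shared marginal: category probabilities for levels 0..4
    p <- c(0.50, 0.20, 0.14, 0.10, 0.06)
    cutpoints <- matrix(stats::qnorm(cumsum(p)[1:4]), nrow = 16, ncol = 4,
                        byrow = TRUE)
  } else {
    cutpoints <- as.matrix(cutpoints)
    if (nrow(cutpoints) == 1) cutpoints <- cutpoints[rep(1, 16), , drop = FALSE]
    if (!all(dim(cutpoints) == c(16, 4)))
      stop("cutpoints must be a 16 x 4 matrix (or one recycled row)")
    if (any(apply(cutpoints, 1, function(r) any(diff(r) <= 0))))
      stop("cutpoints must be strictly increasing within each item")
  }

  imp <- impairment_names()
  if (is.null(impairment_intercepts)) {
    # baseline prevalences of the six analysis impairments among completers
    prev <- c(appointments = 87, conversations = 114, driving = 15,
              math = 70, paperwork = 94, planning = 74) / 254
    impairment_intercepts <- stats::qlogis(prev)
  }
  if (is.null(names(impairment_intercepts)))
    names(impairment_intercepts) <- imp
  if (!setequal(names(impairment_intercepts), imp))
    stop("impairment_intercepts must be named by the six analysis impairments")
  impairment_intercepts <- impairment_intercepts[imp]

  if (is.null(impairment_slopes))
    impairment_slopes <- matrix(0, length(blocks), length(imp),
                                dimnames = list(names(blocks), imp))
  impairment_slopes <- as.matrix(impairment_slopes)
  if (!all(dim(impairment_slopes) == c(length(blocks), length(imp))))
    stop("impairment_slopes must be clusters x impairments")
  dimnames(impairment_slopes) <- list(names(blocks), imp)

  sigma <- matrix(rho_between, 16, 16)
  for (g in blocks) sigma[g, g] <- rho_within
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("implied latent correlation matrix is not positive definite")

  structure(list(
    n_participants = as.integer(n_participants),
    prolonged_fraction = prolonged_fraction,
    blocks = blocks,
    rho_within = rho_within, rho_between = rho_between,
    sigma = sigma,
    cutpoints = cutpoints,
    impairment_intercepts = impairment_intercepts,
    impairment_slopes = impairment_slopes,
    p_other = p_other,
    p_impairment_data = p_impairment_data
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic RPQ cohort configuration\n")
  cat("  n =", x$n_participants,
      " prolonged fraction =", signif(x$prolonged_fraction, 4), "\n")
  cat("  planted blocks:", paste(names(x$blocks), collapse = ", "), "\n")
  cat("  rho within/between =", x$rho_within, "/", x$rho_between, "\n")
  cat("  nonzero severity slopes:", sum(x$impairment_slopes != 0), "\n")
  invisible(x)
}

# expected corrected score per item implied by the cutpoints
# (levels 0..4 recoded 1 -> 0 before averaging)
item_expected_corrected <- function(config) {
  vals <- c(0, 0, 2, 3, 4)
  apply(config$cutpoints, 1, function(cp) {
    p <- diff(stats::pnorm(c(-Inf, cp, Inf)))
    sum(vals * p)
  })
}

# expected mean corrected severity per planted cluster (centring constants
# for the logistic impairment model)
cluster_expected_severity <- function(config) {
  e <- item_expected_corrected(config)
  vapply(config$blocks, function(g) mean(e[g]), numeric(1))
}

#' Category probabilities implied by an item's cutpoints
#'
#' Closed-form multinomial probabilities for the five ordinal levels of one
#' item under the Gaussian copula: successive differences of the standard
#' normal CDF at the cutpoints.
#'
#' @param config A [synth_config].
#' @param item Item index 1-16.
#' @return Numeric vector of length 5 summing to 1.
#' @export
category_probabilities <- function(config, item) {
  diff(stats::pnorm(c(-Inf, config$cutpoints[item, ], Inf)))
}

#' Generate a synthetic RPQ cohort
#'
#' Draws one cohort from the generative model in a [synth_config]:
#' a latent multivariate normal vector per participant (block correlation
#' structure), discretised through the per-item cutpoints into raw 0-4
#' scores, plus logistic functional-impairment flags driven by centred mean
#' corrected cluster severities. Deterministic given `(config, seed)`.
#'
#' Impairment flags are `NA` for participants who did not complete the
#' impairment questionnaire (`impairment_data_available == 0`). The "none"
#' flag is derived: 1 exactly when all seven specific flags are 0.
#'
#' @param config A [synth_config].
#' @param seed Integer master seed; independent sub-streams are derived for
#'   the duration, latent-score, impairment and availability components.
#' @return A `data.frame` cohort table: `id`, `months_since_concussion`,
#'   `rpq_01` .. `rpq_16`, `imp_*` flags and `impairment_data_available`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_participants
  seed <- as.integer(seed)

  # independent sub-streams so each component is reproducible on its own
  sub <- local({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, 4L)
  })

  # duration / group
  set.seed(sub[1])
  prolonged <- stats::runif(n) < config$prolonged_fraction
  months <- ifelse(prolonged, stats::runif(n, 12, 120), stats::runif(n, 0.5, 12))
  months <- round(months, 1)
  months[!prolonged & months >= 12] <- 11.9  # guard rounding at the boundary

  # latent scores -> ordinal raw responses
  set.seed(sub[2])
  z <- MASS::mvrnorm(n, mu = rep(0, 16), Sigma = config$sigma)
  raw <- matrix(0L, n, 16, dimnames = list(NULL, rpq_score_cols()))
  for (j in 1:16) raw[, j] <- findInterval(z[, j], config$cutpoints[j, ])

  # impairments from the logistic model on centred mean corrected severities
  corrected <- correct_scores(raw)
  mu <- cluster_expected_severity(config)
  sev <- vapply(seq_along(config$blocks),
                function(k) rowMeans(corrected[, config$blocks[[k]], drop = FALSE]) - mu[k],
                numeric(n))
  eta <- sweep(sev %*% config$impairment_slopes, 2,
               config$impairment_intercepts, `+`)
  set.seed(sub[3])
  p <- stats::plogis(eta)
  flags <- matrix(as.integer(stats::runif(length(p)) < p), nrow = n,
                  dimnames = list(NULL, paste0("imp_", impairment_names())))
  other <- as.integer(stats::runif(n) < config$p_other)
  none <- as.integer(rowSums(flags) + other == 0L)

  set.seed(sub[4])
  avail <- as.integer(stats::runif(n) < config$p_impairment_data)
  flags[avail == 0L, ] <- NA_integer_
  other[avail == 0L] <- NA_integer_
  none[avail == 0L] <- NA_integer_

  out <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    months_since_concussion = months,
    raw, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  out[paste0("imp_", impairment_names())] <- as.data.frame(flags)
  out$imp_other <- other
  out$imp_none <- none
  out$impairment_data_available <- avail
  out
}

#' Planted ground-truth partition of a synthetic configuration
#'
#' @param config A [synth_config].
#' @return The configuration's block structure as an [rpq_partition];
#'   independent of any seed.
#' @export
planted_partition <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  config$blocks
}

#' Population odds ratio implied by one severity slope
#'
#' Computes, by large-sample Monte-Carlo integration over the severity
#' distribution, the odds ratio between symptom-cluster membership (mean
#' corrected severity at or above `threshold`) and an impairment whose
#' log-odds rise by `slope` per unit of centred cluster severity.
#' `slope_for_target_or()` inverts this mapping with `uniroot`, returning
#' the slope that plants a desired population odds ratio.
#'
#' @param config A [synth_config] (its cutpoints/blocks define the severity
#'   distribution; its slopes are ignored here).
#' @param cluster Cluster name or index in `config$blocks`.
#' @param impairment One of [impairment_names()].
#' @param slope Log-odds increment per unit centred severity.
#' @param threshold Membership threshold on the corrected scale (2 = mild).
#' @param n_mc Monte-Carlo sample size for the severity distribution.
#' @param mc_seed Seed of the integration sample (fixed by default so the
#'   mapping is a deterministic function of the configuration).
#' @return `implied_or`: the population odds ratio. `slope_for_target_or`:
#'   the slope achieving `target_or`.
#' @export
implied_or <- function(config, cluster, impairment, slope, threshold = 2,
                       n_mc = 200000, mc_seed = 20260101) {
  sev <- severity_sample(config, cluster, n_mc, mc_seed)
  a <- config$impairment_intercepts[[impairment]]
  m <- sev$centred + sev$mu >= threshold
  if (!any(m) || all(m)) stop("membership is degenerate at this threshold")
  p <- stats::plogis(a + slope * sev$centred)
  p1 <- mean(p[m]); p0 <- mean(p[!m])
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' @rdname implied_or
#' @param target_or Desired population odds ratio (> 0).
#' @export
slope_for_target_or <- function(config, cluster, impairment, target_or,
                                threshold = 2, n_mc = 200000,
                                mc_seed = 20260101) {
  stopifnot(target_or > 0)
  sev <- severity_sample(config, cluster, n_mc, mc_seed)
  a <- config$impairment_intercepts[[impairment]]
  m <- sev$centred + sev$mu >= threshold
  f <- function(b) {
    p <- stats::plogis(a + b * sev$centred)
    p1 <- mean(p[m]); p0 <- mean(p[!m])
    log((p1 / (1 - p1)) / (p0 / (1 - p0))) - log(target_or)
  }
  stats::uniroot(f, c(-10, 10), tol = 1e-8)$root
}

# draw the centred mean corrected severity of one cluster (marginal of the
# generative model restricted to that block)
severity_sample <- function(config, cluster, n_mc, mc_seed) {
  if (is.character(cluster)) cluster <- match(cluster, names(config$blocks))
  g <- config$blocks[[cluster]]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(mc_seed)
  z <- MASS::mvrnorm(n_mc, mu = rep(0, length(g)),
                     Sigma = config$sigma[g, g, drop = FALSE])
  raw <- matrix(0L, n_mc, length(g))
  for (j in seq_along(g)) raw[, j] <- findInterval(z[, j], config$cutpoints[g[j], ])
  corr <- ifelse(raw == 1L, 0L, raw)
  mu <- cluster_expected_severity(config)[[cluster]]
  list(centred = rowMeans(corr) - mu, mu = mu)
}
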