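#' Inter-observer correlation of the ALPS index
#'
#' Pearson correlation between the two observers' indices across subjects,
#' with a two-sided 95\% confidence interval by the Fisher z-transform.
#' An intraclass correlation ICC(2,1) — two-way random effects, absolute
#' agreement, single rater — is also returned as a labeled extension for
#' modern agreement practice; the headline statistic is the Pearson r.
#'
#' @param table cohort table (see [makeCohortTable()]) with per-observer
#'   columns \code{index_obs_a}, \code{index_obs_b}.
#' @return list with \code{r}, \code{ci} (length 2), \code{n}, \code{icc21}.
#' @export
interobserverCorrelation <- function(table) {
  assertCohortTable(table, needObservers = TRUE)
  a <- table$index_obs_a; b <- table$index_obs_b
  bad <- !is.finite(a) | !is.finite(b)
  if (any(bad)) {
    who <- if ("subject_id" %in% names(table)) table$subject_id[bad] else which(bad)
    stop("missing observer value for subject(s): ", paste(who, collapse = ", "))
  }
  n <- length(a)
  r <- stats::cor(a, b)
  ci <- if (n > 3 && abs(r) < 1) {
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    tanh(z + stats::qnorm(c(0.025, 0.975)) * se)
  } else c(NA_real_, NA_real_)
  ## ICC(2,1) from the two-way mean squares (subjects x 2 raters)
  ms <- iccMeanSquares(a, b)
  icc <- (ms$msr - ms$mse) /
    (ms$msr + ms$mse + 2 * (ms$msc - ms$mse) / n)
  list(r = r, ci = ci, n = n, icc21 = icc)
}

iccMeanSquares <- function(a, b) {
  x <- cbind(a, b); n <- nrow(x); k <- 2
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  list(msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)))
}

#' Linear regression of the ALPS index on age
#'
#' Ordinary least squares of the per-subject (observer-mean) index on age,
#' optionally restricted to subjects strictly older than \code{minAge}
#' ("older than 40 years" means age > 40). The correlation coefficient is
#' signed.
#'
#' @param table cohort table with columns \code{age} and \code{index}.
#' @param minAge strict lower age bound for a subgroup fit, or \code{NULL}
#'   for all subjects.
#' @return A \linkS4class{RegressionResult}.
#' @export
linearFit <- function(table, minAge = NULL) {
  assertCohortTable(table)
  sub <- if (is.null(minAge)) table else table[table$age > minAge, , drop = FALSE]
  if (nrow(sub) < 3)
    stop(sprintf("need at least 3 records, have %d", nrow(sub)))
  fit <- stats::lm(index ~ age, data = sub)
  r <- suppressWarnings(stats::cor(sub$age, sub$index))
  if (!is.finite(r)) r <- 0 # zero-variance response: flat line, no association
  new("RegressionResult",
    model = "linear",
    coefficients = c(intercept = unname(stats::coef(fit)[1]),
                     age = unname(stats::coef(fit)[2])),
    r = r, R = abs(r), vertexAge = NA_real_,
    band = confidenceBand(fit, sub$age), n = nrow(sub)
  )
}

#' Quadratic (second-degree) regression of the ALPS index on age
#'
#' OLS on age and age^2. Returns the multiple correlation
#' R = sqrt(coefficient of determination) and, when the quadratic term is
#' negative (concave trajectory), the fitted vertex age -b1 / (2 b2) — the
#' age at which the index peaks.
#'
#' @param table cohort table with columns \code{age} and \code{index}.
#' @return A \linkS4class{RegressionResult}.
#' @export
quadraticFit <- function(table) {
  assertCohortTable(table)
  if (nrow(table) < 4)
    stop(sprintf("need at least 4 records, have %d", nrow(table)))
  if (length(unique(table$age)) < 3)
    stop("degenerate design: need at least 3 distinct ages")
  fit <- stats::lm(index ~ age + I(age^2), data = table)
  co <- stats::coef(fit)
  if (any(is.na(co))) stop("degenerate design: quadratic fit is rank deficient")
  ## exact parabolas are legitimate inputs; silence lm's perfect-fit warning
  R <- sqrt(max(suppressWarnings(summary(fit)$r.squared), 0))
  vertex <- if (co[3] < 0) -co[2] / (2 * co[3]) else NA_real_
  new("RegressionResult",
    model = "quadratic",
    coefficients = c(intercept = unname(co[1]), age = unname(co[2]),
                     age2 = unname(co[3])),
    r = NA_real_, R = R, vertexAge = unname(vertex),
    band = confidenceBand(fit, table$age), n = nrow(table)
  )
}

## internal: two-sided 95% confidence band over the observed age range
confidenceBand <- function(fit, ages, length.out = 101) {
  grid <- data.frame(age = seq(min(ages), max(ages), length.out = length.out))
  p <- stats::predict(fit, newdata = grid, interval = "confidence", level = 0.95)
  data.frame(age = grid$age, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
}

#' Decade-wise one-way ANOVA with Tukey post-hoc comparisons
#'
#' Tests whether the mean index differs across decade groups, then compares
#' all group pairs by Tukey's honest significant difference at family-wise
#' level 0.05. Group summaries use type-7 quantiles and flag outliers beyond
#' 1.5 IQR from the quartiles, matching standard boxplot conventions.
#'
#' @param table cohort table with columns \code{index} and \code{decade}
#'   (see [makeCohortTable()]; \code{decade} is derived if only \code{age}
#'   is present).
#' @return An \linkS4class{AnovaResult}.
#' @export
decadeAnova <- function(table) {
  assertCohortTable(table)
  if (!"decade" %in% names(table)) table$decade <- decadeOf(table$age)
  grp <- factor(table$decade, levels = sort(unique(table$decade)))
  sizes <- table(grp)
  if (length(sizes) < 2 || sum(sizes >= 2) < 2)
    stop("insufficient groups: need >= 2 decades with >= 2 records each")
  x <- table$index
  fit <- stats::aov(x ~ grp)
  an <- summary(fit)[[1]]
  fStat <- an[["F value"]][1]
  pVal <- an[["Pr(>F)"]][1]
  ## exactly zero within-group variance: report the limit, not QR round-off
  if (sum((x - stats::ave(x, grp))^2) == 0) {
    fStat <- Inf
    pVal <- 0
  }
  ## pairwise table, C(k, 2) rows
  tk <- tryCatch(stats::TukeyHSD(fit, conf.level = 0.95)$grp,
                 error = function(e) NULL)
  levs <- levels(grp)
  pairs <- t(utils::combn(levs, 2))
  pairwise <- data.frame(
    group1 = pairs[, 1], group2 = pairs[, 2],
    diff = NA_real_, p_adj = NA_real_, significant = NA
  )
  gm <- tapply(x, grp, mean)
  for (i in seq_len(nrow(pairwise))) {
    key <- paste(pairwise$group2[i], pairwise$group1[i], sep = "-")
    pairwise$diff[i] <- unname(gm[pairwise$group2[i]] - gm[pairwise$group1[i]])
    if (!is.null(tk) && key %in% rownames(tk) && is.finite(tk[key, "p adj"])) {
      pairwise$p_adj[i] <- tk[key, "p adj"]
    } else if (is.infinite(fStat)) {
      ## degenerate zero-within-variance case: any mean difference is exact
      pairwise$p_adj[i] <- if (pairwise$diff[i] != 0) 0 else 1
    }
    pairwise$significant[i] <- is.finite(pairwise$p_adj[i]) && pairwise$p_adj[i] < 0.05
  }
  ## boxplot summaries, type-7 quantiles, 1.5 IQR outlier rule
  groups <- do.call(rbind, lapply(levs, function(l) {
    v <- x[grp == l]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    inliers <- v[v >= lo & v <= hi]
    data.frame(decade = l, n = length(v), mean = mean(v),
               min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
               whisker_low = min(inliers), whisker_high = max(inliers),
               n_outliers = sum(v < lo | v > hi))
  }))
  outliers <- do.call(rbind, lapply(levs, function(l) {
    v <- x[grp == l]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr]
    if (length(out)) data.frame(decade = l, value = out) else NULL
  }))
  if (is.null(outliers)) outliers <- data.frame(decade = character(), value = numeric())
  new("AnovaResult", groups = groups, fStatistic = fStat, pValue = pVal,
      pairwise = pairwise, outliers = outliers)
}

#' Plot the cohort: age trajectory and decade boxplots
#'
#' Builds (and optionally writes) the two cohort figures: the age-index
#' scatter with the all-ages linear fit (red), the over-40 subgroup fit
#' (green), the quadratic fit (blue), each with its 95\% confidence band;
#' and the decade boxplot with outliers as open circles. The numeric curve
#' data behind the lines and bands are returned so plots are testable
#' without image comparison.
#'
#' @param table cohort table.
#' @param linear,subgroup,quadratic \linkS4class{RegressionResult} objects;
#'   \code{subgroup} may be \code{NULL} (e.g. no subjects over the age
#'   cutoff), in which case the line is omitted with a message.
#' @param anova optional \linkS4class{AnovaResult} for the boxplot panel.
#' @param outDir if non-NULL, writes \code{age_trajectory.png} and
#'   \code{decade_boxplot.png} there.
#' @return Invisibly, list with ggplot objects \code{scatter}, \code{box}
#'   and \code{plotData} (per-fit band data.frames and boxplot summaries).
#' @export
plotCohort <- function(table, linear, subgroup = NULL, quadratic = NULL,
                       anova = NULL, outDir = NULL) {
  assertCohortTable(table)
  if (!"decade" %in% names(table)) table$decade <- decadeOf(table$age)
  bands <- list(linear = linear@band)
  cols <- c(linear = "red")
  if (!is.null(subgroup)) {
    bands$subgroup <- subgroup@band
    cols["subgroup"] <- "darkgreen"
  } else {
    message("subgroup fit unavailable; omitting its regression line")
  }
  if (!is.null(quadratic)) {
    bands$quadratic <- quadratic@band
    cols["quadratic"] <- "blue"
  }
  age <- index <- fit <- lwr <- upr <- decade <- NULL # NSE bindings
  p1 <- ggplot2::ggplot(table, ggplot2::aes(x = age, y = index)) +
    ggplot2::geom_point(shape = 1)
  for (nm in names(bands)) {
    p1 <- p1 +
      ggplot2::geom_ribbon(data = bands[[nm]],
        ggplot2::aes(x = age, ymin = lwr, ymax = upr), inherit.aes = FALSE,
        fill = "grey70", alpha = 0.4) +
      ggplot2::geom_line(data = bands[[nm]],
        ggplot2::aes(x = age, y = fit), inherit.aes = FALSE,
        color = cols[[nm]], linewidth = 0.8)
  }
  p1 <- p1 + ggplot2::labs(x = "Age (years)", y = "ALPS index") +
    ggplot2::theme_classic()
  p2 <- ggplot2::ggplot(table, ggplot2::aes(x = decade, y = index)) +
    ggplot2::geom_boxplot(outlier.shape = 1, coef = 1.5) +
    ggplot2::labs(x = "Age group", y = "ALPS index") +
    ggplot2::theme_classic()
  plotData <- list(bands = bands,
                   box = if (!is.null(anova)) anova@groups else NULL)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    ggplot2::ggsave(file.path(outDir, "age_trajectory.png"), p1,
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(outDir, "decade_boxplot.png"), p2,
                    width = 6, height = 4, dpi = 150)
  }
  invisible(list(scatter = p1, box = p2, plotData = plotData))
}
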