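#' @include social-metrics.R
NULL

#' Correlation-matrix PCA of a behavioral-test battery
#'
#' Columns are z-scored internally, so the decomposition is of the
#' correlation matrix. Components are ordered by descending eigenvalue and
#' each component's sign is oriented so that its largest-magnitude loading is
#' positive. Loadings are unit-norm eigenvectors (the \code{prcomp} rotation
#' convention); proportion of variance is eigenvalue over total across all
#' components, so the proportions sum to one.
#'
#' @param table subjects x items numeric table (data.frame or matrix)
#' @param nKeep components retained for interpretation (salience assignment,
#'   scores used downstream); the Kaiser count is reported alongside so the
#'   caller can override either way
#' @param cutoff salient-loading cutoff forwarded to [salientAssignment()]
#' @return a \linkS4class{PCAResult}
#' @export
pcaBattery <- function(table, nKeep = 4L, cutoff = 0.4) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("battery table must be numeric")
  if (nrow(m) < nKeep + 1L)
    stop("PCA needs at least nKeep + 1 subjects (got ", nrow(m), ")")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  loadings <- p$rotation
  scores <- p$x
  # sign orientation: largest-|loading| item positive, per component
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  nKeep <- as.integer(min(nKeep, ncol(loadings)))
  sal <- salientAssignment(loadings[, seq_len(nKeep), drop = FALSE],
                           cutoff = cutoff)
  methods::new("PCAResult", loadings = loadings, eigenvalues = ev,
               proportionOfVariance = ev / sum(ev), scores = scores,
               salience = sal, nKeep = nKeep,
               scaling = "unit-norm eigenvectors of the correlation matrix")
}

setMethod("show", "PCAResult", function(object) {
  cat(sprintf("PCAResult: %d items, %d subjects, %d components kept\n",
              nrow(object@loadings), nrow(object@scores), object@nKeep))
  pv <- object@proportionOfVariance[seq_len(object@nKeep)]
  cat(sprintf("  proportion of variance: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.3f", pv), collapse = " "),
              100 * sum(pv)))
  cat(sprintf("  Kaiser count (eigenvalue > 1): %d\n",
              kaiserCount(object@eigenvalues)))
  assigned <- !is.na(object@salience$component)
  cat(sprintf("  salient items: %d of %d assigned\n",
              sum(assigned), nrow(object@salience)))
})

#' Assign items to components by salient loadings
#'
#' An item is salient on every component where its absolute loading meets the
#' cutoff. An item salient on several components is assigned to the one where
#' its absolute loading is largest; an item salient nowhere is unassigned
#' (NA). The rule is two-sided: a loading of -0.56 is salient at cutoff 0.4.
#'
#' @param loadings items x components matrix
#' @param cutoff salience cutoff on the absolute loading
#' @return data.frame: item, component (integer or NA), loading (the loading
#'   on the assigned component)
#' @export
salientAssignment <- function(loadings, cutoff = 0.4) {
  loadings <- as.matrix(loadings)
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  items <- rownames(loadings)
  if (is.null(items)) items <- paste0("item", seq_len(nrow(loadings)))
  comp <- rep(NA_integer_, nrow(loadings))
  val <- rep(NA_real_, nrow(loadings))
  for (i in seq_len(nrow(loadings))) {
    sal <- which(abs(loadings[i, ]) >= cutoff)
    if (length(sal)) {
      j <- sal[which.max(abs(loadings[i, sal]))]
      comp[i] <- j
      val[i] <- loadings[i, j]
    }
  }
  data.frame(item = items, component = comp, loading = val,
             stringsAsFactors = FALSE)
}

#' Kaiser criterion component count
#'
#' The number of correlation-matrix eigenvalues strictly greater than one.
#'
#' @param eigenvalues eigenvalues of a correlation-matrix PCA
#' @return integer count
#' @export
kaiserCount <- function(eigenvalues) sum(eigenvalues > 1)

#' Cumulative variance of selected components, in percent
#'
#' @param proportions per-component proportions of variance
#' @param components which components to sum (default the first four)
#' @return percent, e.g. 75.3
#' @export
cumulativeVariance <- function(proportions, components = 1:4) {
  100 * sum(proportions[components])
}

#' ICC(3,k): two-way mixed, consistency, average measures
#'
#' Computed from the two-way ANOVA without interaction as
#' \code{(BMS - EMS) / BMS}, where BMS is the between-subject mean square and
#' EMS the residual mean square. Occasions (columns) containing any missing
#' value are dropped and k adjusted. Negative estimates are reported as
#' computed and classified "low"; a zero BMS yields an undefined (NA)
#' estimate, also classified "low". Classification: substantial above 0.7,
#' moderate in \[0.4, 0.7\], low otherwise.
#'
#' @param m subjects x occasions numeric matrix
#' @return an \linkS4class{ICCResult}
#' @export
icc3k <- function(m) {
  m <- as.matrix(m)
  keep <- colSums(is.na(m)) == 0L
  m <- m[, keep, drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("ICC needs at least 2 subjects")
  if (k < 2L) stop("ICC needs at least 2 complete occasions")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  bms <- ssr / (n - 1)
  ems <- sse / ((n - 1) * (k - 1))
  value <- if (bms <= 0) NA_real_ else (bms - ems) / bms
  methods::new("ICCResult", value = value, k = as.integer(k),
               n = as.integer(n), consistency = iccClass(value),
               bms = bms, ems = ems)
}

#' Consistency class of an ICC value
#'
#' @param value ICC estimate (NA allowed)
#' @return "substantial" (> 0.7), "moderate" (0.4--0.7) or "low"
#' @export
iccClass <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return("low")
    if (v > 0.7) "substantial"
    else if (v >= 0.4) "moderate"
    else "low"
  }, "")
}

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC(3,k): %s  (n = %d subjects, k = %d occasions) -> %s\n",
              ifelse(is.na(object@value), "undefined",
                     sprintf("%.3f", object@value)),
              object@n, object@k, object@consistency))
})

#' Likelihood-ratio test of familiarity in a random-intercept model
#'
#' Fits, by maximum likelihood, a Gaussian random-intercept model of
#' proximity on familiarity with a subject random effect, and the null model
#' without familiarity; the LRT statistic is twice the log-likelihood
#' difference, referred to a chi-square with one degree of freedom. A
#' familiarity column with no variation yields the degenerate chi2 = 0,
#' p = 1. Convergence problems are reported, never silently swallowed.
#'
#' @param data data.frame with one row per (subject, partner) pair
#' @param response,familiarity,subject column names
#' @return list: chi2, df, p, converged, messages
#' @export
lmmFamiliarityLrt <- function(data, response = "proximity",
                              familiarity = "familiar",
                              subject = "subject") {
  stopifnot(all(c(response, familiarity, subject) %in% names(data)))
  tab <- table(data[[subject]])
  if (any(tab < 2L))
    stop("every subject needs at least 2 partner rows")
  if (length(unique(data[[familiarity]])) < 2L)
    return(list(chi2 = 0, df = 1L, p = 1, converged = TRUE,
                messages = "familiarity constant; degenerate predictor"))
  msgs <- character(0)
  fit <- function(fml) {
    withCallingHandlers(
      lme4::lmer(fml, data = data, REML = FALSE),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {  # e.g. boundary (singular) fit notes
        msgs <<- c(msgs, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  full <- fit(as.formula(sprintf("%s ~ %s + (1 | %s)",
                                 response, familiarity, subject)))
  null <- fit(as.formula(sprintf("%s ~ 1 + (1 | %s)", response, subject)))
  chi2 <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
  if (chi2 < 0 && chi2 > -1e-6) chi2 <- 0  # optimizer noise on a nested fit
  conv <- !any(grepl("failed to converge", msgs, fixed = TRUE))
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1L, lower.tail = FALSE),
       converged = conv, messages = if (length(msgs)) msgs else NULL)
}

# Fisher-z confidence interval for a Pearson correlation.
fisherCI <- function(r, n, level = 0.95) {
  if (is.na(r) || n < 4 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Correlation panel between component scores and social indices
#'
#' Pearson correlations of every (component, index) pair over paired complete
#' observations, with Fisher-z 95% confidence intervals. Cells with
#' |r| >= \code{cutoff} are flagged as moderate-to-high. Components named in
#' \code{invert} have their displayed values sign-inverted (display only —
#' the \code{r} column is untouched), the convention used for an activity
#' axis whose raw loadings point "less active".
#'
#' @param pcScores subjects x components matrix (columns named PC1, ...)
#' @param indexTable subjects x indices data.frame, same row order
#' @param cutoff flag threshold on |r|
#' @param invert character, components to sign-invert for display
#' @param level confidence level
#' @return data.frame: component, index, n, r, ci_lo, ci_hi, flagged,
#'   display_r, display_lo, display_hi
#' @export
correlationPanel <- function(pcScores, indexTable, cutoff = 0.4,
                             invert = "PC3", level = 0.95) {
  pcScores <- as.matrix(pcScores)
  stopifnot(nrow(pcScores) == nrow(indexTable))
  comps <- colnames(pcScores)
  if (is.null(comps)) comps <- paste0("PC", seq_len(ncol(pcScores)))
  rows <- list()
  for (j in seq_along(comps)) {
    for (idx in names(indexTable)) {
      xv <- pcScores[, j]; yv <- indexTable[[idx]]
      ok <- complete.cases(xv, yv)
      n <- sum(ok)
      if (n < 4L) {
        r <- NA_real_
      } else if (sd(xv[ok]) == 0 || sd(yv[ok]) == 0) {
        warning("zero-variance column in (", comps[j], ", ", idx,
                "); correlation undefined")
        r <- NA_real_
      } else r <- cor(xv[ok], yv[ok])
      ci <- fisherCI(r, n, level)
      sgn <- if (comps[j] %in% invert) -1 else 1
      rows[[length(rows) + 1L]] <- data.frame(
        component = comps[j], index = idx, n = n, r = r,
        ci_lo = ci[1], ci_hi = ci[2],
        flagged = !is.na(r) & abs(r) >= cutoff,
        display_r = sgn * r,
        display_lo = if (sgn == 1) ci[1] else -ci[2],
        display_hi = if (sgn == 1) ci[2] else -ci[1],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Trait-similarity versus dyadic proximity
#'
#' For each retained component, the Pearson correlation between the absolute
#' difference of the two dyad members' component scores (trait similarity;
#' smaller = more similar) and the dyad's standardized proximity time.
#'
#' @param pcScores subjects x components matrix with subject rownames
#' @param dyadProx data.frame: a, b (subject ids), proximity
#' @param invert components sign-inverted for display (display only; the
#'   absolute difference is unaffected by sign, so this only flips nothing —
#'   kept for table symmetry with [correlationPanel()])
#' @return data.frame: component, n_dyads, r, ci_lo, ci_hi, flagged
#' @export
similarityAnalysis <- function(pcScores, dyadProx, invert = "PC3") {
  pcScores <- as.matrix(pcScores)
  if (nrow(dyadProx) < 4L) stop("similarity analysis needs at least 4 dyads")
  comps <- colnames(pcScores)
  if (is.null(comps)) comps <- paste0("PC", seq_len(ncol(pcScores)))
  rows <- lapply(seq_along(comps), function(j) {
    d <- abs(pcScores[dyadProx$a, j] - pcScores[dyadProx$b, j])
    ok <- complete.cases(d, dyadProx$proximity)
    r <- if (sum(ok) < 4L || sd(d[ok]) == 0 || sd(dyadProx$proximity[ok]) == 0) {
      if (sum(ok) >= 4L) warning("zero-variance similarity for ", comps[j])
      NA_real_
    } else cor(d[ok], dyadProx$proximity[ok])
    ci <- fisherCI(r, sum(ok))
    data.frame(component = comps[j], n_dyads = sum(ok), r = r,
               ci_lo = ci[1], ci_hi = ci[2],
               flagged = !is.na(r) & abs(r) >= 0.4,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
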