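#' Plant-by-fungus BLUP matrix for heat-map style summaries
#'
#' Maps the BLUPs of a plant-by-fungus interaction random effect onto a
#' matrix over realized (plant, fungus) combinations, on the LRR scale and
#' as percent-scale deviations from the overall mean response. Cells for
#' combinations never observed are absent (\code{NA}), not zero. Marginal
#' means per plant and per fungus are computed across realized cells only
#' (the "bars" flanking a paired-phylogeny heat map); the matrices plus the
#' level orders are emitted as data so any plotting layer can consume them.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param term Name of a plant-by-fungus interaction term of the fit (its
#'   levels must be \code{"plant:fungus"} labels).
#' @return List of class \code{"blup_matrix"}: \code{lrr} (plants x fungi
#'   matrix of BLUPs), \code{percent_deviation} (deviation of the cell's
#'   percent response from the overall percent mean), \code{plant_marginal}
#'   and \code{fungus_marginal} (LRR-scale means over realized cells),
#'   \code{overall_percent}, \code{overall_se_percent}, \code{n_realized}.
#' @export
blup_matrix <- function(fit, term) {
  stopifnot(inherits(fit, "meta_fit"))
  if (!term %in% names(fit$sigma2))
    stop("unknown term '", term, "'", call. = FALSE)
  b <- meta_blups(fit, terms = term)
  parts <- strsplit(b$level, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("term '", term, "' does not have plant:fungus levels", call. = FALSE)
  plant <- vapply(parts, `[`, "", 1L)
  fungus <- vapply(parts, `[`, "", 2L)
  plants <- sort(unique(plant))
  fungi <- sort(unique(fungus))
  M <- matrix(NA_real_, length(plants), length(fungi),
              dimnames = list(plants, fungi))
  M[cbind(plant, fungus)] <- b$blup
  mu <- if ("(Intercept)" %in% names(fit$beta))
    unname(fit$beta["(Intercept)"]) else 0
  overall_pct <- percent_change(mu)
  pct_dev <- percent_change(mu + M) - overall_pct
  se_mu <- sqrt(fit$vcov_beta[1, 1])
  out <- list(lrr = M,
              percent_deviation = pct_dev,
              plant_marginal = rowMeans(M, na.rm = TRUE),
              fungus_marginal = colMeans(M, na.rm = TRUE),
              plant_marginal_percent = rowMeans(pct_dev, na.rm = TRUE),
              fungus_marginal_percent = colMeans(pct_dev, na.rm = TRUE),
              overall_percent = overall_pct,
              overall_se_percent = 100 * exp(mu) * se_mu,
              n_realized = sum(!is.na(M)),
              term = term)
  class(out) <- "blup_matrix"
  out
}

#' @export
print.blup_matrix <- function(x, digits = 3, ...) {
  cat("BLUP matrix for '", x$term, "': ", nrow(x$lrr), " plants x ",
      ncol(x$lrr), " fungi, ", x$n_realized, " realized combination(s)\n",
      sep = "")
  cat("overall mean response: ",
      formatC(x$overall_percent, digits = digits, format = "f"), "% ± ",
      formatC(x$overall_se_percent, digits = digits, format = "f"),
      " SE\n", sep = "")
  invisible(x)
}

#' Model-based marginal means for a fixed-effect predictor
#'
#' For each level of the focal predictor, averages the fitted fixed-effect
#' value over the observed distribution of the remaining predictors
#' (observed-proportion weighting by default; equal-weighting of the
#' non-focal design rows is available), with standard errors from the
#' fixed-effect covariance. Also returns covariate-adjusted observations:
#' each effect size minus the fitted contribution of all non-focal fixed
#' terms (re-centred at the mean non-focal contribution), the form in which
#' raw data are displayed alongside marginal means.
#'
#' @param fit A \code{\link{fit_meta_model}} object whose fixed formula
#'   contains \code{predictor}.
#' @param predictor Name of a (categorical) fixed-effect column.
#' @param weighting \code{"observed"} (default) or \code{"equal"} weighting
#'   over non-focal factor combinations.
#' @return List of class \code{"marginal_means"}: \code{means} (data frame
#'   with level, lrr mean, SE, percent labels) and \code{adjusted} (data
#'   frame with level and adjusted LRR per observation).
#' @export
marginal_means <- function(fit, predictor,
                           weighting = c("observed", "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(fit, "meta_fit"))
  dat <- fit$effects
  if (!predictor %in% names(dat))
    stop("predictor '", predictor, "' not found in the data", call. = FALSE)
  lev <- sort(unique(as.character(dat[[predictor]])))
  base <- dat
  if (weighting == "equal") {
    others <- setdiff(all.vars(fit$fixed), predictor)
    if (length(others)) {
      combos <- unique(base[others])
      base <- base[match(do.call(paste, combos),
                         do.call(paste, base[others])), , drop = FALSE]
    }
  }
  means <- do.call(rbind, lapply(lev, function(L) {
    d2 <- base
    d2[[predictor]] <- factor(L, levels = lev)
    Xl <- model.matrix(fit$fixed, d2)
    a <- colMeans(Xl)[names(fit$beta)]
    est <- sum(a * fit$beta)
    se <- sqrt(drop(t(a) %*% fit$vcov_beta %*% a))
    data.frame(level = L, lrr = est, se = se,
               percent = percent_change(est),
               percent_se = 100 * exp(est) * se)
  }))
  # adjusted observations: subtract the non-focal fixed contribution,
  # keeping the intercept and re-centring so location is preserved
  X <- model.matrix(fit$fixed, dat)
  focal_cols <- grepl(predictor, colnames(X), fixed = TRUE)
  focal_cols[colnames(X) == "(Intercept)"] <- TRUE
  other_contrib <- drop(X[, !focal_cols, drop = FALSE] %*%
                          fit$beta[!focal_cols])
  adjusted <- data.frame(level = as.character(dat[[predictor]]),
                         lrr_adjusted = fit$effects$lrr - other_contrib +
                           mean(other_contrib))
  out <- list(means = means, adjusted = adjusted, predictor = predictor,
              weighting = weighting)
  class(out) <- "marginal_means"
  out
}

#' @export
print.marginal_means <- function(x, digits = 3, ...) {
  cat("Marginal means for '", x$predictor, "' (", x$weighting,
      " weighting over non-focal effects):\n", sep = "")
  m <- x$means
  m[-1] <- lapply(m[-1], round, digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Funnel-plot data (effect size vs precision)
#'
#' Per-observation export for publication-bias inspection: effect size,
#' standard error and precision, with imputed-variance rows flagged. No
#' automated bias statistic is computed; funnel plots are judged visually.
#'
#' @param effects Effect-size table from \code{\link{compute_effect_sizes}}.
#' @return Data frame with columns \code{study_id}, \code{lrr}, \code{se},
#'   \code{precision}, \code{variance_imputed}.
#' @export
funnel_data <- function(effects) {
  effects <- as.data.frame(effects)
  data.frame(study_id = effects$study_id,
             lrr = effects$lrr,
             se = sqrt(effects$variance),
             precision = 1 / sqrt(effects$variance),
             variance_imputed = effects$variance_imputed)
}

#' Variance-component summary table
#'
#' One row per random effect of the fit with its estimate, optional
#' profile-likelihood confidence interval, and partial conditional
#' R-squared. Following the convention of highlighting components that
#' matter, \code{notable} flags terms accounting for more than 5% of
#' between-studies variance; partial R-squared is reported for those terms.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param ci Compute profile-likelihood CIs (can be slow for large fits).
#' @param level Confidence level.
#' @param share_threshold Partial-R2 share above which a term is flagged
#'   (default 0.05).
#' @return Data frame of class \code{"variance_table"}.
#' @export
variance_table <- function(fit, ci = TRUE, level = 0.95,
                           share_threshold = 0.05) {
  r2 <- r2_summaries(fit)
  out <- data.frame(term = names(fit$sigma2),
                    estimate = unname(fit$sigma2),
                    row.names = NULL)
  if (ci) {
    cis <- profile_cis(fit, level = level)
    out$ci_lower <- cis[, "lower"]
    out$ci_upper <- cis[, "upper"]
  }
  out$partial_r2 <- unname(r2$partial_r2[out$term])
  out$notable <- out$partial_r2 > share_threshold
  attr(out, "marginal_r2") <- r2$marginal_r2
  attr(out, "sigma2_fixed") <- r2$sigma2_fixed
  class(out) <- c("variance_table", "data.frame")
  out
}

#' Write a structured plain-text summary of a fitted model
#'
#' Key/value header (mode, n, log-likelihood, convergence, R-squared)
#' followed by aligned coefficient and variance-component tables; a
#' human-readable companion to \code{\link{write_fit_report}}.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param path Output path.
#' @export
write_fit_summary <- function(fit, path) {
  r2 <- r2_summaries(fit)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  kv <- c(mode = fit$mode, n = fit$n, loglik = format(fit$loglik),
          converged = fit$converged,
          marginal_r2 = format(r2$marginal_r2),
          sigma2_fixed = format(r2$sigma2_fixed))
  writeLines(paste(names(kv), kv, sep = ": "), con)
  writeLines("", con)
  writeLines("[fixed_effects]", con)
  fe <- data.frame(term = names(fit$beta), estimate = unname(fit$beta),
                   se = sqrt(diag(fit$vcov_beta)))
  writeLines(utils::capture.output(print(fe, row.names = FALSE)), con)
  writeLines("", con)
  writeLines("[variance_components]", con)
  vc <- data.frame(term = names(fit$sigma2),
                   estimate = unname(fit$sigma2),
                   partial_r2 = unname(r2$partial_r2[names(fit$sigma2)]))
  writeLines(utils::capture.output(print(vc, row.names = FALSE)), con)
  invisible(path)
}

#' Write a machine-readable JSON report of a fitted model
#'
#' Serializes coefficients, variance components, R-squared summaries and
#' convergence information; BLUP tables can be exported alongside with
#' \code{\link{write_blups}}.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param path Output path for the JSON report.
#' @export
write_fit_report <- function(fit, path) {
  r2 <- r2_summaries(fit)
  rep <- list(mode = fit$mode, n = fit$n, loglik = fit$loglik,
              converged = fit$converged,
              fixed = as.list(fit$beta),
              fixed_se = as.list(sqrt(diag(fit$vcov_beta))),
              sigma2 = as.list(fit$sigma2),
              marginal_r2 = r2$marginal_r2,
              partial_r2 = as.list(r2$partial_r2))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_report
#' @param terms Terms whose BLUPs to export (default: all but study_id).
#' @export
write_blups <- function(fit, path, terms = NULL) {
  b <- meta_blups(fit, terms = terms)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(b, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
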