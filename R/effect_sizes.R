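#' Log response ratio of inoculated vs control means
#'
#' The effect-size metric used throughout the package: the natural log of the
#' ratio of mean plant biomass in the inoculated treatment to mean biomass in
#' the non-inoculated control. Positive values indicate growth promotion by
#' the fungal symbiont, negative values growth depression.
#'
#' @param mean_inoc Numeric vector of inoculated-group means (must be > 0).
#' @param mean_ctrl Numeric vector of control-group means (must be > 0).
#' @return Numeric vector \code{log(mean_inoc / mean_ctrl)}.
#' @examples
#' compute_lrr(2, 1)   # log(2)
#' compute_lrr(1, 2)   # -log(2)
#' @export
compute_lrr <- function(mean_inoc, mean_ctrl) {
  .check_positive(mean_inoc, "mean_inoc")
  .check_positive(mean_ctrl, "mean_ctrl")
  log(mean_inoc / mean_ctrl)
}

#' Sampling variance of a log response ratio
#'
#' Large-sample variance of the log response ratio from group standard
#' deviations, replicate counts and means:
#' \deqn{\hat\sigma^2 = SD_{inoc}^2 / (n_{inoc}\,\bar x_{inoc}^2) +
#'       SD_{ctrl}^2 / (n_{ctrl}\,\bar x_{ctrl}^2).}
#' Equivalently, \code{CV_inoc^2 / n_inoc + CV_ctrl^2 / n_ctrl}, which is the
#' form used when a missing SD is imputed from a median coefficient of
#' variation (see \code{\link{impute_variances}}).
#'
#' Rows with a missing (\code{NA}) SD return \code{NA}: that is the signal
#' that the row needs imputation, distinct from invalid input (negative SD,
#' zero replicate count, non-positive mean), which errors.
#'
#' @param sd_inoc,sd_ctrl Group standard deviations (\code{NA} allowed).
#' @param n_inoc,n_ctrl Replicate counts (integers >= 1).
#' @param mean_inoc,mean_ctrl Group means (> 0).
#' @return Numeric vector of sampling variances (\code{NA} where an SD is
#'   missing).
#' @examples
#' lrr_sampling_variance(1, 4, 2, 1, 4, 1)  # 1/16 + 1/4 = 0.3125
#' @export
lrr_sampling_variance <- function(sd_inoc, n_inoc, mean_inoc,
                                  sd_ctrl, n_ctrl, mean_ctrl) {
  .check_positive(mean_inoc, "mean_inoc")
  .check_positive(mean_ctrl, "mean_ctrl")
  .check_counts(n_inoc, "n_inoc")
  .check_counts(n_ctrl, "n_ctrl")
  .check_sd(sd_inoc, "sd_inoc")
  .check_sd(sd_ctrl, "sd_ctrl")
  sd_inoc^2 / (n_inoc * mean_inoc^2) + sd_ctrl^2 / (n_ctrl * mean_ctrl^2)
}

#' Percent growth response from a log response ratio
#'
#' Transforms effect sizes to the percent change in plant biomass caused by
#' inoculation, \code{100 * (exp(lrr) - 1)}. \code{lrr_from_percent} is the
#' exact inverse, used when reading percent-scale summaries back onto the
#' modelling scale.
#'
#' @param lrr Numeric vector of log response ratios.
#' @param percent Numeric vector of percent changes (> -100).
#' @return Numeric vector.
#' @examples
#' percent_change(log(2))        # 100
#' lrr_from_percent(62)          # ~0.482
#' @export
percent_change <- function(lrr) 100 * (exp(lrr) - 1)

#' @rdname percent_change
#' @export
lrr_from_percent <- function(percent) {
  if (any(percent <= -100, na.rm = TRUE))
    stop("percent change must be > -100", call. = FALSE)
  log(percent / 100 + 1)
}

#' Compute effect sizes (with variance imputation) from trial records
#'
#' Turns a table of inoculation trials (one row per effect size: group means,
#' SDs, replicate counts and grouping labels) into a table of log response
#' ratios and sampling variances. Rows lacking an SD get their missing
#' coefficient of variation replaced by the median CV among rows of the same
#' dataset that did report SDs; such rows are flagged
#' \code{variance_imputed = TRUE}. Imputation is always performed within the
#' supplied table, so call this separately on each analysis subset (AM-full,
#' AM-sub, EM) after \code{\link{partition_datasets}}.
#'
#' Variances are floored at \code{var_floor} (a reported SD of exactly zero
#' would otherwise give an infinite meta-analytic weight); flooring triggers
#' a warning.
#'
#' @param trials Data frame of trial records. Required columns:
#'   \code{study_id}, \code{paper_id}, \code{control_set_id},
#'   \code{plant_species}, \code{mean_inoc}, \code{mean_ctrl},
#'   \code{n_inoc}, \code{n_ctrl}. Optional: \code{sd_inoc}, \code{sd_ctrl}
#'   (\code{NA} = not reported), \code{fungal_genus}, \code{plant_origin},
#'   \code{fungal_origin}, plus any covariate columns, all carried through.
#' @param cv_pooling How the median CV is formed: \code{"pooled"} (default)
#'   pools inoculated and control CVs into one vector before taking the
#'   median; \code{"per_group"} takes separate medians for each group.
#' @param var_floor Lower bound applied to computed variances.
#' @return A data frame of class \code{"myco_effects"} with columns
#'   \code{lrr}, \code{variance}, \code{variance_imputed} prepended to all
#'   input grouping/covariate columns.
#' @seealso \code{\link{impute_variances}}, \code{\link{partition_datasets}}
#' @export
compute_effect_sizes <- function(trials,
                                 cv_pooling = c("pooled", "per_group"),
                                 var_floor = 1e-8) {
  cv_pooling <- match.arg(cv_pooling)
  trials <- as.data.frame(trials)
  req <- c("study_id", "paper_id", "control_set_id", "plant_species",
           "mean_inoc", "mean_ctrl", "n_inoc", "n_ctrl")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trials is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(trials$study_id))
    stop("study_id values must be unique within a dataset", call. = FALSE)
  if (is.null(trials$sd_inoc)) trials$sd_inoc <- NA_real_
  if (is.null(trials$sd_ctrl)) trials$sd_ctrl <- NA_real_

  lrr <- compute_lrr(trials$mean_inoc, trials$mean_ctrl)
  variance <- lrr_sampling_variance(trials$sd_inoc, trials$n_inoc,
                                    trials$mean_inoc,
                                    trials$sd_ctrl, trials$n_ctrl,
                                    trials$mean_ctrl)
  out <- cbind(data.frame(lrr = lrr, variance = variance,
                          variance_imputed = FALSE),
               trials[setdiff(names(trials), c("lrr", "variance",
                                               "variance_imputed"))])
  out <- impute_variances(out, cv_pooling = cv_pooling)
  low <- which(out$variance < var_floor)
  if (length(low)) {
    warning(length(low), " variance(s) below ", var_floor,
            " floored (zero or near-zero reported SDs)", call. = FALSE)
    out$variance[low] <- var_floor
  }
  class(out) <- c("myco_effects", "data.frame")
  out
}

#' Impute missing sampling variances from the median coefficient of variation
#'
#' For rows whose sampling variance could not be computed because an SD was
#' not reported, fills the missing group's CV with the median CV among rows
#' of the same table that did report SDs, then applies the usual variance
#' formula \code{CV_inoc^2/n_inoc + CV_ctrl^2/n_ctrl}. A row missing both
#' SDs gets the median CV on both sides; a row missing one SD keeps its
#' reported side. Rows already carrying a variance are untouched.
#'
#' @param effects Data frame with columns \code{variance},
#'   \code{variance_imputed}, \code{sd_inoc}, \code{sd_ctrl},
#'   \code{mean_inoc}, \code{mean_ctrl}, \code{n_inoc}, \code{n_ctrl}.
#' @inheritParams compute_effect_sizes
#' @return \code{effects} with missing variances filled in and
#'   \code{variance_imputed} set on those rows.
#' @export
impute_variances <- function(effects, cv_pooling = c("pooled", "per_group")) {
  cv_pooling <- match.arg(cv_pooling)
  need <- is.na(effects$variance)
  if (!any(need)) return(effects)
  cv_inoc <- effects$sd_inoc / effects$mean_inoc
  cv_ctrl <- effects$sd_ctrl / effects$mean_ctrl
  if (all(is.na(cv_inoc)) && all(is.na(cv_ctrl)))
    stop("cannot impute variances: no row in this dataset reports an SD",
         call. = FALSE)
  if (cv_pooling == "pooled") {
    m <- stats::median(c(cv_inoc, cv_ctrl), na.rm = TRUE)
    m_inoc <- m_ctrl <- m
  } else {
    m_inoc <- stats::median(cv_inoc, na.rm = TRUE)
    m_ctrl <- stats::median(cv_ctrl, na.rm = TRUE)
    if (is.na(m_inoc)) m_inoc <- m_ctrl
    if (is.na(m_ctrl)) m_ctrl <- m_inoc
  }
  cvi <- ifelse(is.na(cv_inoc), m_inoc, cv_inoc)
  cvc <- ifelse(is.na(cv_ctrl), m_ctrl, cv_ctrl)
  effects$variance[need] <-
    (cvi^2 / effects$n_inoc + cvc^2 / effects$n_ctrl)[need]
  effects$variance_imputed[need] <- TRUE
  effects
}

#' Partition trial records into the AM-full, AM-sub and EM analysis subsets
#'
#' Splits a combined trial table by mycorrhizal type and by whether the
#' inoculum involved a single fungal genus. \code{AM-full} contains all
#' arbuscular mycorrhizal rows (including multi-genus inocula);
#' \code{AM-sub} is its subset inoculated with a single AM fungal genus;
#' \code{EM} contains ectomycorrhizal rows with a single fungal genus.
#' Rows with mixed AM+EM inoculation, and multi-genus EM rows, are dropped
#' (a message reports the count).
#'
#' @param trials Data frame with a \code{myc_type} column (\code{"AM"},
#'   \code{"EM"} or \code{"AM+EM"}) and a \code{fungal_genus} column in
#'   which multi-genus inocula are encoded as labels joined by \code{"+"}
#'   (or \code{NA} when genera were not resolved; treated as multi-genus).
#' @return Named list \code{list(am_full, am_sub, em)} of data frames, with
#'   attribute \code{"n_dropped"} giving the number of discarded rows.
#' @export
partition_datasets <- function(trials) {
  trials <- as.data.frame(trials)
  if (is.null(trials$myc_type))
    stop("trials must carry a myc_type column (AM, EM or AM+EM)",
         call. = FALSE)
  if (nrow(trials) == 0) {
    out <- list(am_full = trials, am_sub = trials, em = trials)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  type <- as.character(trials$myc_type)
  known <- c("AM", "EM", "AM+EM")
  if (any(!type %in% known))
    stop("unknown mycorrhizal type label(s): ",
         paste(unique(setdiff(type, known)), collapse = ", "), call. = FALSE)
  genus <- if (is.null(trials$fungal_genus)) rep(NA_character_, nrow(trials))
           else as.character(trials$fungal_genus)
  single <- !is.na(genus) & !grepl("+", genus, fixed = TRUE)
  am_full <- trials[type == "AM", , drop = FALSE]
  am_sub  <- trials[type == "AM" & single, , drop = FALSE]
  em      <- trials[type == "EM" & single, , drop = FALSE]
  n_drop <- sum(type == "AM+EM") + sum(type == "EM" & !single)
  if (n_drop > 0)
    message(n_drop, " row(s) dropped (mixed AM+EM or multi-genus EM inocula)")
  out <- list(am_full = am_full, am_sub = am_sub, em = em)
  attr(out, "n_dropped") <- as.integer(n_drop)
  out
}

#' Read and write trial / effect-size tables
#'
#' Delimited-file I/O for the flat tables the pipeline consumes and emits.
#' The delimiter is inferred from the extension (\code{.tsv}/\code{.txt} =
#' tab, otherwise comma); files are UTF-8 with a header row. Unknown columns
#' are preserved untouched.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return \code{read_trials} returns a data frame.
#' @export
read_trials <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", check.names = FALSE)
}

#' @rdname read_trials
#' @export
write_effects <- function(x, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# -- input validation helpers -------------------------------------------------

.check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0))
    stop("invalid input: ", name, " must be strictly positive", call. = FALSE)
  invisible(x)
}

.check_counts <- function(x, name) {
  if (any(is.na(x) | x < 1 | x != round(x)))
    stop("invalid input: ", name, " must be an integer >= 1", call. = FALSE)
  invisible(x)
}

.check_sd <- function(x, name) {
  if (any(x[!is.na(x)] < 0))
    stop("invalid input: ", name, " must be >= 0 where reported",
         call. = FALSE)
  invisible(x)
}
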