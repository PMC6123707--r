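#' Enumerate candidate fixed-effect models under marginality
#'
#' Builds the candidate set for AICc model selection: every subset of the
#' main-effect predictors, each augmented with every subset of the declared
#' two-way interactions whose parent main effects are present (marginality).
#' With no interactions this is the power set of the predictors (e.g. the
#' six EM predictors give 64 models).
#'
#' @param predictors Character vector of main-effect names.
#' @param interactions List of length-2 character vectors, each naming the
#'   parents of an allowed two-way interaction.
#' @return List of character vectors of fixed terms (empty vector =
#'   intercept-only model), each with a \code{"model_id"} attribute.
#' @export
enumerate_candidates <- function(predictors, interactions = list()) {
  predictors <- unique(as.character(predictors))
  for (int in interactions) {
    if (length(int) != 2L || !all(int %in% predictors))
      stop("interaction ", paste(int, collapse = ":"),
           " references undeclared main effects", call. = FALSE)
  }
  m <- length(predictors)
  out <- list()
  for (bits in seq_len(2^m) - 1L) {
    mains <- predictors[bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0]
    ok_ints <- Filter(function(int) all(int %in% mains), interactions)
    ni <- length(ok_ints)
    for (ibits in seq_len(2^ni) - 1L) {
      ints <- ok_ints[bitwAnd(ibits, 2^(seq_len(max(ni, 1)) - 1L))[
        seq_len(ni)] > 0]
      terms <- c(mains, vapply(ints, paste, "", collapse = ":"))
      attr(terms, "model_id") <- if (length(terms))
        paste(sort(terms), collapse = "+") else "(Intercept)"
      out[[length(out) + 1L]] <- terms
    }
  }
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' \code{AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)}. Undefined (errors)
#' when \code{n <= k + 1}.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size (number of effect sizes).
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights and relative variable importance
#'
#' Given a candidate-model table with AICc values, computes
#' \code{delta_aicc}, normalized Akaike weights \code{w propto
#' exp(-delta/2)}, and the relative variable importance of each predictor:
#' the sum of the weights of all models containing it (a predictor
#' appearing only through an interaction counts as present).
#'
#' @param table Data frame with columns \code{model_id}, \code{terms}
#'   (list-column of character vectors), \code{k}, \code{loglik},
#'   \code{aicc}.
#' @param predictors Character vector of main-effect predictor names.
#' @return Object of class \code{"myco_selection"}: the table augmented
#'   with \code{delta_aicc} and \code{weight} (sorted by AICc, ties broken
#'   by fewer parameters then model id), plus \code{rvi},
#'   \code{best_model_id}, \code{n_within_2}.
#' @export
weights_and_rvi <- function(table, predictors) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  tab <- table
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  ord <- order(tab$aicc, tab$k, tab$model_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  contains <- function(p, terms)
    any(vapply(terms, function(t)
      p %in% strsplit(t, ":", fixed = TRUE)[[1]], logical(1)))
  rvi <- vapply(predictors, function(p)
    sum(tab$weight[vapply(tab$terms, function(tt) contains(p, tt),
                          logical(1))]), numeric(1))
  out <- list(table = tab, rvi = rvi,
              best_model_id = tab$model_id[1],
              best_terms = tab$terms[[1]],
              n_within_2 = sum(tab$delta_aicc <= 2))
  class(out) <- "myco_selection"
  out
}

#' AICc model selection over fixed-effect candidates
#'
#' Two-stage procedure: a saturated model (all predictors and interactions,
#' all random terms) is first fitted by REML; random terms whose estimated
#' component falls below \code{gate} are dropped from the selection-stage
#' random structure (\code{study_id} is always retained). Every candidate
#' fixed-effect model is then fitted in the requested mode with that
#' identical random structure and ranked by AICc; Akaike weights and
#' per-predictor relative variable importance are computed from the table.
#'
#' ML is the default mode. REML comparison across different fixed-effect
#' structures is statistically non-standard; it is supported because
#' practitioners use it as a sensitivity check, and selecting it emits a
#' one-time caveat message.
#'
#' @inheritParams fit_meta_model
#' @param predictors Character vector of main-effect column names in
#'   \code{effects}.
#' @param interactions List of length-2 character vectors (see
#'   \code{\link{enumerate_candidates}}).
#' @param mode \code{"ML"} (default) or \code{"REML"}.
#' @param gate Variance threshold below which a random term estimated in
#'   the saturated fit is dropped (default 1e-6).
#' @param k_style Parameter count for AICc: \code{"all"} (fixed
#'   coefficients + free variance components, default) or
#'   \code{"fixed_only"}.
#' @param max_fail_frac Abort if more than this fraction of candidates
#'   fails to converge (default 0.1).
#' @return A \code{"myco_selection"} object (see
#'   \code{\link{weights_and_rvi}}) with extra elements
#'   \code{random_terms}, \code{mode}, \code{n_failed} and
#'   \code{saturated_sigma2}.
#' @export
select_fixed_effects <- function(effects, structures, predictors,
                                 interactions = list(),
                                 mode = c("ML", "REML"), gate = 1e-6,
                                 k_style = c("all", "fixed_only"),
                                 max_fail_frac = 0.1, control = list()) {
  mode <- match.arg(mode)
  k_style <- match.arg(k_style)
  if (mode == "REML")
    message("note: REML comparison of models with different fixed effects ",
            "is non-standard; interpret AICc differences with caution")
  sat_terms <- c(predictors,
                 vapply(interactions, paste, "", collapse = ":"))
  sat_fixed <- if (length(sat_terms))
    stats::reformulate(sat_terms) else ~1
  sat <- fit_meta_model(effects, structures, fixed = sat_fixed,
                        mode = "REML", control = control)
  keep <- names(sat$sigma2)[sat$sigma2 >= gate]
  keep <- union(keep, "study_id")
  keep <- intersect(names(structures), keep)  # preserve original order
  cands <- enumerate_candidates(predictors, interactions)
  n <- nrow(effects)
  rows <- vector("list", length(cands))
  n_failed <- 0L
  for (i in seq_along(cands)) {
    terms <- cands[[i]]
    fml <- if (length(terms)) stats::reformulate(terms) else ~1
    fit <- tryCatch(
      fit_meta_model(effects, structures, fixed = fml, mode = mode,
                     random_terms = keep, control = control),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      warning("candidate '", attr(terms, "model_id"),
              "' failed to converge; excluded", call. = FALSE)
      next
    }
    k <- if (k_style == "all") fit$p + fit$k_varcomp else fit$p
    rows[[i]] <- data.frame(model_id = attr(terms, "model_id"),
                            k = k, loglik = fit$loglik,
                            aicc = aicc(fit$loglik, k, n))
    rows[[i]]$terms <- list(as.character(terms))
  }
  if (n_failed > max_fail_frac * length(cands))
    stop("more than ", 100 * max_fail_frac,
         "% of candidate models failed to converge; aborting selection",
         call. = FALSE)
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- weights_and_rvi(tab, predictors)
  out$random_terms <- keep
  out$mode <- mode
  out$n_failed <- n_failed
  out$saturated_sigma2 <- sat$sigma2
  out
}

#' @export
print.myco_selection <- function(x, digits = 3, max_rows = 10, ...) {
  cat("AICc model selection", if (!is.null(x$mode))
    paste0(" (", x$mode, ")"), ": ", nrow(x$table), " candidate model(s)\n",
    sep = "")
  cat("best model: ", x$best_model_id, "  (", x$n_within_2,
      " model(s) within 2 AICc units)\n\n", sep = "")
  show <- utils::head(x$table[c("model_id", "k", "loglik", "aicc",
                                "delta_aicc", "weight")], max_rows)
  show[-1] <- lapply(show[-1], round, digits)
  print(show)
  cat("\nRelative variable importance:\n")
  print(round(sort(x$rvi, decreasing = TRUE), digits))
  invisible(x)
}

#' Export a selection table to a delimited file
#'
#' @param x A \code{"myco_selection"} object.
#' @param path Output path (.tsv/.txt = tab, else comma).
#' @export
write_selection <- function(x, path) {
  tab <- x$table
  tab$terms <- vapply(tab$terms, paste, "", collapse = "+")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
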