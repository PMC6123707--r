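#' @importFrom stats model.matrix optim qchisq uniroot setNames median var
#'   rnorm runif rpois rlnorm cutree hclust as.dist qnorm
NULL

# Cholesky factor (lower) of a PSD correlation matrix, allowing at most
# 1e-10 jitter on the diagonal for matrices that are singular to rounding.
.chol_psd <- function(R) {
  out <- tryCatch(t(chol(R)), error = function(e) NULL)
  if (is.null(out))
    out <- tryCatch(t(chol(R + 1e-10 * diag(nrow(R)))),
                    error = function(e) NULL)
  if (is.null(out))
    stop("correlation matrix is not positive semi-definite ",
         "(Cholesky failed even with 1e-10 jitter)", call. = FALSE)
  out
}

.is_identity_R <- function(struct) {
  if (is.null(struct$R)) return(TRUE)
  R <- struct$R
  nrow(R) == 0L || all(abs(R[row(R) != col(R)]) < 1e-14)
}

# Materialize the correlation matrix of a cov_structure (identity sentinel
# expanded).
#' Correlation matrix of a covariance structure
#' @param struct A \code{\link{cov_structure}}.
#' @return Dense correlation matrix over the structure's levels.
#' @export
struct_correlation <- function(struct) {
  if (!is.null(struct$R)) return(struct$R)
  R <- diag(length(struct$levels))
  dimnames(R) <- list(struct$levels, struct$levels)
  R
}

# ---------------------------------------------------------------------------
# Likelihood engine.
#
# V = diag(v) + sum_k sigma2_k Z_k R_k Z_k'.  Terms whose Z R Z' is diagonal
# (identity correlation, at most one observation per level — e.g. study_id)
# are folded into the diagonal d = v + sum sigma2_k 1{mapped}.  The remaining
# terms are stacked as W = [Z_1 C_1 | Z_2 C_2 | ...] with R_k = C_k C_k', so
# V = diag(d) + U U' with U = W diag(rep(sigma_k)).  When the total number of
# stacked columns q is below n, log|V| and V^-1 are obtained through the
# low-rank identity log|V| = log|diag(d)| + log|I_q + U' diag(d)^-1 U|,
# which is algebraically identical to the dense Cholesky of V (the dense
# route is kept for q >= n and as a test oracle).
# ---------------------------------------------------------------------------
.make_engine <- function(y, v, X, structures) {
  n <- length(y)
  stopifnot(nrow(X) == n, length(v) == n)
  if (any(!is.finite(y))) stop("non-finite effect sizes", call. = FALSE)
  if (any(!is.finite(v) | v <= 0))
    stop("sampling variances must be finite and > 0", call. = FALSE)
  terms <- names(structures)
  if (is.null(terms) || any(!nzchar(terms)) || anyDuplicated(terms))
    stop("structures must be a uniquely named list", call. = FALSE)
  diag_ind <- list()
  blocks <- list()
  col_term <- integer(0)
  for (k in terms) {
    s <- structures[[k]]
    if (length(s$obs_levels) != n)
      stop("structure '", k, "' maps ", length(s$obs_levels),
           " observations but data has ", n, call. = FALSE)
    mapped <- !is.na(s$obs_levels)
    if (.is_identity_R(s) && !anyDuplicated(s$obs_levels[mapped])) {
      diag_ind[[k]] <- as.numeric(mapped)
    } else {
      Z <- incidence_matrix(s, n)
      ZC <- if (.is_identity_R(s)) Z else Z %*% .chol_psd(struct_correlation(s))
      blocks[[k]] <- methods::as(ZC, "CsparseMatrix")
      col_term <- c(col_term, rep(match(k, terms), ncol(ZC)))
    }
  }
  q <- length(col_term)
  ZC <- if (q) methods::as(do.call(cbind, unname(blocks)), "CsparseMatrix")
        else NULL
  eng <- list(y = y, v = v, X = X, A = cbind(y, X), n = n, p = ncol(X),
              terms = terms, diag_ind = diag_ind, q = q, ZC = ZC,
              col_term = col_term,
              xcol = if (q) rep(seq_len(q), diff(ZC@p)) else integer(0),
              xrow = if (q) ZC@i + 1L else integer(0),
              ldXtX = as.numeric(determinant(crossprod(X),
                                             logarithm = TRUE)$modulus),
              use_dense = q >= n)
  eng
}

# Core evaluation. Returns the log-likelihood, or (full = TRUE) a list with
# beta, vcov, V^-1-products and a reusable V^-1 multiplier.
.engine_ll <- function(eng, sigma2, mode = c("REML", "ML"), full = FALSE) {
  mode <- match.arg(mode)
  s2 <- sigma2[eng$terms]
  if (anyNA(s2))
    stop("sigma2 must supply a value for every term: ",
         paste(setdiff(eng$terms, names(sigma2)), collapse = ", "),
         call. = FALSE)
  if (any(s2 < 0)) stop("variance components must be >= 0", call. = FALSE)
  names(s2) <- eng$terms
  d <- eng$v
  for (k in names(eng$diag_ind)) d <- d + s2[[k]] * eng$diag_ind[[k]]
  if (any(d <= 0)) stop("V is not positive definite", call. = FALSE)
  A <- eng$A
  q <- eng$q
  Vinv_parts <- NULL
  if (q && any(s2[eng$col_term] > 0)) {
    sig <- sqrt(s2)[eng$col_term]
    U <- eng$ZC
    U@x <- U@x * sig[eng$xcol]
    if (!eng$use_dense) {
      Us <- U
      Us@x <- Us@x / sqrt(d)[eng$xrow]
      Ad <- A / d
      Q <- as.matrix(Matrix::crossprod(U, Ad))
      B <- Matrix::crossprod(Us)
      if (q <= 500L) {
        Bd <- as.matrix(B)
        diag(Bd) <- diag(Bd) + 1
        cB <- chol(Bd)
        ldB <- 2 * sum(log(diag(cB)))
        sol <- backsolve(cB, backsolve(cB, Q, transpose = TRUE))
        Vinv_parts <- list(kind = "wood_dense", cB = cB, U = U, d = d)
      } else {
        Bs <- Matrix::forceSymmetric(B + Matrix::Diagonal(q))
        ch <- Matrix::Cholesky(Bs, LDL = FALSE, perm = TRUE)
        ldB <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
        sol <- as.matrix(Matrix::solve(ch, Q, system = "A"))
        Vinv_parts <- list(kind = "wood_sparse", ch = ch, U = U, d = d)
      }
      ViA <- Ad - as.matrix(U %*% sol) / d
      logdetV <- sum(log(d)) + ldB
    } else {
      V <- diag(d) + as.matrix(Matrix::tcrossprod(U))
      cV <- tryCatch(chol(V), error = function(e)
        stop("V is not positive definite", call. = FALSE))
      logdetV <- 2 * sum(log(diag(cV)))
      ViA <- backsolve(cV, backsolve(cV, A, transpose = TRUE))
      Vinv_parts <- list(kind = "dense", cV = cV)
    }
  } else {
    ViA <- A / d
    logdetV <- sum(log(d))
    Vinv_parts <- list(kind = "diag", d = d)
  }
  yVi <- ViA[, 1L]
  XVi <- ViA[, -1L, drop = FALSE]
  XViX <- crossprod(eng$X, XVi)
  XViX <- (XViX + t(XViX)) / 2
  XViy <- drop(crossprod(eng$X, yVi))
  cX <- tryCatch(chol(XViX), error = function(e)
    stop("X' V^-1 X is singular (rank-deficient fixed effects?)",
         call. = FALSE))
  beta <- backsolve(cX, backsolve(cX, XViy, transpose = TRUE))
  quad <- max(sum(eng$y * yVi) - sum(beta * XViy), 0)
  n <- eng$n; p <- eng$p
  ll <- if (mode == "ML")
    -0.5 * (n * log(2 * pi) + logdetV + quad)
  else
    -0.5 * ((n - p) * log(2 * pi) - eng$ldXtX + logdetV +
              2 * sum(log(diag(cX))) + quad)
  if (!full) return(ll)
  Vinv <- local({
    parts <- Vinv_parts
    function(M) {
      M <- as.matrix(M)
      switch(parts$kind,
        diag = M / parts$d,
        dense = backsolve(parts$cV,
                          backsolve(parts$cV, M, transpose = TRUE)),
        wood_dense = {
          Md <- M / parts$d
          Qm <- as.matrix(Matrix::crossprod(parts$U, Md))
          sm <- backsolve(parts$cB,
                          backsolve(parts$cB, Qm, transpose = TRUE))
          Md - as.matrix(parts$U %*% sm) / parts$d
        },
        wood_sparse = {
          Md <- M / parts$d
          Qm <- as.matrix(Matrix::crossprod(parts$U, Md))
          sm <- as.matrix(Matrix::solve(parts$ch, Qm, system = "A"))
          Md - as.matrix(parts$U %*% sm) / parts$d
        })
    }
  })
  beta <- drop(beta)
  names(beta) <- colnames(eng$X)
  vcov_beta <- chol2inv(cX)
  dimnames(vcov_beta) <- list(colnames(eng$X), colnames(eng$X))
  list(loglik = ll, beta = beta, vcov_beta = vcov_beta,
       sigma2 = s2, yVi = yVi, XVi = XVi, XViy = XViy,
       logdetV = logdetV, quad = quad, Vinv = Vinv, d = d)
}

#' Log-likelihood of the multilevel meta-analytic mixed model
#'
#' Evaluates the restricted (REML) or full (ML) log-likelihood of the model
#' \deqn{y = X\beta + \sum_k Z_k u_k + e, \quad u_k \sim N(0, \sigma^2_k
#' R_k), \quad e \sim N(0, \mathrm{diag}(\hat v_i)),} at the supplied
#' variance components, with the fixed effects profiled out by generalized
#' least squares. Constant conventions: ML uses \code{-(1/2)[n log 2pi +
#' log|V| + r' V^-1 r]}; REML uses \code{-(1/2)[(n-p) log 2pi - log|X'X| +
#' log|V| + log|X' V^-1 X| + r' V^-1 r]} — the \code{+(1/2) log|X'X|}
#' constant is the convention of standard meta-analytic software, so
#' restricted log-likelihoods are directly comparable across tools.
#'
#' @param y Numeric vector of effect sizes (LRR).
#' @param v Numeric vector of sampling variances (> 0).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param structures Named list of \code{\link{cov_structure}} objects.
#' @param sigma2 Named numeric vector of variance components (one per
#'   structure, all >= 0).
#' @param mode \code{"REML"} or \code{"ML"}.
#' @return The log-likelihood (scalar).
#' @export
meta_loglik <- function(y, v, X = NULL, structures, sigma2,
                        mode = c("REML", "ML")) {
  mode <- match.arg(mode)
  if (is.null(X)) X <- matrix(1, length(y), 1,
                              dimnames = list(NULL, "(Intercept)"))
  eng <- .make_engine(y, v, X, structures)
  .engine_ll(eng, sigma2, mode)
}

#' Fit the multilevel meta-analytic mixed model by REML or ML
#'
#' Maximizes the (restricted) likelihood over the variance components,
#' subject to non-negativity, with the fixed effects profiled out by GLS.
#' Optimization runs on the standard-deviation scale (bounded quasi-Newton,
#' lower bound 0) from a multi-start schedule around a method-of-moments
#' seed, so that true boundary zeros are recovered as exact zeros
#' (components below \code{boundary_tol} on the variance scale are snapped
#' to 0 and the likelihood re-evaluated there).
#'
#' The \code{study_id} term (one random intercept per observation, the
#' residual between-studies heterogeneity) must be present in
#' \code{structures}: every fitted model includes it.
#'
#' @param effects Effect-size table with columns \code{lrr} and
#'   \code{variance} plus any fixed-effect covariates referenced by
#'   \code{fixed}.
#' @param structures Named list of \code{\link{cov_structure}} objects (see
#'   \code{\link{build_structures}}).
#' @param fixed Fixed-effects formula (right-hand side), default \code{~ 1}.
#' @param mode \code{"REML"} (default) or \code{"ML"}.
#' @param random_terms Optional character vector: fit only these structures.
#' @param control List of optimizer settings: \code{reltol} (relative
#'   log-likelihood convergence tolerance, default 1e-8), \code{starts}
#'   (multipliers of the method-of-moments seed, default
#'   \code{c(0.01, 0.1, 1)}), \code{maxit}, \code{boundary_tol} (default
#'   1e-8).
#' @return Object of class \code{"meta_fit"}: fixed-effect estimates with
#'   covariance, named variance components, log-likelihood and mode,
#'   convergence flag, and the data/structure context needed by
#'   \code{\link{profile_ci}}, \code{\link{meta_blups}} and
#'   \code{\link{r2_summaries}}.
#' @export
fit_meta_model <- function(effects, structures, fixed = ~1,
                           mode = c("REML", "ML"), random_terms = NULL,
                           control = list()) {
  mode <- match.arg(mode)
  ctrl <- utils::modifyList(
    list(reltol = 1e-8, starts = c(0.01, 0.1, 1), maxit = 500,
         boundary_tol = 1e-8, require_study = TRUE), control)
  effects <- as.data.frame(effects)
  if (nrow(effects) < 2) stop("need at least 2 observations", call. = FALSE)
  if (!is.null(random_terms)) {
    missing <- setdiff(random_terms, names(structures))
    if (length(missing))
      stop("unknown random term(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    structures <- structures[random_terms]
  }
  if (ctrl$require_study && !"study_id" %in% names(structures))
    stop("the study_id (residual heterogeneity) term must be included ",
         "in every model", call. = FALSE)
  y <- effects$lrr
  v <- effects$variance
  if (is.null(y) || is.null(v))
    stop("effects must carry lrr and variance columns", call. = FALSE)
  X <- model.matrix(fixed, effects)
  if (nrow(X) != length(y))
    stop("fixed-effect covariates contain missing values", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  eng <- .make_engine(y, v, X, structures)
  K <- length(structures)
  terms <- names(structures)
  negll <- function(sg) {
    val <- tryCatch(.engine_ll(eng, setNames(sg^2, terms), mode),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }
  s2tot <- max(var(y) - mean(v), 0.05 * var(y), 1e-4)
  base_sg <- sqrt(s2tot / K)
  best <- NULL
  for (f in ctrl$starts) {
    opt <- tryCatch(
      optim(rep(base_sg * f, K), negll, method = "L-BFGS-B", lower = 0,
            control = list(maxit = ctrl$maxit,
                           factr = ctrl$reltol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best))
    stop("likelihood optimization failed from every start", call. = FALSE)
  if (best$convergence != 0) {
    # restart schedule: derivative-free polish from the best point (the
    # quasi-Newton line search can stall at variance boundaries)
    polish <- if (K == 1)
      optim(best$par, negll, method = "Brent", lower = 0,
            upper = max(10 * best$par + 1, 10))
    else
      optim(best$par, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = ctrl$reltol))
    if (polish$value <= best$value + 1e-8) {
      polish$par <- pmax(polish$par, 0)
      best <- polish
    }
  }
  # boundary exploration: surfaces with several variance terms can carry
  # competing interior and boundary modes; restart with each non-zero
  # component pinned to the boundary and keep any improvement
  improved <- TRUE
  sweeps <- 0L
  while (improved && sweeps < 2L) {
    improved <- FALSE
    sweeps <- sweeps + 1L
    for (k in which(best$par > 1e-4)) {
      par0 <- best$par
      par0[k] <- 0
      o <- tryCatch(
        optim(par0, negll, method = "L-BFGS-B", lower = 0,
              control = list(maxit = ctrl$maxit,
                             factr = ctrl$reltol / .Machine$double.eps)),
        error = function(e) NULL)
      if (!is.null(o) && o$value < best$value - 1e-9) {
        best <- o
        improved <- TRUE
      }
    }
  }
  converged <- best$convergence == 0
  if (!converged)
    warning("variance-component optimization did not formally converge (",
            best$message, "); fit flagged", call. = FALSE)
  s2 <- setNames(best$par^2, terms)
  s2[s2 < ctrl$boundary_tol] <- 0
  final <- .engine_ll(eng, s2, mode, full = TRUE)
  fit <- list(beta = final$beta, vcov_beta = final$vcov_beta,
              sigma2 = s2, loglik = final$loglik, mode = mode,
              converged = converged, n = eng$n, p = eng$p,
              k_varcomp = K, fixed = fixed, terms = terms,
              fitted_fixed = drop(eng$X %*% final$beta),
              effects = effects, structures = structures, engine = eng,
              control = ctrl, call = match.call())
  class(fit) <- "meta_fit"
  fit
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat("Multilevel meta-analytic mixed model (", x$mode, ")\n", sep = "")
  cat("n = ", x$n, ", fixed coefficients = ", x$p,
      ", variance components = ", x$k_varcomp, "\n", sep = "")
  cat("log-likelihood (", x$mode, "): ",
      formatC(x$loglik, digits = digits, format = "f"), "\n\n", sep = "")
  cat("Variance components:\n")
  print(round(x$sigma2, digits))
  cat("\nFixed effects:\n")
  se <- sqrt(diag(x$vcov_beta))
  print(round(cbind(estimate = x$beta, se = se, z = x$beta / se), digits))
  if (!x$converged) cat("\nWARNING: fit flagged as not converged\n")
  invisible(x)
}

#' @export
logLik.meta_fit <- function(object, ...) {
  structure(object$loglik, df = object$p + object$k_varcomp,
            nobs = object$n, class = "logLik")
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Profiles the (restricted) log-likelihood over one variance component,
#' re-maximizing over all others at each point, and locates the endpoints
#' where the profile drops by \code{qchisq(level, 1) / 2} (1.9207 at 95%)
#' below its maximum, by monotone root bracketing and bisection on each
#' side. The lower endpoint is truncated at 0. A profile that never drops
#' below the cutoff on the upper side is reported as an open-ended bound
#' (\code{Inf}) and flagged.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param term Name of the variance component.
#' @param level Confidence level (default 0.95).
#' @param control List: \code{tol} (absolute root tolerance; default
#'   1e-4 of the profile scale), \code{inner_maxit}.
#' @return Numeric \code{c(lower, upper)} with attributes \code{"flags"}
#'   (per-endpoint status) and \code{"level"}.
#' @export
profile_ci <- function(fit, term, level = 0.95, control = list()) {
  stopifnot(inherits(fit, "meta_fit"))
  if (!term %in% names(fit$sigma2))
    stop("unknown term '", term, "'", call. = FALSE)
  ctrl <- utils::modifyList(list(tol = NULL, inner_maxit = 200,
                                 inner_factr = 1e8), control)
  crit <- qchisq(level, 1) / 2
  others <- setdiff(names(fit$sigma2), term)
  eng <- fit$engine
  mode <- fit$mode
  cur <- sqrt(pmax(fit$sigma2[others], 1e-6))
  pl <- function(s2k) {
    if (!length(others))
      return(.engine_ll(eng, setNames(s2k, term), mode))
    nll <- function(sg) {
      val <- tryCatch(
        .engine_ll(eng, setNames(c(sg^2, s2k), c(others, term)), mode),
        error = function(e) NA_real_)
      if (!is.finite(val)) 1e10 else -val
    }
    o <- optim(cur, nll, method = "L-BFGS-B", lower = 0,
               control = list(maxit = ctrl$inner_maxit,
                              factr = ctrl$inner_factr))
    cur <<- o$par
    -o$value
  }
  est <- unname(fit$sigma2[term])
  llmax <- max(fit$loglik, pl(est))
  target <- llmax - crit
  f <- function(s2k) pl(s2k) - target
  scale <- max(est, median(fit$effects$variance), 0.01)
  tol <- if (is.null(ctrl$tol)) max(1e-8, 1e-4 * scale) else ctrl$tol
  flags <- c(lower = "ok", upper = "ok")
  lower <- 0
  if (est > tol) {
    f0 <- f(0)
    if (f0 < 0)
      lower <- uniroot(f, c(0, est), f.lower = f0, f.upper = crit,
                       tol = tol)$root
  }
  hi <- est + scale
  lo <- est
  fhi <- f(hi)
  iter <- 0L
  while (fhi > 0 && iter < 40L) {
    lo <- hi
    hi <- 2 * hi + scale
    fhi <- f(hi)
    iter <- iter + 1L
  }
  if (fhi > 0) {
    upper <- Inf
    flags["upper"] <- "open (flat profile)"
  } else {
    upper <- uniroot(f, c(lo, hi), f.upper = fhi, tol = tol)$root
  }
  structure(c(lower = lower, upper = upper), flags = flags, level = level,
            loglik_max = llmax)
}

#' @rdname profile_ci
#' @param terms Character vector of terms (default: all components of the
#'   fit).
#' @return \code{profile_cis}: a matrix with one row per term and columns
#'   \code{lower}, \code{upper}.
#' @export
profile_cis <- function(fit, terms = NULL, level = 0.95, control = list()) {
  if (is.null(terms)) terms <- names(fit$sigma2)
  out <- t(vapply(terms, function(k)
    unclass(profile_ci(fit, k, level = level, control = control))[1:2],
    numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Best linear unbiased predictors (BLUPs) of random-effect levels
#'
#' Computes the shrinkage estimates \eqn{\hat u_k = \sigma^2_k R_k Z_k'
#' V^{-1}(y - X\hat\beta)} of each level's deviation from the weighted mean
#' effect size, with standard errors from the prediction-variance expression
#' \eqn{\sigma^2_k R_k - \sigma^4_k R_k Z_k' P Z_k R_k}. Deviations are
#' reported on the LRR scale and, for display, as percent growth responses
#' \code{100 * (exp(mu + u) - 1)} built on the model intercept \code{mu}.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param terms Terms to extract (default: all non-observation-level terms,
#'   i.e. everything except \code{study_id}).
#' @return Data frame with columns \code{term}, \code{level}, \code{blup},
#'   \code{se}, \code{percent}.
#' @export
meta_blups <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "meta_fit"))
  if (is.null(terms))
    terms <- setdiff(names(fit$sigma2), "study_id")
  full <- .engine_ll(fit$engine, fit$sigma2, fit$mode, full = TRUE)
  Vir <- full$yVi - drop(full$XVi %*% full$beta)
  mu <- if ("(Intercept)" %in% names(full$beta))
    unname(full$beta["(Intercept)"]) else 0
  out <- lapply(terms, function(k) {
    s <- fit$structures[[k]]
    s2 <- unname(fit$sigma2[k])
    lev <- s$levels
    if (s2 == 0) {
      u <- rep(0, length(lev))
      se <- rep(0, length(lev))
    } else {
      Z <- incidence_matrix(s, fit$n)
      ident <- .is_identity_R(s)
      t1 <- as.numeric(Matrix::crossprod(Z, Vir))
      u <- if (ident) s2 * t1
           else s2 * as.numeric(struct_correlation(s) %*% t1)
      W <- if (ident) Z else Z %*% struct_correlation(s)
      ViW <- full$Vinv(W)
      WViW <- as.matrix(Matrix::crossprod(W, ViW))
      XViW <- crossprod(fit$engine$X, as.matrix(ViW))
      WPW <- WViW - t(XViW) %*% full$vcov_beta %*% XViW
      Rd <- if (ident) rep(1, length(lev)) else diag(struct_correlation(s))
      se <- sqrt(pmax(s2 * Rd - s2^2 * diag(WPW), 0))
    }
    data.frame(term = k, level = lev, blup = u, se = se,
               percent = percent_change(mu + u), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Variance-explained summaries of a fitted meta-analytic model
#'
#' Marginal R-squared (share of variance attributable to the fixed effects)
#' and partial conditional R-squared per random effect (a single term's
#' variance component as a share of total model variance). The fixed-effect
#' variance is the population variance (divide by n) of the fitted
#' fixed-effect values; the denominator is \code{sigma2_fixed + sum(sigma2)}
#' — the sampling variances are excluded because the summaries describe
#' proportions of between-studies variance. The alternative
#' components-only denominator is available behind the \code{denominator}
#' flag.
#'
#' @param fit A \code{\link{fit_meta_model}} object.
#' @param denominator \code{"with_fixed"} (default) or
#'   \code{"components_only"}.
#' @return List with \code{marginal_r2}, \code{partial_r2} (named vector)
#'   and \code{sigma2_fixed}.
#' @export
r2_summaries <- function(fit,
                         denominator = c("with_fixed", "components_only")) {
  stopifnot(inherits(fit, "meta_fit"))
  xb <- fit$fitted_fixed
  s2f <- mean((xb - mean(xb))^2)
  r2_from_components(fit$sigma2, s2f, denominator = denominator)
}

#' @rdname r2_summaries
#' @param sigma2 Named vector of variance components.
#' @param sigma2_fixed Variance of the fitted fixed-effect values.
#' @export
r2_from_components <- function(sigma2, sigma2_fixed = 0,
                               denominator = c("with_fixed",
                                               "components_only")) {
  denominator <- match.arg(denominator)
  tot_rand <- sum(sigma2)
  if (denominator == "with_fixed") {
    D <- sigma2_fixed + tot_rand
    if (D <= 0) stop("total variance is zero", call. = FALSE)
    list(marginal_r2 = sigma2_fixed / D, partial_r2 = sigma2 / D,
         sigma2_fixed = sigma2_fixed)
  } else {
    if (tot_rand <= 0) stop("total random variance is zero", call. = FALSE)
    list(marginal_r2 = if (sigma2_fixed + tot_rand > 0)
           sigma2_fixed / (sigma2_fixed + tot_rand) else NA_real_,
         partial_r2 = sigma2 / tot_rand, sigma2_fixed = sigma2_fixed)
  }
}

#' Overall weighted mean effect size (pure random-effects model)
#'
#' Fits the intercept-only REML model with all supplied random effects and
#' reports the overall weighted mean on the LRR and percent scales. Two
#' percent-scale SE conventions are reported: the delta method
#' (\code{100 * exp(lrr) * se}) and back-transformed Wald endpoints.
#'
#' @inheritParams fit_meta_model
#' @param level Confidence level for the endpoint transform.
#' @return List of class \code{"myco_overall"} with elements \code{lrr},
#'   \code{se}, \code{percent}, \code{percent_se} (delta method),
#'   \code{percent_ci} (back-transformed endpoints), and \code{fit}.
#' @export
overall_mean <- function(effects, structures, mode = "REML", level = 0.95,
                         control = list()) {
  fit <- fit_meta_model(effects, structures, fixed = ~1, mode = mode,
                        control = control)
  b <- unname(fit$beta[1])
  se <- sqrt(fit$vcov_beta[1, 1])
  z <- qnorm(1 - (1 - level) / 2)
  out <- list(lrr = b, se = se,
              percent = percent_change(b),
              percent_se = 100 * exp(b) * se,
              percent_ci = percent_change(c(b - z * se, b + z * se)),
              level = level, fit = fit)
  class(out) <- "myco_overall"
  out
}

#' @export
print.myco_overall <- function(x, digits = 3, ...) {
  cat("Overall weighted mean growth response: ",
      formatC(x$percent, digits = digits, format = "f"), "% ± ",
      formatC(x$percent_se, digits = digits, format = "f"),
      " SE (delta method)\n", sep = "")
  cat("  LRR ", formatC(x$lrr, digits = digits, format = "f"), " ± ",
      formatC(x$se, digits = digits, format = "f"),
      "; back-transformed ", 100 * x$level, "% CI on percent scale: [",
      formatC(x$percent_ci[1], digits = digits, format = "f"), ", ",
      formatC(x$percent_ci[2], digits = digits, format = "f"), "]\n",
      sep = "")
  invisible(x)
}
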