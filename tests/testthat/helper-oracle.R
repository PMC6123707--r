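# Independent likelihood oracle: plain dense algebra (solve/determinant),
# sharing no code with the package's engine.
oracle_loglik <- function(y, v, X, Zlist, Rlist, s2, mode = "REML") {
  n <- length(y)
  V <- diag(v, n)
  for (k in seq_along(Zlist))
    V <- V + s2[k] * Zlist[[k]] %*% Rlist[[k]] %*% t(Zlist[[k]])
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% b
  quad <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  p <- ncol(X)
  if (mode == "ML") {
    -0.5 * (n * log(2 * pi) + ldV + quad)
  } else {
    ldXX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
    ldXVX <- as.numeric(determinant(XtVi %*% X, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(2 * pi) - ldXX + ldV + ldXVX + quad)
  }
}

# Derivative-free global search over the variance components (sd-squared
# parameterisation keeps the boundary smooth): Brent in 1-D, multi-start
# Nelder-Mead otherwise.
oracle_max_loglik <- function(y, v, Zlist, Rlist, mode = "REML",
                              X = matrix(1, length(y), 1), n_starts = 8) {
  K <- length(Zlist)
  f <- function(sg) {
    val <- tryCatch(oracle_loglik(y, v, X, Zlist, Rlist, sg^2, mode),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }
  starts <- c(list(rep(0.01, K), rep(0.3, K), rep(1, K)),
              lapply(seq_len(n_starts), function(i) runif(K, 0, 1.5)))
  best <- Inf
  best_par <- NULL
  for (par0 in starts) {
    o <- if (K == 1)
      optim(par0, f, method = "Brent", lower = 0, upper = 25)
    else
      optim(par0, f, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-13))
    if (o$value < best) { best <- o$value; best_par <- o$par }
  }
  if (K > 1) {  # polish from the best point
    o <- optim(best_par, f, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
    best <- min(best, o$value)
  }
  -best
}

# Random small model instance: term 1 is the observation-level study term;
# further terms are random groupings with identity or Brownian correlation.
rand_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:10, 1)
  K <- sample(1:3, 1)
  y <- rnorm(n, 0.3, 0.7)
  v <- runif(n, 0.05, 0.5)
  eff <- data.frame(lrr = y, variance = v, study_id = paste0("s", 1:n))
  structures <- list(study_id = cov_structure("study_id", NULL,
                                              eff$study_id))
  Zlist <- list(diag(n))
  Rlist <- list(diag(n))
  if (K >= 2) for (k in 2:K) {
    nlev <- sample(2:4, 1)
    g <- sample(paste0("g", seq_len(nlev)), n, replace = TRUE)
    lev <- sort(unique(g))
    R <- NULL
    if (length(lev) >= 3 && runif(1) < 0.5) {
      tr <- ape::rcoal(length(lev), tip.label = lev)
      R <- brownian_correlation(tr, taxa = lev)
    }
    structures[[paste0("term", k)]] <-
      cov_structure(paste0("term", k), R, g)
    Z <- matrix(0, n, length(lev))
    Z[cbind(seq_len(n), match(g, lev))] <- 1
    Zlist[[k]] <- Z
    Rlist[[k]] <- if (is.null(R)) diag(length(lev)) else R
  }
  list(eff = eff, structures = structures, Zlist = Zlist, Rlist = Rlist)
}

small_tree <- function() read_phylogeny(text = "((A:1,B:1):1,C:2);")

# Minimal trial table used across effect-size tests.
toy_trials <- function() {
  data.frame(
    study_id = paste0("s", 1:4),
    paper_id = c("P1", "P1", "P2", "P2"),
    control_set_id = c("C1", "C1", "C2", "C3"),
    plant_species = c("A", "B", "A", "C"),
    fungal_genus = c("f1", "f1", "f2", "f2"),
    myc_type = "AM",
    mean_inoc = c(2, 1, 4, 3), mean_ctrl = c(1, 1, 2, 3),
    sd_inoc = c(1, 0.5, NA, 0.9), sd_ctrl = c(1, 0.5, NA, 0.9),
    n_inoc = c(4L, 5L, 4L, 6L), n_ctrl = c(4L, 5L, 4L, 6L),
    stringsAsFactors = FALSE)
}
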