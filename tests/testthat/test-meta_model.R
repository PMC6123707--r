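test_that("two-observation REML recovers the closed-form heterogeneity", {
  # intercept-only, equal v: tau2_hat = max(0, (y1 - y2)^2 / 2 - v)
  eff <- data.frame(lrr = c(0, 2), variance = c(0.5, 0.5),
                    study_id = c("a", "b"))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  fit <- fit_meta_model(eff, st, mode = "REML")
  expect_equal(unname(fit$sigma2), 1.5, tolerance = 1e-6)
  # boundary case: close observations push the estimate to exactly 0
  eff0 <- data.frame(lrr = c(0, 0.1), variance = c(0.5, 0.5),
                     study_id = c("a", "b"))
  st0 <- list(study_id = cov_structure("study_id", NULL, eff0$study_id))
  fit0 <- fit_meta_model(eff0, st0, mode = "REML")
  expect_identical(unname(fit0$sigma2), 0)
})

test_that("all-zero components reduce the likelihood to weighted least squares", {
  set.seed(3)
  y <- rnorm(8); v <- runif(8, 0.1, 0.4)
  eff <- data.frame(lrr = y, variance = v, study_id = paste0("s", 1:8))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  ll <- meta_loglik(y, v, NULL, st, c(study_id = 0), mode = "ML")
  bhat <- sum(y / v) / sum(1 / v)
  expect_equal(ll, sum(dnorm(y, bhat, sqrt(v), log = TRUE)), tolerance = 1e-10)
})

test_that("engine log-likelihood equals the independent dense oracle", {
  for (seed in 1:25) {
    inst <- rand_instance(seed)
    K <- length(inst$structures)
    s2 <- setNames(runif(K, 0, 0.8), names(inst$structures))
    for (mode in c("REML", "ML")) {
      ours <- meta_loglik(inst$eff$lrr, inst$eff$variance, NULL,
                          inst$structures, s2, mode)
      orac <- oracle_loglik(inst$eff$lrr, inst$eff$variance,
                            matrix(1, nrow(inst$eff), 1),
                            inst$Zlist, inst$Rlist, s2, mode)
      expect_equal(ours, orac, tolerance = 1e-8)
    }
  }
})

test_that("REML fit agrees with metafor on a crossed phylogenetic example", {
  skip_if_not_installed("metafor")
  set.seed(42)
  n <- 40
  tr <- ape::rcoal(5, tip.label = paste0("sp", 1:5))
  dat <- data.frame(study_id = paste0("s", 1:n),
                    plant_species = sample(paste0("sp", 1:5), n, TRUE),
                    paper_id = rep(paste0("P", 1:8), each = 5),
                    lrr = rnorm(n, 0.4, 0.6),
                    variance = runif(n, 0.05, 0.3))
  Rp <- brownian_correlation(tr, taxa = paste0("sp", 1:5))
  st <- list(
    plant_phylogeny = cov_structure("plant_phylogeny", Rp,
                                    dat$plant_species),
    study_id = cov_structure("study_id", NULL, dat$study_id),
    paper = cov_structure("paper", NULL, dat$paper_id))
  ours <- fit_meta_model(dat, st, mode = "REML")
  dat$phylo <- dat$plant_species
  mf <- metafor::rma.mv(lrr, variance,
                        random = list(~1 | phylo, ~1 | study_id, ~1 | paper_id),
                        R = list(phylo = Rp), Rscale = "none",
                        data = dat, method = "REML")
  expect_equal(ours$loglik, as.numeric(stats::logLik(mf)), tolerance = 1e-4)
  expect_equal(unname(ours$sigma2), unname(mf$sigma2), tolerance = 2e-3)
  expect_equal(unname(ours$beta), as.numeric(mf$beta), tolerance = 1e-4)
})

test_that("fit is invariant to row permutation", {
  inst <- rand_instance(101)
  fit1 <- fit_meta_model(inst$eff, inst$structures, mode = "REML")
  set.seed(9); perm <- sample(nrow(inst$eff))
  eff2 <- inst$eff[perm, ]
  st2 <- lapply(inst$structures, function(s)
    cov_structure(s$term, s$R, s$obs_levels[perm]))
  fit2 <- fit_meta_model(eff2, st2, mode = "REML")
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-4)
})

test_that("adding a random term never decreases the maximized log-likelihood", {
  for (seed in c(7, 19, 33)) {
    inst <- rand_instance(seed)
    if (length(inst$structures) < 2) next
    full <- fit_meta_model(inst$eff, inst$structures, mode = "ML")
    sub <- fit_meta_model(inst$eff, inst$structures["study_id"], mode = "ML")
    expect_gte(full$loglik, sub$loglik - 1e-6)
  }
})

test_that("REML and ML nearly coincide for intercept-only models at large n", {
  cfg <- sim_config(seed = 77, n_papers = 63, mean_effects_per_paper = 8,
                    effects_per_paper_dist = "fixed",
                    true_sigma2 = c(study_id = 0.10, paper = 0.15))
  sim <- simulate_dataset(cfg)
  eff <- suppressWarnings(compute_effect_sizes(sim$trials))
  st <- build_structures(eff, sim$plant_tree, sim$fungal_tree, "am_sub")
  terms <- c("study_id", "paper")
  reml <- fit_meta_model(eff, st, mode = "REML", random_terms = terms)
  ml <- fit_meta_model(eff, st, mode = "ML", random_terms = terms)
  expect_lt(max(abs(reml$sigma2 - ml$sigma2) / pmax(reml$sigma2, 0.01)),
            0.05)
})

test_that("profile CI matches a grid oracle on the two-observation model", {
  eff <- data.frame(lrr = c(0, 2), variance = c(0.5, 0.5),
                    study_id = c("a", "b"))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  fit <- fit_meta_model(eff, st, mode = "REML")
  ci <- profile_ci(fit, "study_id", control = list(tol = 1e-7))
  # oracle: REML profile of the single component via the dense likelihood
  Z <- list(diag(2)); R <- list(diag(2))
  oll <- function(t2) oracle_loglik(eff$lrr, eff$variance,
                                    matrix(1, 2, 1), Z, R, t2, "REML")
  target <- oll(1.5) - qchisq(0.95, 1) / 2
  up <- uniroot(function(t2) oll(t2) - target, c(1.5, 500), tol = 1e-9)$root
  lo_f <- function(t2) oll(t2) - target
  lo <- if (lo_f(0) >= 0) 0 else
    uniroot(lo_f, c(0, 1.5), tol = 1e-9)$root
  expect_equal(unname(ci["lower"]), lo, tolerance = 1e-4)
  expect_equal(unname(ci["upper"]), up, tolerance = 1e-4)
  expect_true(ci["lower"] <= 1.5 && 1.5 <= ci["upper"])
})

test_that("boundary estimates get intervals of the form [0, u > 0]", {
  eff <- data.frame(lrr = c(0, 0.05, -0.05, 0.02),
                    variance = rep(0.4, 4),
                    study_id = paste0("s", 1:4))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  fit <- fit_meta_model(eff, st, mode = "REML")
  expect_identical(unname(fit$sigma2), 0)
  ci <- profile_ci(fit, "study_id")
  expect_identical(unname(ci["lower"]), 0)
  expect_gt(ci["upper"], 0)
})

test_that("noisier data never narrows a profile interval", {
  inst <- rand_instance(55)
  fit1 <- fit_meta_model(inst$eff, inst$structures["study_id"],
                         mode = "REML")
  eff2 <- inst$eff; eff2$variance <- eff2$variance * 4
  st2 <- inst$structures["study_id"]
  fit2 <- fit_meta_model(eff2, st2, mode = "REML")
  ci1 <- profile_ci(fit1, "study_id")
  ci2 <- profile_ci(fit2, "study_id")
  expect_gte(diff(ci2) - diff(ci1), -1e-4)
})

test_that("BLUPs shrink group means and sum to zero with an intercept", {
  # balanced two-group design, equal sampling variance, group term only:
  # u_hat_g = (s2 / (s2 + v/m)) * (group mean - grand mean)
  y <- c(0.9, 1.1, 1.0, 0.1, -0.1, 0.0)
  g <- rep(c("g1", "g2"), each = 3)
  eff <- data.frame(lrr = y, variance = 0.2,
                    study_id = paste0("s", 1:6), grp = g)
  st <- list(grp = cov_structure("grp", NULL, g))
  fit <- fit_meta_model(eff, st, mode = "REML",
                        control = list(require_study = FALSE))
  b <- meta_blups(fit, "grp")
  s2 <- unname(fit$sigma2["grp"])
  shrink <- s2 / (s2 + 0.2 / 3)
  gm <- tapply(y, g, mean); grand <- mean(y)
  expect_equal(b$blup, as.numeric(shrink * (gm[b$level] - grand)),
               tolerance = 1e-6)
  expect_equal(sum(b$blup), 0, tolerance = 1e-8)
  expect_true(all(b$se > 0))
  # a zero component gives all-zero BLUPs
  inst <- rand_instance(13)
  fitz <- fit_meta_model(inst$eff, inst$structures, mode = "REML")
  zero_terms <- names(which(fitz$sigma2 == 0))
  if (length(zero_terms)) {
    bz <- meta_blups(fitz, zero_terms[1])
    expect_true(all(bz$blup == 0))
  }
})

test_that("variance-explained summaries follow the shared-denominator rule", {
  r2 <- r2_from_components(c(a = 3, b = 1), sigma2_fixed = 0)
  expect_equal(unname(r2$partial_r2["a"]), 0.75)
  expect_equal(r2$marginal_r2, 0)
  r2b <- r2_from_components(c(a = 0), sigma2_fixed = 0.5)
  expect_equal(r2b$marginal_r2, 1)
  # fitted-model version: population variance of X beta in the numerator
  set.seed(8)
  n <- 30
  eff <- data.frame(lrr = rnorm(n, 0.3), variance = runif(n, 0.1, 0.2),
                    study_id = paste0("s", 1:n),
                    x = factor(rep(c("no", "yes"), n / 2)))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  fit <- fit_meta_model(eff, st, fixed = ~x, mode = "REML")
  r2f <- r2_summaries(fit)
  xb <- fit$fitted_fixed
  expect_equal(r2f$sigma2_fixed, mean((xb - mean(xb))^2))
  expect_lte(r2f$marginal_r2 + sum(r2f$partial_r2), 1 + 1e-10)
})

test_that("overall mean degenerates correctly for homogeneous data", {
  eff <- data.frame(lrr = rep(0.5, 6), variance = rep(1e-6, 6),
                    study_id = paste0("s", 1:6))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  om <- overall_mean(eff, st)
  expect_equal(om$lrr, 0.5, tolerance = 1e-6)
  expect_equal(om$percent, percent_change(0.5), tolerance = 1e-4)
  expect_lt(om$se, 1e-3)
})
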