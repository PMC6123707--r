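make_em_fit <- function(seed = 61) {
  cfg <- sim_config(seed = seed, em_mode = TRUE, n_plants = 6, n_fungi = 4,
                    n_papers = 15, mean_effects_per_paper = 10,
                    effects_per_paper_dist = "fixed",
                    n_plant_origins = 2, n_fungal_origins = 2,
                    true_sigma2 = c(
                      plant_phylogeny_x_fungal_phylogeny = 0.15,
                      study_id = 0.05, paper = 0.2))
  sim <- simulate_dataset(cfg)
  eff <- suppressWarnings(compute_effect_sizes(sim$trials))
  st <- build_structures(eff, sim$plant_tree, sim$fungal_tree, "em")
  fit <- fit_meta_model(eff, st, mode = "REML",
                        random_terms = c("plant_phylogeny_x_fungal_phylogeny",
                                         "study_id", "paper"))
  list(fit = fit, eff = eff)
}

test_that("BLUP matrices map interaction levels onto realized cells only", {
  res <- make_em_fit()
  bm <- blup_matrix(res$fit, "plant_phylogeny_x_fungal_phylogeny")
  realized <- unique(paste(res$eff$plant_species, res$eff$fungal_genus,
                           sep = ":"))
  expect_equal(bm$n_realized, length(realized))
  expect_equal(sum(!is.na(bm$lrr)), length(realized))
  # unrealized combinations are absent (NA), not zero
  expect_true(anyNA(bm$lrr) || bm$n_realized == length(bm$lrr))
  # marginal means are means over realized cells only
  expect_equal(bm$plant_marginal, rowMeans(bm$lrr, na.rm = TRUE))
  expect_equal(bm$fungus_marginal, colMeans(bm$lrr, na.rm = TRUE))
  # percent deviations are measured from the overall percent mean
  mu <- unname(res$fit$beta["(Intercept)"])
  ij <- which(!is.na(bm$lrr), arr.ind = TRUE)[1, ]
  expect_equal(bm$percent_deviation[ij[1], ij[2]],
               percent_change(mu + bm$lrr[ij[1], ij[2]]) -
                 percent_change(mu))
})

test_that("balanced antisymmetric BLUPs have zero plant marginals", {
  M <- matrix(c(0.1, -0.1, 0.2, -0.2), 2, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("f1", "f2")))
  expect_equal(unname(rowMeans(M)), c(0, 0))
})

test_that("zero interaction variance yields an all-zero BLUP matrix", {
  res <- make_em_fit()
  fit <- res$fit
  # refit with the interaction clamped out by using a null simulation
  cfg <- sim_config(seed = 62, em_mode = TRUE, n_plants = 6, n_fungi = 4,
                    n_papers = 15, mean_effects_per_paper = 10,
                    effects_per_paper_dist = "fixed",
                    n_plant_origins = 2, n_fungal_origins = 2,
                    true_sigma2 = c(study_id = 0.05, paper = 0.2))
  sim <- simulate_dataset(cfg)
  eff <- suppressWarnings(compute_effect_sizes(sim$trials))
  st <- build_structures(eff, sim$plant_tree, sim$fungal_tree, "em")
  fit0 <- fit_meta_model(eff, st, mode = "REML",
                         random_terms = c(
                           "plant_phylogeny_x_fungal_phylogeny",
                           "study_id", "paper"))
  if (fit0$sigma2[["plant_phylogeny_x_fungal_phylogeny"]] == 0) {
    bm <- blup_matrix(fit0, "plant_phylogeny_x_fungal_phylogeny")
    expect_true(all(bm$lrr[!is.na(bm$lrr)] == 0))
  } else {
    succeed("interaction component not estimated at the boundary this seed")
  }
})

test_that("marginal means equal GLS group means for a single-predictor model", {
  set.seed(71)
  n <- 40
  eff <- data.frame(lrr = rnorm(n, 0.3), variance = rep(0.15, n),
                    study_id = paste0("s", 1:n),
                    n_fert = factor(rep(c("no", "yes"), each = n / 2)))
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  fit <- fit_meta_model(eff, st, fixed = ~n_fert, mode = "REML")
  mm <- marginal_means(fit, "n_fert")
  # equal v and balanced design: GLS group means = arithmetic group means
  expect_equal(mm$means$lrr,
               as.numeric(tapply(eff$lrr, eff$n_fert, mean)[mm$means$level]),
               tolerance = 1e-6)
  expect_equal(mm$means$percent, percent_change(mm$means$lrr))
})

test_that("adjusted data reproduce marginal means in a balanced design", {
  set.seed(72)
  n <- 48
  d <- expand.grid(n_fert = c("no", "yes"), p_fert = c("no", "yes"),
                   rep = 1:(n / 4), stringsAsFactors = FALSE)
  eff <- data.frame(lrr = rnorm(n, 0.2) + 0.5 * (d$n_fert == "yes") -
                      0.3 * (d$p_fert == "yes"),
                    variance = rep(0.1, n),
                    study_id = paste0("s", 1:n),
                    n_fert = d$n_fert, p_fert = d$p_fert)
  st <- list(study_id = cov_structure("study_id", NULL, eff$study_id))
  fit <- fit_meta_model(eff, st, fixed = ~ n_fert + p_fert, mode = "REML")
  mm <- marginal_means(fit, "n_fert")
  adj_means <- tapply(mm$adjusted$lrr_adjusted, mm$adjusted$level, mean)
  expect_equal(mm$means$lrr, as.numeric(adj_means[mm$means$level]),
               tolerance = 1e-6)
})

test_that("funnel export carries one row per effect with SE and flags", {
  tr <- toy_trials()
  eff <- compute_effect_sizes(tr)
  fd <- funnel_data(eff)
  expect_equal(nrow(fd), nrow(eff))
  expect_equal(fd$se, sqrt(eff$variance))
  expect_equal(fd$se[eff$variance == 0.04], rep(0.2, sum(eff$variance == 0.04)))
  expect_equal(fd$variance_imputed, eff$variance_imputed)
})

test_that("variance table lists every term once and flags notable shares", {
  res <- make_em_fit()
  vt <- variance_table(res$fit, ci = FALSE)
  expect_setequal(vt$term, names(res$fit$sigma2))
  expect_equal(anyDuplicated(vt$term), 0L)
  expect_equal(vt$notable, vt$partial_r2 > 0.05)
})

test_that("fit reports and BLUP tables serialize round-trip", {
  res <- make_em_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(res$fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$n, res$fit$n)
  expect_equal(unlist(rep$sigma2), res$fit$sigma2, tolerance = 1e-10)
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_blups(res$fit, bpath, terms = "paper")
  b <- read_trials(bpath)
  expect_equal(nrow(b), length(unique(res$eff$paper_id)))
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_fit_summary(res$fit, tpath)
  txt <- readLines(tpath)
  expect_true(any(grepl("^mode: REML", txt)))
  expect_true(any(grepl("\\[variance_components\\]", txt)))
})
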