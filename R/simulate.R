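#' Configuration for the synthetic MycoDB-style data generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate the
#' structure of the real inoculation-trial database: crossed plant/fungus
#' membership with only a fraction of all combinations realized, papers
#' contributing multiple effect sizes that share non-inoculated controls,
#' phylogenetically heritable and non-heritable random effects, origin-clade
#' effects (EM mode), heteroscedastic sampling variances, and a stated
#' fraction of rows with unreported SDs.
#'
#' Defaults mirror the two study conditions: AM mode (the default) follows
#' the single-genus arbuscular mycorrhizal subset — 234 plant species, 14
#' fungal genera, 297 papers with ~8 effect sizes each, realized-pair
#' density 0.14, 3.5% of rows missing SDs, and true variance components
#' \{plant species 0.15, study 0.10, control set 0.16, paper 0.15, plant
#' phylogeny 0.009, plant phylogeny x fungal genus 0.06\}; EM mode follows
#' the ectomycorrhizal subset — 62 plants, 40 fungal genera, 83 papers,
#' density 0.077, 21.2% missing SDs, 7 plant and 24 fungal origin clades,
#' and components \{plant origin 0.232, plant phylogeny x fungal phylogeny
#' 0.11, plant x fungal origin 0.01, study 0.04, control set 0.15, paper
#' 0.65\}. The intercept defaults to the log of the observed overall
#' response ratio (log 1.62 AM, log 1.80 EM); other fixed effects default
#' to zero. Sampling variances are log-normal (meanlog log(0.03),
#' sdlog 1), a typical spread for biomass log response ratios.
#'
#' @param seed Integer seed (mandatory); sub-streams for trees and data are
#'   derived from it with fixed offsets.
#' @param em_mode Logical: generate an ectomycorrhizal-style dataset with
#'   origin clades.
#' @param ... Overrides for any default field: \code{n_plants},
#'   \code{n_fungi}, \code{n_papers}, \code{mean_effects_per_paper},
#'   \code{effects_per_paper_dist} (\code{"poisson"} or \code{"fixed"}),
#'   \code{pair_density}, \code{true_beta} (named; must include
#'   \code{"(Intercept)"}; other entries name binary predictors and give
#'   the effect of the second level), \code{true_sigma2} (named),
#'   \code{v_meanlog}, \code{v_sdlog}, \code{missing_sd_rate},
#'   \code{control_fanout} (mean control sets per paper, default 1),
#'   \code{n_plant_origins}, \code{n_fungal_origins}, \code{reps} (range of
#'   replicate counts).
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(seed, em_mode = FALSE, ...) {
  if (missing(seed) || is.na(seed))
    stop("seed is mandatory", call. = FALSE)
  base <- if (!em_mode) list(
    n_plants = 234, n_fungi = 14, n_papers = 297,
    mean_effects_per_paper = 8, effects_per_paper_dist = "poisson",
    pair_density = 0.14,
    true_beta = c("(Intercept)" = log(1.62)),
    true_sigma2 = c(plant_phylogeny = 0.009, plant_species = 0.15,
                    fungal_phylogeny = 0, fungal_genus = 0,
                    plant_phylogeny_x_fungal_phylogeny = 0,
                    plant_phylogeny_x_fungal_genus = 0.06,
                    plant_species_x_fungal_phylogeny = 0,
                    plant_species_x_fungal_genus = 0.0001,
                    study_id = 0.10, control_set = 0.16, paper = 0.15),
    v_meanlog = log(0.03), v_sdlog = 1,
    missing_sd_rate = 0.035, control_fanout = 1,
    n_plant_origins = 0, n_fungal_origins = 0, reps = 3:10
  ) else list(
    n_plants = 62, n_fungi = 40, n_papers = 83,
    mean_effects_per_paper = 12, effects_per_paper_dist = "poisson",
    pair_density = 0.077,
    true_beta = c("(Intercept)" = log(1.80)),
    true_sigma2 = c(plant_phylogeny = 0, plant_species = 0,
                    fungal_phylogeny = 0, fungal_genus = 0,
                    plant_phylogeny_x_fungal_phylogeny = 0.11,
                    plant_phylogeny_x_fungal_genus = 0,
                    plant_species_x_fungal_phylogeny = 0,
                    plant_species_x_fungal_genus = 0,
                    plant_origin = 0.232, fungal_origin = 0,
                    plant_x_fungal_origin = 0.01,
                    study_id = 0.04, control_set = 0.15, paper = 0.65),
    v_meanlog = log(0.03), v_sdlog = 1,
    missing_sd_rate = 0.212, control_fanout = 1,
    n_plant_origins = 7, n_fungal_origins = 24, reps = 3:10
  )
  cfg <- utils::modifyList(base, list(...))
  cfg$seed <- as.integer(seed)
  cfg$em_mode <- em_mode
  if (any(cfg$true_sigma2 < 0)) stop("variances must be >= 0", call. = FALSE)
  if (cfg$missing_sd_rate < 0 || cfg$missing_sd_rate > 1)
    stop("missing_sd_rate must be in [0, 1]", call. = FALSE)
  if (cfg$pair_density <= 0 || cfg$pair_density > 1)
    stop("pair_density must be in (0, 1]", call. = FALSE)
  if (!"(Intercept)" %in% names(cfg$true_beta))
    stop("true_beta must include an \"(Intercept)\" entry", call. = FALSE)
  if (!em_mode && any(cfg$true_sigma2[c("plant_origin", "fungal_origin",
                                        "plant_x_fungal_origin")] > 0,
                      na.rm = TRUE))
    stop("origin variance components require em_mode = TRUE", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Pure-birth tree with n tips, scaled to unit height, tips prefix1..prefixn.
.rphylo_unit <- function(n, prefix) {
  if (n == 1L) {
    tree <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = paste0(prefix, 1),
                 edge.length = 1, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::rphylo(n, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length / max(depths)
  tree$tip.label <- paste0(prefix, seq_len(n))
  tree
}

#' Simulate the plant and fungal phylogenies of a synthetic dataset
#'
#' Pure-birth trees with the configured tip counts, scaled to unit height;
#' deterministic given the config seed (the tree sub-stream uses fixed seed
#' offsets so editing other config fields does not change the trees).
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{plant} and \code{fungal} (\code{"phylo"}
#'   objects, tips \code{p1..} and \code{f1..}).
#' @export
simulate_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  plant <- .rphylo_unit(config$n_plants, "p")
  set.seed(config$seed + 202L)
  fungal <- .rphylo_unit(config$n_fungi, "f")
  list(plant = plant, fungal = fungal)
}

#' Simulate a MycoDB-style trial table with known ground truth
#'
#' Draws every model layer at its configured truth: random effects
#' \eqn{u_k \sim N(0, \sigma^2_k R_k)} (Brownian correlations from the
#' simulated trees for the phylogenetic terms, tensor-product correlations
#' over the realized pairs for the interactions, identity otherwise), fixed
#' effects over binary ecological covariates, and heteroscedastic sampling
#' noise \eqn{e_i \sim N(0, v_i)} with log-normal \eqn{v_i}. Group means,
#' SDs and replicate counts are then constructed to invert exactly:
#' \code{mean_ctrl = 1}, \code{mean_inoc = exp(y_i)}, and
#' \code{SD_g = mean_g * sqrt(v_i * n_g / 2)}, so that recomputing the
#' effect sizes returns \code{lrr = y_i} and \code{variance = v_i} on every
#' row whose SDs are not masked. SDs are masked (both groups) at the
#' configured missing rate. Origin clades (EM mode) are contiguous clades
#' obtained by cutting the corresponding tree's cophenetic distances into
#' the configured number of groups.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{"myco_sim"}: \code{trials} (data frame ready
#'   for \code{\link{compute_effect_sizes}}), \code{truth} (list with
#'   \code{beta}, \code{sigma2}, per-term level effects \code{u},
#'   \code{v}, \code{y}), \code{plant_tree}, \code{fungal_tree},
#'   \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  trees <- simulate_trees(config)
  set.seed(config$seed + 303L)
  np <- config$n_papers
  sizes <- if (config$effects_per_paper_dist == "fixed")
    rep(round(config$mean_effects_per_paper), np)
  else
    1L + rpois(np, config$mean_effects_per_paper - 1)
  n <- sum(sizes)
  paper <- rep(paste0("paper", seq_len(np)), sizes)

  # realized plant x fungus pool
  grid <- expand.grid(plant = trees$plant$tip.label,
                      fungus = trees$fungal$tip.label,
                      stringsAsFactors = FALSE)
  m <- max(1L, round(config$pair_density * nrow(grid)))
  pool <- grid[sample(nrow(grid), m), , drop = FALSE]
  pick <- pool[sample(m, n, replace = TRUE), ]
  plant <- pick$plant
  fungus <- pick$fungus

  # control sets nested in papers
  cs_of_paper <- pmax(1L, 1L + rpois(np, max(config$control_fanout - 1, 0)))
  control <- unlist(lapply(seq_len(np), function(i)
    paste0("paper", i, "_cs",
           sample.int(cs_of_paper[i], sizes[i], replace = TRUE))))

  # origin clades from tree structure (EM mode)
  origin_of <- function(tree, k) {
    if (k <= 1L || length(tree$tip.label) <= k)
      return(setNames(rep("o1", length(tree$tip.label)), tree$tip.label))
    cl <- cutree(hclust(as.dist(ape::cophenetic.phylo(tree)), "average"), k)
    setNames(paste0("o", cl), names(cl))
  }
  if (config$em_mode) {
    p_origin <- origin_of(trees$plant, config$n_plant_origins)
    f_origin <- origin_of(trees$fungal, config$n_fungal_origins)
    plant_origin <- unname(p_origin[plant])
    fungal_origin <- unname(f_origin[fungus])
  } else {
    plant_origin <- fungal_origin <- rep(NA_character_, n)
  }

  # binary ecological covariates (treatment-level except location, which is
  # a paper-level property, and plant functional group, a species trait)
  loc_of_paper <- sample(c("lab", "field"), np, replace = TRUE)
  pfg_of_plant <- setNames(sample(c("woody", "herbaceous"),
                                  config$n_plants, replace = TRUE),
                           trees$plant$tip.label)
  covars <- data.frame(
    n_fert = sample(c("no", "yes"), n, replace = TRUE),
    p_fert = sample(c("no", "yes"), n, replace = TRUE),
    sterilization = sample(c("no", "yes"), n, replace = TRUE),
    microbial_control = sample(c("no", "yes"), n, replace = TRUE),
    location = rep(loc_of_paper, sizes),
    plant_functional_group = unname(pfg_of_plant[plant]),
    stringsAsFactors = FALSE)

  beta <- config$true_beta
  eta <- rep(unname(beta["(Intercept)"]), n)
  for (p in setdiff(names(beta), "(Intercept)")) {
    if (!p %in% names(covars))
      stop("true_beta names unknown predictor '", p, "'", call. = FALSE)
    second <- sort(unique(covars[[p]]))[2]
    eta <- eta + beta[[p]] * (covars[[p]] == second)
  }

  # random-effect draws
  s2 <- config$true_sigma2
  Rp <- brownian_correlation(trees$plant)
  Rf <- brownian_correlation(trees$fungal)
  pair_lab <- paste(plant, fungus, sep = ":")
  pairs <- unique(data.frame(plant = plant, fungus = fungus))
  Ip <- diag(nrow(Rp)); dimnames(Ip) <- dimnames(Rp)
  If <- diag(nrow(Rf)); dimnames(If) <- dimnames(Rf)
  term_R <- function(term) switch(term,
    plant_phylogeny = Rp,
    fungal_phylogeny = Rf,
    plant_phylogeny_x_fungal_phylogeny = tensor_interaction(Rp, Rf, pairs),
    plant_phylogeny_x_fungal_genus = tensor_interaction(Rp, If, pairs),
    plant_species_x_fungal_phylogeny = tensor_interaction(Ip, Rf, pairs),
    NULL)
  term_levels <- function(term) switch(term,
    plant_phylogeny = , plant_species = plant,
    fungal_phylogeny = , fungal_genus = fungus,
    plant_phylogeny_x_fungal_phylogeny = ,
    plant_phylogeny_x_fungal_genus = ,
    plant_species_x_fungal_phylogeny = ,
    plant_species_x_fungal_genus = pair_lab,
    plant_origin = plant_origin,
    fungal_origin = fungal_origin,
    plant_x_fungal_origin = paste(plant_origin, fungal_origin, sep = ":"),
    study_id = paste0("s", seq_len(n)),
    control_set = control,
    paper = paper,
    stop("unknown random term '", term, "'", call. = FALSE))
  u <- list()
  eta_rand <- numeric(n)
  for (term in names(s2)) {
    if (s2[[term]] <= 0) next
    obs_lev <- term_levels(term)
    R <- term_R(term)
    lev <- if (is.null(R)) sort(unique(obs_lev)) else rownames(R)
    z <- rnorm(length(lev))
    uk <- if (is.null(R)) sqrt(s2[[term]]) * z
          else sqrt(s2[[term]]) * drop(.chol_psd(R) %*% z)
    names(uk) <- lev
    u[[term]] <- uk
    eta_rand <- eta_rand + unname(uk[obs_lev])
  }

  v <- rlnorm(n, config$v_meanlog, config$v_sdlog)
  y <- eta + eta_rand + rnorm(n, 0, sqrt(v))

  reps <- sample(config$reps, n, replace = TRUE)
  mean_inoc <- exp(y)
  sd_half <- sqrt(v * reps / 2)          # per-group CV implying variance v
  sd_inoc <- mean_inoc * sd_half
  sd_ctrl <- 1 * sd_half
  masked <- runif(n) < config$missing_sd_rate
  sd_inoc[masked] <- NA_real_
  sd_ctrl[masked] <- NA_real_

  trials <- data.frame(
    study_id = paste0("s", seq_len(n)),
    paper_id = paper,
    control_set_id = control,
    plant_species = plant,
    fungal_genus = fungus,
    myc_type = if (config$em_mode) "EM" else "AM",
    plant_origin = plant_origin,
    fungal_origin = fungal_origin,
    mean_inoc = mean_inoc, mean_ctrl = 1,
    sd_inoc = sd_inoc, sd_ctrl = sd_ctrl,
    n_inoc = reps, n_ctrl = reps,
    covars,
    stringsAsFactors = FALSE)

  out <- list(trials = trials,
              truth = list(beta = beta, sigma2 = s2, u = u, v = v, y = y,
                           eta_fixed = eta, masked = masked),
              plant_tree = trees$plant, fungal_tree = trees$fungal,
              config = config)
  class(out) <- "myco_sim"
  out
}

#' @export
print.myco_sim <- function(x, ...) {
  cat("Synthetic inoculation-trial dataset: ", nrow(x$trials), " effect ",
      "sizes, ", length(unique(x$trials$plant_species)), " plants, ",
      length(unique(x$trials$fungal_genus)), " fungi, ",
      length(unique(x$trials$paper_id)), " papers (",
      if (x$config$em_mode) "EM" else "AM", " mode, seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk (trial table, trees, truth record)
#'
#' @param sim A \code{\link{simulate_dataset}} result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes \code{trials.csv},
#'   \code{plant_tree.nwk}, \code{fungal_tree.nwk}, \code{truth.json}.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_effects(sim$trials, file.path(dir, "trials.csv"))
  ape::write.tree(sim$plant_tree, file.path(dir, "plant_tree.nwk"))
  ape::write.tree(sim$fungal_tree, file.path(dir, "fungal_tree.nwk"))
  tr <- sim$truth
  jsonlite::write_json(
    list(beta = as.list(tr$beta), sigma2 = as.list(tr$sigma2),
         u = lapply(tr$u, as.list), v = tr$v, y = tr$y),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate-fit-compare recovery experiment
#'
#' Repeatedly simulates a dataset at the configured truth, recomputes
#' effect sizes, rebuilds covariance structures, fits the model by REML,
#' and compares estimates against the truth. Reports per-component bias,
#' RMSE and (optionally) profile-CI coverage, plus the same for the
#' intercept. Deterministic given (config, n_replicates): replicate r uses
#' seed \code{config$seed + r}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_replicates Number of simulate-fit replicates.
#' @param fit_terms Random terms to fit (default: every term with true
#'   variance > 0, plus \code{study_id}).
#' @param fixed Fixed-effects formula for the fit (default intercept-only).
#' @param profile Compute profile CIs and their coverage (slower).
#' @param level CI level.
#' @param ci_control Control list passed to \code{\link{profile_cis}}
#'   (e.g. a looser root tolerance for large batches).
#' @return List of class \code{"myco_recovery"}: \code{components} (data
#'   frame: term, true, median_est, bias, rmse, coverage), \code{intercept}
#'   (true, bias, rmse), \code{estimates} (replicate x term matrix),
#'   \code{cis} (list of CI matrices), \code{n_replicates}.
#' @export
recovery_experiment <- function(config, n_replicates, fit_terms = NULL,
                                fixed = ~1, profile = TRUE, level = 0.95,
                                ci_control = list()) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  if (is.null(fit_terms))
    fit_terms <- union(names(config$true_sigma2)[config$true_sigma2 > 0],
                       "study_id")
  dataset <- if (config$em_mode) "em" else "am_sub"
  est <- matrix(NA_real_, n_replicates, length(fit_terms),
                dimnames = list(NULL, fit_terms))
  b0 <- numeric(n_replicates)
  cover <- matrix(NA, n_replicates, length(fit_terms),
                  dimnames = list(NULL, fit_terms))
  cis <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    sim <- simulate_dataset(cfg_r)
    eff <- suppressWarnings(compute_effect_sizes(sim$trials))
    structs <- build_structures(eff, sim$plant_tree, sim$fungal_tree,
                                dataset = dataset)
    fit <- fit_meta_model(eff, structs, fixed = fixed, mode = "REML",
                          random_terms = fit_terms)
    est[r, ] <- fit$sigma2[fit_terms]
    b0[r] <- unname(fit$beta[1])
    if (profile) {
      ci <- profile_cis(fit, terms = fit_terms, level = level,
                        control = ci_control)
      cis[[r]] <- ci
      truth <- config$true_sigma2[fit_terms]
      truth[is.na(truth)] <- 0
      cover[r, ] <- truth >= ci[, "lower"] & truth <= ci[, "upper"]
    }
  }
  truth <- config$true_sigma2[fit_terms]
  truth[is.na(truth)] <- 0
  comp <- data.frame(
    term = fit_terms,
    true = unname(truth),
    median_est = apply(est, 2, median),
    bias = colMeans(est) - unname(truth),
    rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
    coverage = if (profile) colMeans(cover) else NA_real_,
    row.names = NULL)
  mu0 <- unname(config$true_beta["(Intercept)"])
  out <- list(components = comp,
              intercept = c(true = mu0, bias = mean(b0) - mu0,
                            rmse = sqrt(mean((b0 - mu0)^2))),
              estimates = est, cis = cis, n_replicates = n_replicates,
              level = level, config = config)
  class(out) <- "myco_recovery"
  out
}

#' @export
print.myco_recovery <- function(x, digits = 3, ...) {
  cat("Recovery experiment: ", x$n_replicates, " replicate(s), seed ",
      x$config$seed, "\n", sep = "")
  comp <- x$components
  comp[-1] <- lapply(comp[-1], round, digits)
  print(comp, row.names = FALSE)
  cat("intercept: true ", round(x$intercept["true"], digits), ", bias ",
      round(x$intercept["bias"], digits), ", rmse ",
      round(x$intercept["rmse"], digits), "\n", sep = "")
  invisible(x)
}
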