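test_that("Newick reading validates branch lengths and tips", {
  tr <- read_phylogeny(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  star <- read_phylogeny(text = "(A:1,B:1,C:1);")
  expect_equal(length(star$tip.label), 3L)
  suppressWarnings(expect_error(read_phylogeny(text = "((A:1,B:1")))
  expect_error(read_phylogeny(text = "((A,B),C);"), "branch lengths")
  expect_error(read_phylogeny(text = "((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("Brownian correlation encodes shared path over depth", {
  tr <- small_tree()
  R <- brownian_correlation(tr)
  expect_equal(diag(R), setNames(rep(1, 3), rownames(R)))
  expect_equal(R["A", "B"], 0.5)
  expect_equal(R["A", "C"], 0)
  expect_equal(R["B", "C"], 0)
  star <- read_phylogeny(text = "(A:1,B:1,C:1);")
  expect_equal(unname(brownian_correlation(star)), diag(3))
  # lambda = 0 collapses any tree to the identity
  expect_equal(unname(brownian_correlation(tr, lambda = 0)), diag(3))
  expect_error(brownian_correlation(tr, taxa = c("A", "Z")), "Z")
})

test_that("restricting to a taxon subset equals subsetting the full matrix", {
  set.seed(11)
  for (i in 1:5) {
    tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
    keep <- sort(sample(tr$tip.label, 4))
    R_full <- brownian_correlation(tr)
    R_sub <- brownian_correlation(tr, taxa = keep)
    expect_equal(R_sub, R_full[keep, keep], tolerance = 1e-12)
  }
})

test_that("Brownian correlation matches a path-enumeration oracle", {
  set.seed(12)
  for (i in 1:4) {
    tr <- ape::rtree(6, tip.label = paste0("t", 1:6))  # non-ultrametric too
    R <- brownian_correlation(tr)
    # oracle: shared path = depth of the MRCA from the root, via node depths
    depths <- ape::node.depth.edgelength(tr)
    m <- ape::mrca(tr)
    tipdepth <- max(depths[seq_along(tr$tip.label)])
    for (a in tr$tip.label) for (b in tr$tip.label) {
      expected <- if (a == b) 1 else
        depths[m[a, b]] / tipdepth
      expect_equal(R[a, b], expected, tolerance = 1e-12)
    }
  }
})

test_that("tensor interaction applies the element product rule", {
  Rp <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("p1", "p2"),
                                                     c("p1", "p2")))
  Rf <- diag(2); dimnames(Rf) <- list(c("f1", "f2"), c("f1", "f2"))
  pairs <- expand.grid(plant = c("p1", "p2"), fungus = c("f1", "f2"),
                       stringsAsFactors = FALSE)
  R <- tensor_interaction(Rp, Rf, pairs)
  expect_equal(R["p1:f1", "p2:f1"], 0.5)
  expect_equal(R["p1:f1", "p2:f2"], 0)
  expect_equal(diag(R), setNames(rep(1, 4), rownames(R)))
  # identity x identity = identity over pairs
  Ip <- diag(2); dimnames(Ip) <- dimnames(Rp)
  expect_equal(unname(tensor_interaction(Ip, Rf, pairs)), diag(4))
  # single realized pair -> 1x1
  expect_equal(dim(tensor_interaction(Rp, Rf, pairs[1, ])), c(1L, 1L))
  expect_error(tensor_interaction(Rp, Rf,
                                  data.frame(plant = "p9", fungus = "f1")),
               "p9")
})

test_that("tensor over the full Cartesian set equals the Kronecker product", {
  set.seed(21)
  for (i in 1:4) {
    np <- sample(2:4, 1); nf <- sample(2:4, 1)
    tp <- ape::rcoal(np, tip.label = paste0("p", 1:np))
    tf <- ape::rcoal(nf, tip.label = paste0("f", 1:nf))
    Rp <- brownian_correlation(tp, taxa = paste0("p", 1:np))
    Rf <- brownian_correlation(tf, taxa = paste0("f", 1:nf))
    pairs <- expand.grid(plant = paste0("p", 1:np),
                         fungus = paste0("f", 1:nf),
                         stringsAsFactors = FALSE)
    R <- tensor_interaction(Rp, Rf, pairs)
    # lexicographic (plant, fungus) ordering = kronecker(Rp, Rf)
    K <- kronecker(Rp, Rf)
    expect_equal(unname(R), unname(K), tolerance = 1e-12)
    # PSD: Cholesky passes with at most 1e-10 jitter
    expect_no_error(chol(R + 1e-10 * diag(nrow(R))))
  }
})

test_that("build_structures emits the documented term sets per dataset", {
  sim <- simulate_dataset(sim_config(seed = 5, em_mode = TRUE, n_plants = 3,
                                     n_fungi = 2, n_papers = 2,
                                     mean_effects_per_paper = 6,
                                     n_plant_origins = 2,
                                     n_fungal_origins = 2))
  eff <- suppressWarnings(compute_effect_sizes(sim$trials))
  em <- build_structures(eff, sim$plant_tree, sim$fungal_tree, "em")
  expect_length(em, 14L)
  expect_setequal(names(em), c(
    "plant_phylogeny", "plant_species", "fungal_phylogeny", "fungal_genus",
    "plant_phylogeny_x_fungal_phylogeny", "plant_phylogeny_x_fungal_genus",
    "plant_species_x_fungal_phylogeny", "plant_species_x_fungal_genus",
    "plant_origin", "fungal_origin", "plant_x_fungal_origin",
    "study_id", "control_set", "paper"))
  amf <- build_structures(eff, sim$plant_tree, dataset = "am_full")
  expect_setequal(names(amf), c("plant_phylogeny", "plant_species",
                                "study_id", "control_set", "paper"))
  ams <- build_structures(eff, sim$plant_tree, sim$fungal_tree, "am_sub")
  expect_length(ams, 11L)
  # study term: one level per observation, identity correlation
  Z <- incidence_matrix(em$study_id)
  expect_equal(unname(as.matrix(Z)[, em$study_id$obs_levels]),
               diag(nrow(eff)))
  expect_equal(unname(struct_correlation(em$study_id)), diag(nrow(eff)))
  # missing origins must error in EM mode
  eff2 <- eff; eff2$plant_origin <- NA
  expect_error(build_structures(eff2, sim$plant_tree, sim$fungal_tree, "em"),
               "origin")
})

test_that("cov_structure validates its correlation matrix", {
  R <- matrix(c(1, 0.3, 0.31, 1), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_error(cov_structure("t", R, c("a", "b")), "symmetric")
  R2 <- matrix(c(1.2, 0, 0, 1), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  expect_error(cov_structure("t", R2, c("a", "b")), "unit diagonal")
  expect_error(cov_structure("t", NULL, obs_levels = c("a", "b"))$levels,
               NA)
  s <- cov_structure("t", NULL, c("a", "b", "a"))
  expect_equal(s$levels, c("a", "b"))
  expect_error(
    cov_structure("t", diag(2) |> `dimnames<-`(list(c("a", "b"),
                                                    c("a", "b"))),
                  c("a", "c")), "not in R")
})
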