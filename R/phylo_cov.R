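#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around \code{ape::read.tree} that enforces what the
#' downstream Brownian-motion correlation needs: branch lengths on every
#' edge and unique tip labels. Tip labels are normalised by trimming
#' whitespace and replacing internal spaces with underscores, the same
#' convention applied to taxon labels in the data tables.
#'
#' @param path Path to a Newick file (or a Newick string via \code{text}).
#' @param text Optional Newick string, passed through to
#'   \code{ape::read.tree}.
#' @return An \code{ape} \code{"phylo"} object.
#' @export
read_phylogeny <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree))
    stop("could not parse Newick input", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths; Brownian correlation is undefined",
         call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  tree$tip.label <- normalize_taxa(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels after normalisation: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  tree
}

#' @rdname read_phylogeny
#' @param x Character vector of taxon labels.
#' @export
normalize_taxa <- function(x) {
  x <- trimws(as.character(x))
  gsub("[[:space:]]+", "_", x)
}

#' Brownian-motion phylogenetic correlation matrix
#'
#' Builds the correlation matrix implied by Brownian trait evolution on a
#' tree: entry (i, j) is the shared root-to-MRCA path length of tips i and j
#' divided by the maximum root-to-tip depth, and the diagonal is exactly 1.
#' For an ultrametric tree this is the classical scaled phylogenetic
#' variance-covariance matrix; for a non-ultrametric tree the off-diagonal
#' entries are relative shared branch lengths and raising the diagonal to 1
#' keeps the matrix positive semi-definite. A Pagel's-lambda style
#' multiplier can shrink the off-diagonal entries (\code{lambda = 1} is full
#' Brownian motion, the default; \code{lambda = 0} gives the identity).
#'
#' Shared paths are always measured on the full tree, so restricting to a
#' taxon subset is exactly the row/column subset of the full-tree matrix
#' (the root and depth are not re-defined by pruning).
#'
#' @param tree A \code{"phylo"} object with branch lengths.
#' @param taxa Optional character vector: return the correlation over these
#'   tips only. All must be present in the tree.
#' @param lambda Off-diagonal multiplier in [0, 1].
#' @return Correlation matrix with taxa as dimnames, rows/columns in the
#'   order of \code{taxa} (or the tree's tip order if \code{taxa} is NULL).
#' @export
brownian_correlation <- function(tree, taxa = NULL, lambda = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]", call. = FALSE)
  if (!is.null(taxa)) {
    taxa <- normalize_taxa(taxa)
    missing <- setdiff(unique(taxa), tree$tip.label)
    if (length(missing))
      stop("taxa absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (length(tree$tip.label) == 1L) {
    R <- matrix(1, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    if (!is.null(taxa)) R <- R[taxa, taxa, drop = FALSE]
    return(R)
  }
  C <- ape::vcv.phylo(tree)
  depth <- max(diag(C))
  if (depth <= 0) stop("tree has zero depth", call. = FALSE)
  R <- C / depth
  R[row(R) != col(R)] <- lambda * R[row(R) != col(R)]
  diag(R) <- 1
  if (!is.null(taxa)) R <- R[taxa, taxa, drop = FALSE]
  R
}

#' Tensor-product correlation matrix over realized host-symbiont pairs
#'
#' Correlation structure for a plant-by-fungus interaction random effect:
#' the correlation between pairs (p, f) and (p', f') is the product
#' \code{R_plant[p, p'] * R_fungus[f, f']}. Only the combinations actually
#' observed in the data are materialised (the entries are computed directly
#' from the element product rule, never by forming the full Kronecker
#' product), with rows ordered lexicographically by (plant, fungus).
#'
#' @param R_plant,R_fungus Correlation matrices with taxon dimnames.
#' @param pairs Data frame with columns \code{plant} and \code{fungus}
#'   listing realized combinations (duplicates collapsed), or a character
#'   vector of \code{"plant:fungus"} labels.
#' @return Correlation matrix over the realized pairs, dimnames
#'   \code{"plant:fungus"}.
#' @export
tensor_interaction <- function(R_plant, R_fungus, pairs) {
  if (is.character(pairs)) {
    sp <- strsplit(pairs, ":", fixed = TRUE)
    pairs <- data.frame(plant = vapply(sp, `[`, "", 1L),
                        fungus = vapply(sp, `[`, "", 2L))
  }
  pairs <- unique(data.frame(plant = as.character(pairs$plant),
                             fungus = as.character(pairs$fungus)))
  pairs <- pairs[order(pairs$plant, pairs$fungus), , drop = FALSE]
  bad_p <- setdiff(pairs$plant, rownames(R_plant))
  bad_f <- setdiff(pairs$fungus, rownames(R_fungus))
  if (length(bad_p) || length(bad_f))
    stop("realized pair references unknown level(s): ",
         paste(c(bad_p, bad_f), collapse = ", "), call. = FALSE)
  ip <- match(pairs$plant, rownames(R_plant))
  jf <- match(pairs$fungus, rownames(R_fungus))
  R <- R_plant[ip, ip, drop = FALSE] * R_fungus[jf, jf, drop = FALSE]
  labs <- paste(pairs$plant, pairs$fungus, sep = ":")
  dimnames(R) <- list(labs, labs)
  R
}

#' Construct a named random-effect covariance structure
#'
#' A \code{cov_structure} couples a correlation matrix over the levels of a
#' grouping factor with the observation-to-level map for one random-effect
#' term of the meta-analytic model.
#'
#' @param term Term name (e.g. \code{"plant_phylogeny"}).
#' @param R Symmetric correlation matrix with level labels as dimnames, or
#'   \code{NULL} for an identity correlation over the observed levels.
#' @param obs_levels Character vector, one entry per observation, naming the
#'   level each observation belongs to (\code{NA} = term inapplicable to
#'   that observation).
#' @return An object of class \code{"cov_structure"} with elements
#'   \code{term}, \code{levels}, \code{R}, \code{obs_levels}.
#' @export
cov_structure <- function(term, R = NULL, obs_levels) {
  obs_levels <- as.character(obs_levels)
  if (is.null(R)) {
    lev <- sort(unique(obs_levels[!is.na(obs_levels)]))
    R <- diag(length(lev))
    dimnames(R) <- list(lev, lev)
  }
  lev <- rownames(R)
  if (is.null(lev)) stop("R must carry level labels as dimnames",
                         call. = FALSE)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
    stop("R must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("R must have unit diagonal", call. = FALSE)
  unknown <- setdiff(unique(obs_levels[!is.na(obs_levels)]), lev)
  if (length(unknown))
    stop("term '", term, "': observation level(s) not in R: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(term = term, levels = lev, R = R, obs_levels = obs_levels),
            class = "cov_structure")
}

#' @export
print.cov_structure <- function(x, ...) {
  ident <- isTRUE(all.equal(unname(x$R), diag(length(x$levels)),
                            tolerance = 1e-12))
  cat("cov_structure '", x$term, "': ", length(x$levels), " level(s), ",
      sum(!is.na(x$obs_levels)), " mapped observation(s), ",
      if (ident) "identity" else "structured", " correlation\n", sep = "")
  invisible(x)
}

#' Sparse incidence matrix of a covariance structure
#'
#' @param struct A \code{cov_structure}.
#' @param n Number of observations (defaults to
#'   \code{length(struct$obs_levels)}).
#' @return Sparse n-by-q incidence matrix Z (one 1 per mapped observation).
#' @export
incidence_matrix <- function(struct, n = length(struct$obs_levels)) {
  j <- match(struct$obs_levels, struct$levels)
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = which(keep), j = j[keep], x = 1,
                       dims = c(n, length(struct$levels)),
                       dimnames = list(NULL, struct$levels))
}

#' Build all applicable random-effect covariance structures for a dataset
#'
#' Assembles the full list of random-effect terms for one analysis subset:
#'
#' \itemize{
#'   \item the 11 shared terms: \code{plant_phylogeny} (Brownian correlation),
#'     \code{plant_species} (identity), \code{fungal_phylogeny},
#'     \code{fungal_genus}, the four plant-by-fungus interaction terms
#'     (tensor products of the corresponding marginal correlations, identity
#'     where both margins are non-phylogenetic), \code{study_id} (one level
#'     per observation; the residual between-studies heterogeneity, always
#'     included in model fits), \code{control_set}, \code{paper};
#'   \item for \code{dataset = "em"}, the three additional evolutionary
#'     origin terms \code{plant_origin}, \code{fungal_origin},
#'     \code{plant_x_fungal_origin} (identity correlation over origin
#'     clades and clade combinations) for 14 terms total;
#'   \item for \code{dataset = "am_full"}, only the 5 terms not involving
#'     fungal identity (\code{plant_phylogeny}, \code{plant_species},
#'     \code{study_id}, \code{control_set}, \code{paper}), since AM-full
#'     rows may carry multi-genus inocula.
#' }
#'
#' @param effects Effect-size table (\code{\link{compute_effect_sizes}})
#'   carrying the grouping labels.
#' @param plant_tree,fungal_tree \code{"phylo"} objects; \code{fungal_tree}
#'   may be \code{NULL} for \code{dataset = "am_full"}.
#' @param dataset One of \code{"am_sub"}, \code{"em"}, \code{"am_full"}.
#' @param lambda Off-diagonal Brownian multiplier (default 1).
#' @return Named list of \code{\link{cov_structure}} objects.
#' @export
build_structures <- function(effects, plant_tree, fungal_tree = NULL,
                             dataset = c("am_sub", "em", "am_full"),
                             lambda = 1) {
  dataset <- match.arg(dataset)
  effects <- as.data.frame(effects)
  n <- nrow(effects)
  plants <- normalize_taxa(effects$plant_species)
  Rp <- brownian_correlation(plant_tree, taxa = sort(unique(plants)),
                             lambda = lambda)
  out <- list(
    plant_phylogeny = cov_structure("plant_phylogeny", Rp, plants),
    plant_species   = cov_structure("plant_species", NULL, plants)
  )
  if (dataset != "am_full") {
    fungi <- normalize_taxa(effects$fungal_genus)
    if (anyNA(fungi))
      stop(dataset, " rows must each carry a single fungal genus",
           call. = FALSE)
    if (is.null(fungal_tree))
      stop("fungal_tree is required for ", dataset, call. = FALSE)
    Rf <- brownian_correlation(fungal_tree, taxa = sort(unique(fungi)),
                               lambda = lambda)
    pair_lab <- paste(plants, fungi, sep = ":")
    pairs <- unique(data.frame(plant = plants, fungus = fungi))
    Ip <- diag(nrow(Rp)); dimnames(Ip) <- dimnames(Rp)
    If <- diag(nrow(Rf)); dimnames(If) <- dimnames(Rf)
    out <- c(out, list(
      fungal_phylogeny = cov_structure("fungal_phylogeny", Rf, fungi),
      fungal_genus     = cov_structure("fungal_genus", NULL, fungi),
      plant_phylogeny_x_fungal_phylogeny = cov_structure(
        "plant_phylogeny_x_fungal_phylogeny",
        tensor_interaction(Rp, Rf, pairs), pair_lab),
      plant_phylogeny_x_fungal_genus = cov_structure(
        "plant_phylogeny_x_fungal_genus",
        tensor_interaction(Rp, If, pairs), pair_lab),
      plant_species_x_fungal_phylogeny = cov_structure(
        "plant_species_x_fungal_phylogeny",
        tensor_interaction(Ip, Rf, pairs), pair_lab),
      plant_species_x_fungal_genus = cov_structure(
        "plant_species_x_fungal_genus", NULL, pair_lab)
    ))
  }
  if (dataset == "em") {
    po <- effects$plant_origin
    fo <- effects$fungal_origin
    if (is.null(po) || is.null(fo) || anyNA(po) || anyNA(fo))
      stop("EM dataset requires complete plant_origin and fungal_origin labels",
           call. = FALSE)
    out <- c(out, list(
      plant_origin  = cov_structure("plant_origin", NULL, po),
      fungal_origin = cov_structure("fungal_origin", NULL, fo),
      plant_x_fungal_origin = cov_structure(
        "plant_x_fungal_origin", NULL, paste(po, fo, sep = ":"))
    ))
  }
  out <- c(out, list(
    study_id    = cov_structure("study_id", NULL,
                                as.character(effects$study_id)),
    control_set = cov_structure("control_set", NULL,
                                as.character(effects$control_set_id)),
    paper       = cov_structure("paper", NULL,
                                as.character(effects$paper_id))
  ))
  out
}

#' Export a correlation matrix with level labels
#'
#' @param struct A \code{cov_structure}.
#' @param path Output path (delimiter by extension: .tsv/.txt tab, else
#'   comma).
#' @export
write_cov_matrix <- function(struct, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(level = rownames(struct$R), struct$R,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
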