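# Felsenstein pruning pass over a binary tree, vectorised over columns of
# the tip-value matrix X (tips x m, rownames = tip labels). Returns nodal
# values, raw contrasts, and contrast variances (sums of adjusted branch
# lengths). Used both for independent contrasts and for the D statistic's
# nodal state estimates.
prune_pass <- function(tree, X) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    abort("pruning pass requires a rooted binary tree.")
  }
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(names(X), NULL))
  if (is.null(rownames(X))) abort("tip values must be named by tip label.")
  miss <- setdiff(tree$tip.label, rownames(X))
  if (length(miss) > 0) {
    abort(paste0("tip values missing for: ", paste(miss, collapse = ", ")))
  }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  m <- ncol(X)

  val <- matrix(NA_real_, ntip + nnode, m)
  val[seq_len(ntip), ] <- X[tr$tip.label, , drop = FALSE]
  el <- numeric(ntip + nnode)
  el[tr$edge[, 2]] <- tr$edge.length
  el0 <- el # original lengths, for node ages (el gains pruning extensions)

  kids <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tr$edge[e, 2])
  }
  node_order <- unique(tr$edge[, 1]) # postorder: children appear first

  contrast <- matrix(NA_real_, nnode, m)
  cvar <- numeric(nnode)
  ntips_below <- c(rep(1L, ntip), integer(nnode))
  mean_depth <- numeric(ntip + nnode)
  max_depth <- numeric(ntip + nnode)

  for (nd in node_order) {
    k <- kids[[nd]]
    b1 <- el[k[1]]; b2 <- el[k[2]]
    row <- nd - ntip
    contrast[row, ] <- val[k[1], ] - val[k[2], ]
    cvar[row] <- b1 + b2
    if (b1 + b2 <= 0) {
      val[nd, ] <- (val[k[1], ] + val[k[2], ]) / 2
    } else {
      val[nd, ] <- (b2 * val[k[1], ] + b1 * val[k[2], ]) / (b1 + b2)
      el[nd] <- el[nd] + b1 * b2 / (b1 + b2)
    }
    n1 <- ntips_below[k[1]]; n2 <- ntips_below[k[2]]
    ntips_below[nd] <- n1 + n2
    o1 <- el0[k[1]]; o2 <- el0[k[2]]
    mean_depth[nd] <- (n1 * (mean_depth[k[1]] + o1) + n2 * (mean_depth[k[2]] + o2)) / (n1 + n2)
    max_depth[nd] <- max(max_depth[k[1]] + o1, max_depth[k[2]] + o2)
  }
  list(
    node = node_order,
    values = val[node_order, , drop = FALSE],
    contrasts = contrast[node_order - ntip, , drop = FALSE],
    var = cvar[node_order - ntip],
    mean_age = mean_depth[node_order],
    max_age = max_depth[node_order]
  )
}

#' Transform branch lengths by a power kappa
#'
#' Every branch length `b` becomes `b^kappa`. `kappa = 1` is the identity;
#' `kappa = 0` maps every positive branch to 1 (with the convention
#' `0^0 = 0`, so zero-length branches stay zero); `kappa < 1` compresses
#' long branches relative to short ones. Used to tune contrast
#' standardization so that contrast magnitude is uncorrelated with its
#' standard deviation.
#'
#' @param tree A `phylo`.
#' @param kappa Exponent, `>= 0` (bounded at 3 in the optimizer).
#' @return The transformed `phylo`.
#' @export
kappa_transform <- function(tree, kappa) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0) {
    abort("`kappa` must be a single number >= 0.")
  }
  b <- tree$edge.length
  tree$edge.length <- ifelse(b > 0, b^kappa, 0)
  tree
}

#' Phylogenetically independent contrasts
#'
#' Standard pruning-pass contrasts: at each internal node the two daughter
#' values are differenced, the nodal value is the branch-length-weighted
#' average of the daughters, and the branch below the node is extended by
#' `b1*b2/(b1+b2)`. The contrast standard deviation is the square root of
#' the summed (adjusted) daughter branch lengths; the standardized
#' contrast is the raw contrast divided by its SD. Zero-length branches
#' that would give a zero SD are perturbed by `1e-8 * tree depth` with a
#' warning.
#'
#' @param tree Rooted binary `phylo`.
#' @param trait Named numeric vector of tip values.
#' @param kappa Optional branch-length exponent applied before the pass.
#' @return A tibble of class `fc_contrasts`: one row per internal node with
#'   `node`, `nodal_value`, `contrast` (signed), `sd`, `std_contrast`
#'   (signed), `abs_std_contrast`, `age_mean`, `age_max`; the kappa used is
#'   stored as an attribute.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' independent_contrasts(tr, c(A = 0, B = 2, C = 1))
independent_contrasts <- function(tree, trait, kappa = 1) {
  tree <- validate_phylogeny(tree)
  if (kappa != 1) tree <- kappa_transform(tree, kappa)
  if (any(tree$edge.length == 0)) {
    depth <- max(ape::node.depth.edgelength(tree))
    warn("zero-length branches perturbed to keep contrast SDs positive.")
    tree$edge.length[tree$edge.length == 0] <- 1e-8 * max(depth, 1)
  }
  pp <- prune_pass(tree, trait)
  if (any(pp$var <= 0)) abort("zero contrast variance after branch adjustment.")
  out <- tibble(
    node = pp$node,
    nodal_value = pp$values[, 1],
    contrast = pp$contrasts[, 1],
    sd = sqrt(pp$var),
    std_contrast = pp$contrasts[, 1] / sqrt(pp$var),
    abs_std_contrast = abs(pp$contrasts[, 1]) / sqrt(pp$var),
    age_mean = pp$mean_age,
    age_max = pp$max_age
  )
  structure(out, class = c("fc_contrasts", class(out)), kappa = kappa)
}

#' Optimize the kappa branch-length exponent
#'
#' Finds the kappa in `[0, 3]` minimising the absolute Pearson correlation
#' between absolute standardized contrasts and their standard deviations
#' (the standardization diagnostic): under a well-standardized Brownian
#' model the two are uncorrelated, while labile traits show
#' overstandardization (contrasts shrinking at deeper nodes) that a
#' kappa < 1 corrects. A 0.01-step grid scan is followed by local
#' refinement; ties go to the smallest kappa.
#'
#' @inheritParams independent_contrasts
#' @param bounds Search interval for kappa.
#' @param step Grid step for the initial scan.
#' @return List with `kappa`, `objective` (the minimised |r|), and
#'   `degenerate` (TRUE when the correlation is undefined, e.g. all SDs
#'   equal).
#' @export
optimize_kappa <- function(tree, trait, bounds = c(0, 3), step = 0.01) {
  tree <- validate_phylogeny(tree)
  obj <- function(k) {
    cs <- suppressWarnings(independent_contrasts(tree, trait, kappa = k))
    if (stats::sd(cs$sd) == 0 || stats::sd(cs$abs_std_contrast) == 0) return(NA_real_)
    abs(stats::cor(cs$abs_std_contrast, cs$sd))
  }
  nnode <- tree$Nnode
  if (nnode < 6L) abort("kappa optimization needs at least 6 contrasts.")
  grid <- seq(bounds[1], bounds[2], by = step)
  vals <- vapply(grid, obj, numeric(1))
  if (all(is.na(vals))) {
    return(list(kappa = 1, objective = NA_real_, degenerate = TRUE))
  }
  i <- which.min(vals) # first minimum -> smallest kappa on ties
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  ref <- optimize(function(k) {
    v <- obj(k)
    if (is.na(v)) Inf else v
  }, c(lo, hi))
  if (is.finite(ref$objective) && ref$objective < vals[i] - 1e-12) {
    list(kappa = ref$minimum, objective = ref$objective, degenerate = FALSE)
  } else {
    list(kappa = grid[i], objective = vals[i], degenerate = FALSE)
  }
}

#' Node-age versus divergence regression with outlier flagging
#'
#' Plots-ready summary of where in the tree trait divergence happened:
#' absolute standardized contrasts (on the kappa-transformed tree) are
#' regressed on node age through the origin, and nodes whose externally
#' studentized residual exceeds 3 in absolute value are flagged as having
#' diverged more than expected from their age. Node age is the mean path
#' length from the node to its descendant tips in the transformed tree
#' (transformed trees need not be ultrametric; `age_method = "max"` uses
#' the longest path instead).
#'
#' @inheritParams independent_contrasts
#' @param kappa Exponent; `NULL` optimizes it with [optimize_kappa()].
#' @param age_method `"mean"` or `"max"` node-to-tip path length.
#' @return An `fc_contrasts` tibble with an added `outlier` column and
#'   attributes `kappa`, `slope` (through-origin least squares) and
#'   `residuals` (externally studentized).
#' @export
node_age_divergence <- function(tree, trait, kappa = NULL, age_method = c("mean", "max")) {
  age_method <- match.arg(age_method)
  tree <- validate_phylogeny(tree)
  if (tree$Nnode < 3L) abort("need at least 3 internal nodes.")
  if (is.null(kappa)) kappa <- optimize_kappa(tree, trait)$kappa
  cs <- suppressWarnings(independent_contrasts(tree, trait, kappa = kappa))
  age <- if (age_method == "mean") cs$age_mean else cs$age_max
  y <- cs$abs_std_contrast
  fit <- lm(y ~ 0 + age)
  rs <- rstudent(fit)
  cs$age <- age
  cs$outlier <- abs(rs) > 3 & !is.na(rs)
  structure(
    cs,
    class = class(cs),
    kappa = kappa,
    slope = unname(coef(fit)[1]),
    residuals = unname(rs)
  )
}
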