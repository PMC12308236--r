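#' @useDynLib phyloprev, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median var quantile rnorm runif rbinom qnorm qbeta pbinom
#'   dbinom plogis qlogis acf ks.test setNames rnbinom cor sd
#' @importFrom utils read.csv write.csv head
NULL

#' Normalize species labels for tip matching
#'
#' Trims whitespace and maps spaces to underscores so that CSV species names
#' and Newick tip labels compare equal across the common dialects.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  gsub(" ", "_", trimws(x), fixed = TRUE)
}

#' Read and validate an ultrametric phylogenetic tree
#'
#' Parses a Newick file (or string) with branch lengths on every edge,
#' validates tip labels and ultrametricity, and optionally rescales the tree
#' to unit depth. The returned object is an [ape::phylo] tree carrying a few
#' extra attributes (`depth`, `normalized`) and class `phylo_tree`.
#'
#' Ultrametricity is checked as (max tip depth - min tip depth) / depth
#' <= `ultra_tol`; near-ultrametric consensus trees pass but tip depths are
#' never silently stretched.
#'
#' @param path path to a Newick file, or a Newick string (must end in ";").
#' @param normalize_depth divide all branch lengths by the tree depth so the
#'   root-to-tip height is 1. Recommended before fitting so the OU rate alpha
#'   is comparable across datasets. Default `TRUE`.
#' @param ultra_tol relative tolerance on tip-depth spread (default 1e-3).
#' @return a `phylo_tree` object.
#' @export
read_newick <- function(path, normalize_depth = TRUE, ultra_tol = 1e-3) {
  txt <- if (file.exists(path)) paste(readLines(path, warn = FALSE), collapse = "") else path
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                   error = function(e) stop("Newick parse failure: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: no tree found in input")
  validate_tree(tree, normalize_depth = normalize_depth, ultra_tol = ultra_tol)
}

#' Validate a phylo object as an ultrametric analysis tree
#'
#' @param tree an [ape::phylo] object.
#' @inheritParams read_newick
#' @return the validated (optionally depth-normalized) `phylo_tree`.
#' @export
validate_tree <- function(tree, normalize_depth = FALSE, ultra_tol = 1e-3) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge))
    stop("tree has missing branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has negative or NA branch lengths")
  labs <- normalize_label(tree$tip.label)
  if (any(labs == "")) stop("tree has empty tip labels")
  if (anyDuplicated(labs)) {
    dup <- labs[duplicated(labs)][1L]
    stop("duplicate tip label: ", dup)
  }
  tree$tip.label <- labs
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  depth <- max(depths)
  if (depth <= 0) stop("tree depth must be positive")
  spread <- (max(depths) - min(depths)) / depth
  if (spread > ultra_tol) {
    i <- which.max(depths); j <- which.min(depths)
    stop(sprintf(
      "tree not ultrametric within tolerance %g: tip '%s' depth %.6g vs tip '%s' depth %.6g",
      ultra_tol, tree$tip.label[i], depths[i], tree$tip.label[j], depths[j]))
  }
  if (normalize_depth) {
    tree$edge.length <- tree$edge.length / depth
    attr(tree, "normalized") <- TRUE
    depth <- 1
  } else {
    attr(tree, "normalized") <- FALSE
  }
  attr(tree, "depth") <- depth
  class(tree) <- unique(c("phylo_tree", class(tree)))
  tree
}

#' Tree depth (root-to-tip height)
#' @param tree a validated `phylo_tree`.
#' @return numeric depth.
#' @export
tree_depth <- function(tree) {
  d <- attr(tree, "depth")
  if (is.null(d)) d <- max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  d
}

#' Shared-path (root-to-MRCA) time matrix
#'
#' Returns the S x S matrix of shared evolutionary times t_ij: the distance
#' from the root to the most recent common ancestor of tips i and j. The
#' diagonal holds tip depths. On an ultrametric tree t_ij = depth - d_ij / 2,
#' where d_ij is the patristic distance. This is the Brownian-motion
#' variance-covariance matrix of the tree and is the raw ingredient of every
#' correlation structure here.
#'
#' @param tree a validated `phylo_tree`.
#' @return symmetric numeric matrix with species labels as dimnames.
#' @export
shared_path_times <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  v <- ape::vcv(tree)
  v[v < 0] <- 0 # guard fp noise
  v
}

new_correlation_structure <- function(mat, family, parameter = NULL) {
  structure(list(labels = rownames(mat), matrix = mat, family = family,
                 parameter = parameter),
            class = "correlation_structure")
}

#' @export
print.correlation_structure <- function(x, ...) {
  cat(sprintf("correlation_structure: %s, %d species", x$family, length(x$labels)))
  if (!is.null(x$parameter)) cat(sprintf(", parameter = %.4g", x$parameter))
  cat("\n")
  invisible(x)
}

#' Ornstein-Uhlenbeck phylogenetic correlation matrix
#'
#' Root-anchored non-stationary OU covariance on an ultrametric tree of depth
#' T with unit diffusion:
#' \deqn{V_{ij} = \frac{1}{2\alpha} e^{-2\alpha (T - t_{ij})} (1 - e^{-2\alpha t_{ij}})}
#' normalized by its constant diagonal \eqn{V_{ii} = (1 - e^{-2\alpha T})/(2\alpha)}
#' to a correlation matrix. As alpha tends to 0 this converges to the Brownian
#' correlation \eqn{t_{ij}/T}; large alpha erases phylogenetic correlation
#' (identity limit).
#'
#' @param tree validated ultrametric `phylo_tree`.
#' @param alpha OU selection/decay rate, >= 0 (units 1/time of the tree; fit
#'   depth-normalized trees so alpha is comparable across datasets).
#' @return a `correlation_structure` with family `"OU"`.
#' @export
ou_correlation <- function(tree, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0) stop("alpha must be a single value >= 0")
  tmat <- shared_path_times(tree)
  T <- tree_depth(tree)
  R <- ou_matrix_from_times(tmat, T, alpha)
  dimnames(R) <- dimnames(tmat)
  new_correlation_structure(R, "OU", alpha)
}

# Correlation matrix from a shared-path-time matrix; BM limit below alpha_eps.
ou_matrix_from_times <- function(tmat, depth, alpha, alpha_eps = 1e-8) {
  if (alpha <= alpha_eps) {
    R <- tmat / depth
  } else {
    denom <- 1 - exp(-2 * alpha * depth)
    R <- exp(-2 * alpha * (depth - tmat)) * (1 - exp(-2 * alpha * tmat)) / denom
  }
  diag(R) <- 1
  R
}

#' Pagel's-lambda phylogenetic correlation matrix
#'
#' Scales the off-diagonal Brownian correlations by lambda in \[0, 1\]:
#' R_ij = lambda * t_ij / T for i != j, unit diagonal. lambda = 0 is a star
#' phylogeny (no signal), lambda = 1 is Brownian motion.
#'
#' @param tree validated ultrametric `phylo_tree`.
#' @param lam Pagel's lambda in \[0, 1\].
#' @return a `correlation_structure` with family `"LAMBDA"`.
#' @export
lambda_correlation <- function(tree, lam) {
  if (length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  tmat <- shared_path_times(tree)
  R <- lam * tmat / tree_depth(tree)
  diag(R) <- 1
  dimnames(R) <- dimnames(tmat)
  new_correlation_structure(R, "LAMBDA", lam)
}

#' Brownian-motion correlation matrix
#' @inheritParams ou_correlation
#' @return a `correlation_structure` with family `"BM"`.
#' @export
bm_correlation <- function(tree) {
  tmat <- shared_path_times(tree)
  R <- tmat / tree_depth(tree)
  diag(R) <- 1
  new_correlation_structure(R, "BM")
}

#' Minimal diagonal jitter for a Cholesky-stable matrix
#'
#' Tries Cholesky on the matrix as given, then with diagonal inflation
#' epsilon on a ladder 1e-10, 1e-9, ... up to `max_jitter`, and returns the
#' first success. Errors if none works.
#'
#' @param mat symmetric matrix.
#' @param max_jitter largest diagonal inflation tried (default 1e-6).
#' @return the (possibly jittered) matrix, with attribute `"jitter"` holding
#'   the epsilon used (0 when none was needed).
#' @export
nearest_pd_jitter <- function(mat, max_jitter = 1e-6) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat))))
    stop("matrix is not symmetric")
  eps_ladder <- c(0, 10^seq(-10, log10(max_jitter), by = 1))
  eps_ladder <- eps_ladder[eps_ladder <= max_jitter]
  for (eps in eps_ladder) {
    m <- mat
    if (eps > 0) diag(m) <- diag(m) + eps
    ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
    if (ok) {
      attr(m, "jitter") <- eps
      return(m)
    }
  }
  stop("matrix not positive definite within max_jitter = ", max_jitter)
}

#' Export a correlation structure as labelled CSV
#' @param x a `correlation_structure`.
#' @param path output CSV path.
#' @export
write_correlation_csv <- function(x, path) {
  stopifnot(inherits(x, "correlation_structure"))
  df <- as.data.frame(x$matrix)
  df <- cbind(species = x$labels, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
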