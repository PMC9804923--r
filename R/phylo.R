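#' Read a species tree from a newick file
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string, used instead of `path`.
#' @return An `ape::phylo` tree. Duplicate tip labels are an error.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(file = path)
  if (is.null(tree)) stop("malformed newick input", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' Resolve polytomies at random, reproducibly
#'
#' Multifurcations are broken into a random sequence of bifurcations. The
#' result is a deterministic function of the tree and the seed; the tip set
#' is unchanged and an already-binary tree passes through untouched.
#'
#' @param tree An `ape::phylo` tree.
#' @param seed Integer seed (mandatory: the resolution is recorded in run
#'   metadata so the analysis is reproducible).
#' @return A strictly bifurcating `ape::phylo` tree.
#' @export
resolve_polytomies <- function(tree, seed) {
  stopifnot(inherits(tree, "phylo"), is.numeric(seed), length(seed) == 1L)
  if (is_binary_rooted(tree)) return(tree)
  out <- local_seed(as.integer(seed), ape::multi2di(tree, random = TRUE))
  stopifnot(is_binary_rooted(out),
            setequal(out$tip.label, tree$tip.label))
  out
}

# "binary" for our purposes means a strictly bifurcating *rooted* tree;
# ape calls an unrooted basal trifurcation binary, which is not enough here
is_binary_rooted <- function(tree) {
  ape::is.binary(tree) && ape::is.rooted(tree)
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Grafen branch lengths
#'
#' Assigns each internal node a height of (number of descendant tips - 1) /
#' (total tips - 1), raised to the power `rho`, with tips at height 0, so the
#' tree becomes ultrametric with unit depth. Branch lengths are parent height
#' minus child height.
#'
#' @param tree A binary rooted `ape::phylo` tree.
#' @param rho Power applied to relative node heights (default 1, the
#'   conventional Grafen scaling).
#' @return The tree with Grafen branch lengths (ultrametric, depth 1).
#' @export
grafen_lengths <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) {
    stop("Grafen scaling is degenerate on a single-tip tree", call. = FALSE)
  }
  if (!is_binary_rooted(tree)) {
    stop("tree must be binary and rooted; resolve polytomies first",
         call. = FALSE)
  }
  out <- ape::compute.brlen(tree, method = "Grafen", power = rho)
  stopifnot(is_ultrametric_depth1(out))
  out
}

is_ultrametric_depth1 <- function(tree, tol = 1e-10) {
  depths <- ape::node.depth.edgelength(tree)
  tips <- seq_along(tree$tip.label)
  all(abs(depths[tips] - 1) < tol)
}

#' Phylogenetic correlation matrix
#'
#' For an ultrametric unit-depth tree, the expected correlation of two
#' species' effects under Brownian evolution is the shared root-to-MRCA path
#' length, i.e. `1 - height(MRCA)` under Grafen scaling. The diagonal is 1.
#'
#' @param tree Ultrametric, unit-depth `ape::phylo` (from
#'   [grafen_lengths()]).
#' @return Symmetric positive semi-definite correlation matrix with
#'   dimnames = tip labels.
#' @export
phylo_correlation <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (!is_ultrametric_depth1(tree)) {
    stop("tree must be ultrametric with depth 1 (apply grafen_lengths first)",
         call. = FALSE)
  }
  A <- ape::vcv(tree, corr = TRUE)
  A <- (A + t(A)) / 2
  stopifnot(all(abs(diag(A) - 1) < 1e-8),
            all(A >= -1e-10), all(A <= 1 + 1e-10))
  check_psd(A, what = "phylogenetic correlation matrix")
  A
}

check_psd <- function(M, tol = 1e-8, what = "matrix") {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(what, " is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sampling variance-covariance matrix with shared-treatment correlation
#'
#' Stepwise comparisons re-use interior temperature groups, so the sampling
#' errors of consecutive effects are correlated. The matrix has each effect's
#' sampling variance on the diagonal and
#' `r_shared * sqrt(v_i v_j)` off the diagonal for every pair of effects that
#' shares a treatment group (determined from `group_id_lo` / `group_id_hi`);
#' all other entries are zero. The default `r_shared = 0.5` is a conservative
#' convention for the error correlation induced by a shared group.
#'
#' @param effects Effect-size table from [build_effects()] /
#'   [stepwise_effects()] (columns `variance`, `group_id_lo`, `group_id_hi`).
#' @param r_shared Correlation applied to sharing pairs (default 0.5).
#' @return k x k matrix `V`, with `attr(V, "r_shared")` recording the value
#'   used. An error is raised (not silently repaired) if the result is not
#'   positive semi-definite within tolerance.
#' @export
build_sampling_vcv <- function(effects, r_shared = 0.5) {
  stopifnot(is.data.frame(effects), all(effects$variance > 0))
  k <- nrow(effects)
  V <- diag(effects$variance, k, k)
  if (r_shared != 0 && k > 1L &&
      !is.null(effects$group_id_lo) && !is.null(effects$group_id_hi)) {
    gid <- c(effects$group_id_lo, effects$group_id_hi)
    eff <- rep(seq_len(k), 2L)
    for (members in split(eff, gid)) {
      members <- unique(members)
      if (length(members) > 1L) {
        for (a in seq_len(length(members) - 1L)) {
          for (b in (a + 1L):length(members)) {
            i <- members[a]; j <- members[b]
            V[i, j] <- V[j, i] <-
              r_shared * sqrt(effects$variance[i] * effects$variance[j])
          }
        }
      }
    }
  }
  check_psd(V, what = "sampling variance-covariance matrix")
  dimnames(V) <- list(effects$effect_id, effects$effect_id)
  attr(V, "r_shared") <- r_shared
  V
}

#' Match dataset species to tree tips
#'
#' Species names are matched to tip labels after trimming whitespace and
#' replacing spaces with underscores (the newick convention). Any dataset
#' species missing from the tree is a hard error listing the offenders.
#'
#' @param species Character vector of species names (one per effect).
#' @param tree `ape::phylo`.
#' @return Character vector of matched tip labels, same length as `species`.
#' @export
match_species_to_tips <- function(species, tree) {
  norm <- gsub(" ", "_", trimws(species))
  tips <- tree$tip.label
  missing <- setdiff(unique(norm), tips)
  if (length(missing)) {
    stop("species missing from the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  norm
}
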