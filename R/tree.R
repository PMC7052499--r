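#' Neighbor-joining / BioNJ starting tree from a distance matrix
#'
#' Thin wrapper around the canonical agglomerative algorithms (`ape::nj`,
#' `ape::bionj`) that enforces the contracts used downstream: the matrix must
#' be finite and symmetric with a zero diagonal (matrices flagged non-finite
#' by [distance_matrix()] are refused), and negative branch-length estimates
#' are floored at 0, with the number of floored branches recorded in the
#' attribute `n_negative_floored`.
#'
#' @param D Distance matrix (substitutions/site), n >= 3.
#' @param variant `"nj"` or `"bionj"`.
#' @return Unrooted `ape::phylo` tree with n leaves.
#' @export
neighbor_joining <- function(D, variant = c("nj", "bionj")) {
  variant <- match.arg(variant)
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tree <- if (variant == "nj") ape::nj(D) else ape::bionj(D)
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "n_negative_floored") <- sum(neg)
  tree
}

encode_alignment <- function(a) {
  a <- as_alignment(a)
  if (!all(a %in% DNA_STATES)) {
    stop("alignment must be gap-free A/C/G/T; apply complete_deletion() first")
  }
  idx <- matrix(match(a, DNA_STATES), nrow(a), ncol(a),
                dimnames = dimnames(a))
  # collapse identical site patterns; likelihood is a pattern-weighted sum
  key <- apply(idx, 2, paste, collapse = ".")
  first <- !duplicated(key)
  list(patterns = idx[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]))
}

#' Log likelihood of a tree by Felsenstein pruning
#'
#' Post-order accumulation of per-site partial likelihoods under a TN93
#' model with uniform rates across sites, over compressed site patterns. The
#' value is invariant under leaf reordering and (by reversibility) under
#' re-rooting of the unrooted topology.
#'
#' @param tree `ape::phylo` with branch lengths; leaf labels must match the
#'   alignment's sequence names exactly.
#' @param a Gap-free alignment.
#' @param model A [tn93_model()].
#' @return The log likelihood (finite for valid inputs).
#' @export
tree_log_likelihood <- function(tree, a, model) {
  enc <- encode_alignment(a)
  prune_loglik(tree, enc, model)
}

prune_loglik <- function(tree, enc, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "tn93_model"))
  if (!setequal(tree$tip.label, rownames(enc$patterns))) {
    stop("tree leaf labels do not match alignment names")
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(enc$patterns)
  patt <- enc$patterns[tree$tip.label, , drop = FALSE]
  partial <- vector("list", nnode)
  for (tip in seq_len(ntip)) {
    L <- matrix(0, npat, 4L)
    L[cbind(seq_len(npat), patt[tip, ])] <- 1
    partial[[tip]] <- L
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    P <- tn93_probability(model, tree$edge.length[e])
    contrib <- partial[[child]] %*% t(P)
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                         else partial[[parent]] * contrib
  }
  root <- ntip + 1L
  site <- as.vector(partial[[root]] %*% model$freqs)
  if (any(site <= 0)) return(-Inf)
  sum(enc$weights * log(site))
}

# one full pass of per-branch 1-D likelihood maximization (Brent bracketing
# via stats::optimize, tolerance `tol`); repeated until the pass gains < gain_tol
optimize_branch_lengths <- function(tree, enc, model, tol = 1e-6,
                                    gain_tol = 1e-6, max_pass = 20L,
                                    upper = 10) {
  cur <- prune_loglik(tree, enc, model)
  for (pass in seq_len(max_pass)) {
    before <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tree$edge.length[e] <- t
        prune_loglik(tree, enc, model)
      }
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = tol)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - before < gain_tol) break
  }
  list(tree = tree, loglik = cur)
}

# internal edges eligible for NNI: child is an internal node
nni_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  which(tree$edge[, 2] > ntip)
}

# the two NNI neighbors around internal edge `e` = (u, v): exchange one child
# subtree of v with one sibling subtree of v (rewiring preserves branch
# lengths; lengths travel with their child subtree)
nni_neighbors_at <- function(tree, e) {
  u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
  vkids <- tree$edge[tree$edge[, 1] == v, 2]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  w <- sibs[1]
  lapply(vkids[1:2], function(x) {
    t2 <- tree
    t2$edge[t2$edge[, 2] == x & t2$edge[, 1] == v, 1] <- u
    t2$edge[t2$edge[, 2] == w & t2$edge[, 1] == u, 1] <- v
    attr(t2, "order") <- NULL
    stats::reorder(t2, "postorder")
  })
}

#' Maximum-likelihood tree search
#'
#' Hill-climbing ML search: starting from one or more trees (by default the
#' NJ and BioNJ trees on the TN93 distance matrix), branch lengths are
#' optimized one at a time by bracketed 1-D maximization (tolerance 1e-6),
#' then nearest-neighbor-interchange (NNI) rearrangements are scored with
#' their central branch re-optimized; the best improving move is accepted and
#' the cycle repeats until no move improves the log likelihood by more than
#' 1e-4. The best result across starts is returned; its log likelihood is
#' never below that of any start.
#'
#' @param a Gap-free alignment.
#' @param model A [tn93_model()]; default [estimate_tn93_model()] of `a`.
#' @param starts List of `ape::phylo` starting trees; default NJ and BioNJ.
#' @param nni_tol Minimum log-likelihood gain to accept an NNI move.
#' @param max_rounds Cap on NNI acceptance rounds.
#' @return List with `tree` (optimized `phylo`), `loglik`, `start_logliks`
#'   (per starting tree, after branch-length optimization of the start) and
#'   `n_nni` (accepted rearrangements).
#' @export
optimize_tree <- function(a, model = NULL, starts = NULL, nni_tol = 1e-4,
                          max_rounds = 50L) {
  a <- as_alignment(a)
  if (is.null(model)) model <- estimate_tn93_model(a)
  enc <- encode_alignment(a)
  if (is.null(starts)) {
    D <- distance_matrix(a, model$freqs)
    if (attr(D, "nonfinite")) {
      stop("saturated (non-finite) distances; cannot build starting trees")
    }
    starts <- list(nj = neighbor_joining(D, "nj"),
                   bionj = neighbor_joining(D, "bionj"))
  }
  stopifnot(length(starts) >= 1L)
  best <- NULL
  start_lls <- numeric(length(starts))
  total_nni <- 0L
  for (s in seq_along(starts)) {
    fit <- optimize_branch_lengths(starts[[s]], enc, model)
    start_lls[s] <- fit$loglik
    repeat {
      if (total_nni >= max_rounds * length(starts)) break
      improved <- FALSE
      cand_best <- NULL
      for (e in nni_edges(fit$tree)) {
        for (nb in nni_neighbors_at(fit$tree, e)) {
          ctr <- which(nb$edge[, 1] == fit$tree$edge[e, 1] &
                         nb$edge[, 2] == fit$tree$edge[e, 2])
          f <- function(t) {
            nb$edge.length[ctr[1]] <- t
            prune_loglik(nb, enc, model)
          }
          opt <- stats::optimize(f, c(0, 10), maximum = TRUE, tol = 1e-6)
          if (!is.finite(opt$objective)) next
          if (is.null(cand_best) || opt$objective > cand_best$ll) {
            nb$edge.length[ctr[1]] <- opt$maximum
            cand_best <- list(tree = nb, ll = opt$objective)
          }
        }
      }
      if (!is.null(cand_best) && cand_best$ll > fit$loglik + nni_tol) {
        fit <- optimize_branch_lengths(cand_best$tree, enc, model)
        total_nni <- total_nni + 1L
        improved <- TRUE
      }
      if (!improved) break
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  list(tree = best$tree, loglik = best$loglik, start_logliks = start_lls,
       n_nni = total_nni)
}

#' Check whether two leaf groups form a two-clade bipartition
#'
#' On an unrooted tree, a two-group labelling is clade-like exactly when some
#' edge separates the leaves into the two groups. Every internal edge's leaf
#' bipartition is examined (pendant edges cover single-leaf groups).
#'
#' @param tree `ape::phylo`.
#' @param groups Named character (or factor) vector mapping every leaf label
#'   to one of exactly two group labels.
#' @return List with `two_groups` (logical), and when `TRUE` the separating
#'   `edge` index and the two leaf sets `partition`.
#' @export
monophyly_check <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"))
  groups <- groups[tree$tip.label]
  if (anyNA(groups)) stop("every leaf needs a group label")
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) stop("exactly two groups are required")
  g1 <- tree$tip.label[groups == lv[1]]
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  below <- c(as.list(seq_len(ntip)), vector("list", tree$Nnode))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- tree$tip.label[below[[tree$edge[e, 2]]]]
    if (setequal(leaves, g1) || setequal(leaves, setdiff(tree$tip.label, g1))) {
      return(list(two_groups = TRUE, edge = e,
                  partition = list(leaves, setdiff(tree$tip.label, leaves))))
    }
  }
  list(two_groups = FALSE, edge = NA_integer_, partition = NULL)
}
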