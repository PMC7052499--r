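#' Tamura-Nei (TN93) substitution model
#'
#' TN93 allows unequal base frequencies, distinct purine (A<->G) and
#' pyrimidine (C<->T) transition rates, and a single transversion rate. The
#' rate matrix is normalized so the expected substitution rate at
#' stationarity is 1, putting branch lengths on the substitutions-per-site
#' scale.
#'
#' @param freqs Base frequencies `(A, C, G, T)`, non-negative, summing to 1
#'   (within 1e-9).
#' @param rate_AG Purine transition rate (alpha1), > 0.
#' @param rate_CT Pyrimidine transition rate (alpha2), > 0.
#' @param rate_transversion Transversion rate (beta), > 0.
#' @return Object of class `tn93_model`: list with `freqs`, the three rates,
#'   the normalized rate matrix `Q` (rows sum to 0) and its spectral
#'   decomposition used to compute transition probabilities.
#' @export
tn93_model <- function(freqs, rate_AG = 1, rate_CT = 1, rate_transversion = 1) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("`freqs` must be 4 non-negative values summing to 1")
  }
  if (rate_AG <= 0 || rate_CT <= 0 || rate_transversion <= 0) {
    stop("all rates must be positive")
  }
  names(freqs) <- DNA_STATES
  a1 <- rate_AG; a2 <- rate_CT; b <- rate_transversion
  Q <- matrix(c(
    0,            b * freqs[2], a1 * freqs[3], b * freqs[4],
    b * freqs[1], 0,            b * freqs[3],  a2 * freqs[4],
    a1 * freqs[1], b * freqs[2], 0,            b * freqs[4],
    b * freqs[1], a2 * freqs[2], b * freqs[3], 0
  ), 4, 4, byrow = TRUE, dimnames = list(DNA_STATES, DNA_STATES))
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))            # mean rate at stationarity
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  # reversible Q: symmetrize with pi^(1/2) for a stable eigendecomposition
  sq <- sqrt(pmax(freqs, .Machine$double.eps))
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(
    list(freqs = freqs, rate_AG = a1, rate_CT = a2, rate_transversion = b,
         Q = Q,
         evals = es$values,
         right = diag(1 / sq) %*% es$vectors,
         left  = t(es$vectors) %*% diag(sq)),
    class = "tn93_model"
  )
}

#' @export
print.tn93_model <- function(x, ...) {
  cat(sprintf(
    "TN93 model: pi = (%.3f, %.3f, %.3f, %.3f), alpha1(AG) = %.3g, alpha2(CT) = %.3g, beta = %.3g\n",
    x$freqs[1], x$freqs[2], x$freqs[3], x$freqs[4],
    x$rate_AG, x$rate_CT, x$rate_transversion))
  invisible(x)
}

#' TN93 transition probability matrix
#'
#' @param model A [tn93_model()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 4x4 matrix `P` with `P[i, j] = P(state j at the end | state i at
#'   the start)`; rows sum to 1.
#' @export
tn93_probability <- function(model, t) {
  stopifnot(inherits(model, "tn93_model"), t >= 0)
  P <- model$right %*% (exp(model$evals * t) * model$left)
  P[P < 0] <- 0                          # clip eigendecomposition noise
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P / rowSums(P)
}

# observed substitution proportions between two gap-free sequences:
# P1 = A<->G transitions, P2 = C<->T transitions, Q = transversions
substitution_proportions <- function(x, y) {
  stopifnot(length(x) == length(y))
  diff <- x != y
  pair <- paste0(pmin(x[diff], y[diff]), pmax(x[diff], y[diff]))
  n <- length(x)
  c(P1 = sum(pair == "AG") / n,
    P2 = sum(pair == "CT") / n,
    Q  = sum(!(pair %in% c("AG", "CT"))) / n)
}

#' Closed-form TN93 pairwise distance
#'
#' Evolutionary distance (expected substitutions per site) between two aligned
#' gap-free sequences under the TN93 model, computed from the observed
#' purine-transition, pyrimidine-transition and transversion proportions and
#' the supplied base frequencies. Saturated pairs (a logarithm argument <= 0)
#' yield `NaN` rather than a clamped value.
#'
#' @param x,y Character vectors over A/C/G/T of equal length (or single
#'   strings).
#' @param freqs Base frequencies `(A, C, G, T)`; typically
#'   [empirical_frequencies()] of the whole alignment.
#' @return Non-negative distance; 0 for identical sequences; `NaN` on
#'   saturation.
#' @export
tn93_distance <- function(x, y, freqs) {
  if (length(x) == 1L && nchar(x[1]) > 1L) x <- strsplit(toupper(x), "")[[1]]
  if (length(y) == 1L && nchar(y[1]) > 1L) y <- strsplit(toupper(y), "")[[1]]
  if (!all(c(x, y) %in% DNA_STATES)) stop("sequences must be gap-free A/C/G/T")
  freqs <- as.numeric(freqs)
  stopifnot(length(freqs) == 4L)
  pA <- freqs[1]; pC <- freqs[2]; pG <- freqs[3]; pT <- freqs[4]
  pR <- pA + pG; pY <- pC + pT
  pr <- substitution_proportions(x, y)
  P1 <- pr[["P1"]]; P2 <- pr[["P2"]]; Qv <- pr[["Q"]]
  w1 <- 1 - pR * P1 / (2 * pA * pG) - Qv / (2 * pR)
  w2 <- 1 - pY * P2 / (2 * pC * pT) - Qv / (2 * pY)
  w3 <- 1 - Qv / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NaN)
  d <- -(2 * pA * pG / pR) * log(w1) -
        (2 * pC * pT / pY) * log(w2) -
        2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY) * log(w3)
  max(d, 0)
}

#' TN93 distance matrix of an alignment
#'
#' @param a Gap-free alignment (see [as_alignment()]).
#' @param freqs Base frequencies; default [empirical_frequencies()] of `a`.
#' @return Symmetric matrix with zero diagonal, dimnames from the alignment,
#'   and attribute `nonfinite` (TRUE if any pair saturated). Tree building
#'   refuses flagged matrices.
#' @export
distance_matrix <- function(a, freqs = empirical_frequencies(a)) {
  a <- as_alignment(a)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- tn93_distance(a[i, ], a[j, ], freqs)
  }
  attr(D, "nonfinite") <- any(!is.finite(D))
  D
}

#' Moment estimate of TN93 model parameters from an alignment
#'
#' Estimates the two transition rates and the transversion rate (up to the
#' overall scale, which is normalized away) by inverting the TN93 expected
#' substitution-proportion formulas at the pooled pairwise proportions, with
#' empirical base frequencies.
#'
#' @param a Gap-free alignment with at least 2 sequences.
#' @return A [tn93_model()].
#' @export
estimate_tn93_model <- function(a) {
  a <- as_alignment(a)
  freqs <- empirical_frequencies(a)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 sequences")
  props <- matrix(0, 0, 3)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    props <- rbind(props, substitution_proportions(a[i, ], a[j, ]))
  }
  m <- colMeans(props)
  pA <- freqs[1]; pC <- freqs[2]; pG <- freqs[3]; pT <- freqs[4]
  pR <- pA + pG; pY <- pC + pT
  # invert E[Q] = 2 pR pY (1 - e^{-2 b t}), E[P1], E[P2] at the mean pair
  e3 <- 1 - m[["Q"]] / (2 * pR * pY)
  bt <- -log(max(e3, 1e-12)) / 2
  arg1 <- pR + pY * exp(-2 * bt) - m[["P1"]] * pR / (2 * pA * pG)
  arg2 <- pY + pR * exp(-2 * bt) - m[["P2"]] * pY / (2 * pC * pT)
  a1t <- if (arg1 > 0) (-log(arg1) / 2 - pY * bt) / pR else NA_real_
  a2t <- if (arg2 > 0) (-log(arg2) / 2 - pR * bt) / pY else NA_real_
  if (!is.finite(a1t) || a1t <= 0) a1t <- bt
  if (!is.finite(a2t) || a2t <= 0) a2t <- bt
  if (bt <= 0) { a1t <- a2t <- bt <- 1 }
  tn93_model(freqs, rate_AG = a1t / bt, rate_CT = a2t / bt,
             rate_transversion = 1)
}
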