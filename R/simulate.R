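#' Monte Carlo simulation and enumeration oracle
#'
#' Stochastic and brute-force validation of the pattern-probability
#' calculations: a seedable site simulator that draws character states down
#' the quartet, and a literal six-nested-sum enumeration of the pattern
#' probabilities over all k^6 state combinations.
#'
#' @name qsn-simulate
NULL

## Inverse-CDF draw of one state per row index: for character c with parent
## state par[c], returns the smallest j with cumsum(P[par[c], ])[j] >= u[c].
## Platform-stable given the uniform stream.
.draw_states <- function(P, par, u) {
  k <- ncol(P)
  cum <- t(apply(P, 1, cumsum))
  cum[, k] <- 1 # guard against rounding shortfall
  sel <- cum[par, , drop = FALSE]
  1L + rowSums(sel[, -k, drop = FALSE] < u)
}

#' Simulate character states on a quartet
#'
#' For each character, draws the ancestral state M from the equilibrium
#' frequencies, N from the internode transition row of M, tips C1 and C2
#' from the rows of M, and C3 and C4 from the rows of N, then classifies the
#' tip tuple as synapomorphic (C1 = C2 != C3 = C4), homoplasious x1
#' (C1 = C3 != C2 = C4), homoplasious x2 (C1 = C4 != C2 = C3), or other
#' (any non-AABB pattern). Draws use inverse-CDF sampling on the transition
#' rows, so results are reproducible across platforms at a fixed seed.
#'
#' @param tree A [quartet_tree()].
#' @param n Number of characters (at least 1).
#' @param seed RNG seed (integer).
#' @param keep_tips If TRUE, the raw tip-state matrix is attached as
#'   element `tips` (n x 4 integer matrix) for external analysis.
#' @return An object of class `"pattern_counts"`: list with `n`, `seed` and
#'   `counts`, a named integer vector over categories `synapomorphic`,
#'   `homoplasy_x1`, `homoplasy_x2`, `other`.
#' @examples
#' tr <- quartet_tree(0.1, 0.25, 0.25, 0.25, 0.25, lam = 1)
#' simulate_characters(tr, n = 1000, seed = 42)
#' @export
simulate_characters <- function(tree, n, seed = 1L, keep_tips = FALSE) {
  stopifnot(inherits(tree, "quartet_tree"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive number of characters")
  n <- as.integer(n)
  P <- .quartet_P(tree)
  pi <- tree$model$pi
  k <- length(pi)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  cpi <- cumsum(pi); cpi[k] <- 1
  M <- 1L + rowSums(outer(stats::runif(n), cpi[-k], ">"))
  N <- .draw_states(P[[1]], M, stats::runif(n))
  C1 <- .draw_states(P[[2]], M, stats::runif(n))
  C2 <- .draw_states(P[[3]], M, stats::runif(n))
  C3 <- .draw_states(P[[4]], N, stats::runif(n))
  C4 <- .draw_states(P[[5]], N, stats::runif(n))

  syn <- C1 == C2 & C3 == C4 & C1 != C3
  h1 <- C1 == C3 & C2 == C4 & C1 != C2
  h2 <- C1 == C4 & C2 == C3 & C1 != C2
  counts <- c(synapomorphic = sum(syn), homoplasy_x1 = sum(h1),
              homoplasy_x2 = sum(h2), other = n - sum(syn) - sum(h1) - sum(h2))
  out <- list(n = n, seed = as.integer(seed), counts = counts)
  if (keep_tips) out$tips <- cbind(C1 = C1, C2 = C2, C3 = C3, C4 = C4)
  structure(out, class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf("Simulated pattern counts (n = %d, seed = %d)\n", x$n, x$seed))
  freq <- x$counts / x$n
  for (nm in names(x$counts))
    cat(sprintf("  %-14s %8d  (%.5f)\n", nm, x$counts[[nm]], freq[[nm]]))
  invisible(x)
}

#' Compare simulated frequencies with analytic probabilities
#'
#' @param counts A [simulate_characters()] result.
#' @param tree The generating [quartet_tree()].
#' @return Data frame with category, count, empirical frequency, analytic
#'   probability, binomial standard error and z-score, for the three AABB
#'   categories.
#' @export
summarize_simulation <- function(counts, tree) {
  stopifnot(inherits(counts, "pattern_counts"))
  probs <- pattern_probabilities(tree)
  analytic <- c(synapomorphic = probs$y, homoplasy_x1 = probs$x1,
                homoplasy_x2 = probs$x2)
  n <- counts$n
  obs <- counts$counts[names(analytic)]
  se <- sqrt(analytic * (1 - analytic) / n)
  data.frame(category = names(analytic), count = as.integer(obs),
             empirical = as.numeric(obs / n), analytic = as.numeric(analytic),
             se = as.numeric(se),
             z = as.numeric((obs / n - analytic) / se),
             row.names = NULL)
}

#' Literal enumeration of the pattern probabilities
#'
#' Evaluates the six-nested summation over all k^6 combinations of
#' (M, N, C1, C2, C3, C4) of the product
#' pi_M p_MN p_MC1 p_MC2 p_NC3 p_NC4, accumulating the synapomorphic and
#' homoplasious pattern probabilities, the signal probability, and the total
#' over all tuples (which must be 1). This is the independent oracle for
#' [pattern_probabilities()]; it is deliberately the naive sum.
#'
#' @param tree A [quartet_tree()] with at most 20 states.
#' @return List with `y`, `x1`, `x2`, `signal`, `total`.
#' @export
enumerate_oracle <- function(tree) {
  stopifnot(inherits(tree, "quartet_tree"))
  k <- length(tree$model$pi)
  if (k > 20) stop("enumeration over k^6 tuples is limited to k <= 20; ",
                   "use pattern_probabilities() for larger alphabets")
  P <- .quartet_P(tree)
  pi <- tree$model$pi
  y <- x1 <- x2 <- signal <- total <- 0
  for (M in 1:k) for (N in 1:k) {
    base <- pi[M] * P[[1]][M, N]
    if (N != M) signal <- signal + base
    for (C1 in 1:k) for (C2 in 1:k) {
      b2 <- base * P[[2]][M, C1] * P[[3]][M, C2]
      for (C3 in 1:k) for (C4 in 1:k) {
        pr <- b2 * P[[4]][N, C3] * P[[5]][N, C4]
        total <- total + pr
        if (C1 == C2 && C3 == C4 && C3 != C1) y <- y + pr
        if (C1 == C3 && C2 == C4 && C2 != C1) x1 <- x1 + pr
        if (C1 == C4 && C2 == C3 && C2 != C1) x2 <- x2 + pr
      }
    }
  }
  list(y = unname(y), x1 = unname(x1), x2 = unname(x2),
       signal = unname(signal), total = unname(total))
}
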