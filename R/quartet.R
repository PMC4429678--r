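#' Quartet trees and site-pattern probabilities
#'
#' A quartet is an unrooted four-taxon tree: one internal branch (the
#' internode, duration `t0`, rate `lam0`) joining ancestral states M and N,
#' and four subtending branches (durations `T1..T4`, rates `lam1..lam4`)
#' leading to tip states C1, C2 (below M) and C3, C4 (below N). The
#' parsimony-informative "AABB" site patterns are the synapomorphic pattern
#' y (C1 = C2 != C3 = C4, supporting the true tree) and the two homoplasious
#' patterns x1 (C1 = C3 != C2 = C4) and x2 (C1 = C4 != C2 = C3).
#'
#' @name qsn-quartet
NULL

#' Construct a quartet tree
#'
#' @param t0 Internode duration (time units).
#' @param T1,T2,T3,T4 Subtending branch durations.
#' @param lam0,lam1,lam2,lam3,lam4 Per-branch average substitution rates.
#' @param model A [substitution_model()]; defaults to Jukes-Cantor.
#' @return An object of class `"quartet_tree"`.
#' @examples
#' quartet_tree(t0 = 0.1, T1 = 0.4, T2 = 0.8, T3 = 0.4, T4 = 0.8, lam = 1)
#' @param lam Convenience: one rate applied to all five branches (overridden
#'   by any `lam0..lam4` given explicitly).
#' @export
quartet_tree <- function(t0, T1, T2, T3, T4,
                         lam0 = lam, lam1 = lam, lam2 = lam, lam3 = lam, lam4 = lam,
                         lam = 1, model = substitution_model("JC")) {
  stopifnot(inherits(model, "substitution_model"))
  dur <- c(t0 = t0, T1 = T1, T2 = T2, T3 = T3, T4 = T4)
  rate <- c(lam0 = lam0, lam1 = lam1, lam2 = lam2, lam3 = lam3, lam4 = lam4)
  if (any(!is.finite(dur)) || any(dur < 0))
    stop("all branch durations must be finite and nonnegative")
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("all branch rates must be finite and nonnegative")
  structure(list(durations = dur, rates = rate, model = model),
            class = "quartet_tree")
}

#' @export
print.quartet_tree <- function(x, ...) {
  cat("Quartet tree (", x$model$family, " model)\n", sep = "")
  tab <- rbind(duration = x$durations, rate = x$rates,
               `expected length` = x$durations * x$rates)
  colnames(tab) <- c("internode", paste0("branch", 1:4))
  print(signif(tab, 6))
  invisible(x)
}

## The five transition matrices of a quartet, in branch order 0..4.
.quartet_P <- function(tree) {
  m <- tree$model
  lapply(1:5, function(b) {
    Q <- rate_matrix(m, tree$rates[[b]])
    transition_matrix(Q, tree$durations[[b]])$P
  })
}

#' Site-pattern probabilities for one character on a quartet
#'
#' Computes the exact probabilities of the three parsimony-informative AABB
#' patterns by summing the product
#' pi_M p_MN(lam0, t0) p_MC1 p_MC2 p_NC3 p_NC4 over the state combinations
#' defining each pattern, together with the probability of signal (a state
#' difference across the internode), the probability of zero changes on the
#' four subtending branches, the probability of true synapomorphy Pi
#' (signal times no-change), and the probability of apparent synapomorphy
#' (y - Pi). The sums are evaluated by tensor contraction over the ancestral
#' states, which is algebraically identical to the literal six-index
#' summation (see [enumerate_oracle()]).
#'
#' @param tree A [quartet_tree()].
#' @return An object of class `"pattern_probabilities"`: list with numeric
#'   elements `y`, `x1`, `x2`, `signal`, `no_change`, `pi_true`, `apparent`.
#' @examples
#' tr <- quartet_tree(0.1, 0.25, 0.25, 0.25, 0.25, lam = 1)
#' pattern_probabilities(tr)
#' @export
pattern_probabilities <- function(tree) {
  stopifnot(inherits(tree, "quartet_tree"))
  P <- .quartet_P(tree)
  pi <- tree$model$pi

  W <- pi * P[[1]]                    # W[M,N] = pi_M p_MN(lam0, t0)
  A <- P[[2]] * P[[3]]                # A[M,a] = p_Ma(1) p_Ma(2)
  B <- P[[4]] * P[[5]]                # B[N,b] = p_Nb(3) p_Nb(4)
  AB <- tcrossprod(A, B)              # sum_a A[M,a] B[N,a]

  ## y: C1=C2=a, C3=C4=b, b != a
  y <- sum(W * (outer(rowSums(A), rowSums(B)) - AB))
  ## x1: C1=C3=a, C2=C4=b, b != a
  x1 <- sum(W * (tcrossprod(P[[2]], P[[4]]) * tcrossprod(P[[3]], P[[5]]) - AB))
  ## x2: C1=C4=a, C2=C3=b, b != a
  x2 <- sum(W * (tcrossprod(P[[2]], P[[5]]) * tcrossprod(P[[3]], P[[4]]) - AB))

  signal <- 1 - sum(pi * diag(P[[1]]))
  sub <- tree$durations[2:5] * tree$rates[2:5]
  no_change <- exp(-sum(sub))
  pi_true <- signal * no_change

  structure(list(y = y, x1 = x1, x2 = x2, signal = signal,
                 no_change = no_change, pi_true = pi_true,
                 apparent = y - pi_true),
            class = "pattern_probabilities")
}

#' @export
print.pattern_probabilities <- function(x, ...) {
  cat("Quartet site-pattern probabilities\n")
  v <- unlist(x)
  lab <- c(y = "y   (synapomorphic, C1=C2 != C3=C4)",
           x1 = "x1  (homoplasious, C1=C3 != C2=C4)",
           x2 = "x2  (homoplasious, C1=C4 != C2=C3)",
           signal = "signal     Pr{M != N}",
           no_change = "no change  Pr{0 subtending changes}",
           pi_true = "Pi  (true synapomorphy)",
           apparent = "apparent synapomorphy (y - Pi)")
  for (nm in names(lab))
    cat(sprintf("  %-38s %.10g\n", lab[[nm]], v[[nm]]))
  invisible(x)
}

#' Probability of signal across the internode
#'
#' The probability that the ancestral states at the two ends of the
#' internode differ: sum_M sum_{N != M} pi_M p_MN(lam0, t0), equivalently
#' 1 - sum_M pi_M p_MM.
#'
#' @param tree A [quartet_tree()].
#' @return A probability in \[0, 1\].
#' @export
signal_probability <- function(tree) {
  stopifnot(inherits(tree, "quartet_tree"))
  Q <- rate_matrix(tree$model, tree$rates[["lam0"]])
  P0 <- transition_matrix(Q, tree$durations[["t0"]])$P
  1 - sum(tree$model$pi * diag(P0))
}

#' Probability of zero changes on the subtending branches
#'
#' exp(-(lam1 T1 + lam2 T2 + lam3 T3 + lam4 T4)): the chance that a signal
#' on the internode survives unobscured to the four tips.
#'
#' @param tree A [quartet_tree()].
#' @return A probability in (0, 1\].
#' @export
no_change_probability <- function(tree) {
  stopifnot(inherits(tree, "quartet_tree"))
  exp(-sum(tree$durations[2:5] * tree$rates[2:5]))
}

#' Probability of true synapomorphy
#'
#' The product of [signal_probability()] and [no_change_probability()]: an
#' informative state change on the internode followed by zero changes on all
#' four subtending branches.
#'
#' @param tree A [quartet_tree()].
#' @return A probability in \[0, 1\].
#' @export
true_synapomorphy <- function(tree) {
  signal_probability(tree) * no_change_probability(tree)
}

#' Predicted phylogenetic utility of a character on a quartet
#'
#' The parsimony utility y - Max(x1, x2) is positive when a character
#' supports the true tree more strongly than either wrong tree, so sampling
#' more such characters makes parsimony consistent; negative utility predicts
#' inconsistency (long-branch attraction). The conservative lower bound
#' Pi - Max(x1, x2) counts only true, unobscured synapomorphy as support.
#' Three diagnostic ratios are included: y/Max(x1,x2) (the consistency
#' ratio), Pi/y (the fraction of synapomorphic patterns that are true
#' signal), and Pi/Max(x1,x2).
#'
#' Ratios at zero denominators follow IEEE conventions: `Inf` when the
#' numerator is positive and `NaN` when both are zero (e.g. on a quartet
#' with all branch lengths zero).
#'
#' @param tree A [quartet_tree()].
#' @param probs Optionally, a precomputed [pattern_probabilities()] for
#'   `tree` (avoids recomputation in scans).
#' @return An object of class `"quartet_utility"`: list with
#'   `u_parsimony`, `u_conservative`, `ratio_y_max`, `ratio_pi_y`,
#'   `ratio_pi_max`, and the underlying `probs`.
#' @examples
#' quartet_utility(quartet_tree(0.1, 0.4, 0.4, 0.4, 0.4, lam = 1))
#' @export
quartet_utility <- function(tree, probs = pattern_probabilities(tree)) {
  stopifnot(inherits(probs, "pattern_probabilities"))
  mx <- max(probs$x1, probs$x2)
  structure(list(u_parsimony = probs$y - mx,
                 u_conservative = probs$pi_true - mx,
                 ratio_y_max = probs$y / mx,
                 ratio_pi_y = probs$pi_true / probs$y,
                 ratio_pi_max = probs$pi_true / mx,
                 probs = probs),
            class = "quartet_utility")
}

#' @export
print.quartet_utility <- function(x, ...) {
  cat("Predicted phylogenetic utility\n")
  cat(sprintf("  y - Max(x1, x2)  (parsimony utility)    %+.10g\n", x$u_parsimony))
  cat(sprintf("  Pi - Max(x1, x2) (conservative bound)   %+.10g\n", x$u_conservative))
  cat(sprintf("  y / Max(x1, x2)                         %.10g\n", x$ratio_y_max))
  cat(sprintf("  Pi / y                                  %.10g\n", x$ratio_pi_y))
  cat(sprintf("  Pi / Max(x1, x2)                        %.10g\n", x$ratio_pi_max))
  invisible(x)
}
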