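#' Substitution models and transition probabilities
#'
#' Constructors and converters for time-reversible substitution models:
#' model specification, instantaneous rate matrices normalized to a given
#' average substitution rate, and finite-time transition probability
#' matrices obtained by eigendecomposition.
#'
#' @name qsn-models
NULL

.DNA_STATES <- c("T", "C", "A", "G")

## Pair order of the six nucleotide exchangeabilities, rTG fixed to 1 by
## convention. Transitions are T<->C and A<->G.
.DNA_PAIRS <- c("TC", "TA", "TG", "CA", "CG", "AG")
.TRANSITIONS <- c("TC", "AG")

#' Specify a reversible substitution model
#'
#' Builds a validated substitution model from a model family, symmetric
#' exchangeabilities and equilibrium frequencies. The nucleotide families
#' (`"JC"`, `"K2P"`, `"HKY"`, `"GTR"`) use the alphabet T, C, A, G and the
#' six exchangeabilities rTC, rTA, rTG, rCA, rCG, rAG with rTG = 1 as the
#' reference. `"MK_K"` is the k-state symmetric model (all exchangeabilities
#' equal, uniform frequencies); with `k = 4` it coincides with JC. `"CUSTOM"`
#' accepts any symmetric nonnegative exchangeabilities and positive
#' frequencies over an arbitrary alphabet.
#'
#' Family constraints are enforced, and redundant parameters are filled in:
#' JC and MK_K need no parameters; K2P takes a single transition/transversion
#' ratio `kappa` (or equivalently exchangeabilities with rTC = rAG and all
#' transversions equal); HKY is K2P with free frequencies.
#'
#' @param family One of `"JC"`, `"K2P"`, `"HKY"`, `"GTR"`, `"MK_K"`,
#'   `"CUSTOM"`.
#' @param exchangeabilities For `"GTR"`/`"CUSTOM"`: named numeric vector of
#'   upper-triangular relative rates (names like `"TC"`, or an unnamed vector
#'   in row-major upper-triangular order). For `"K2P"`/`"HKY"` a vector in the
#'   same convention (checked for the two-rate-class structure); may be
#'   omitted when `kappa` is given.
#' @param frequencies Equilibrium frequencies, in state order. Ignored (forced
#'   uniform) for JC, K2P and MK_K.
#' @param k Number of states; required for `"MK_K"` and `"CUSTOM"` (for
#'   `"CUSTOM"`, inferred from `states` or `frequencies` when omitted).
#' @param kappa Transition/transversion rate ratio, a shorthand for K2P/HKY.
#' @param states Character vector naming the states (CUSTOM/MK_K; defaults to
#'   `"s1"`, `"s2"`, ... for MK_K and CUSTOM without names).
#' @return An object of class `"substitution_model"`: a list with elements
#'   `family`, `states`, `R` (symmetric k x k exchangeability matrix with
#'   zero diagonal) and `pi` (frequencies).
#' @examples
#' substitution_model("JC")
#' substitution_model("K2P", kappa = 4.493)
#' substitution_model("GTR",
#'   exchangeabilities = c(TC = 9.082, TA = 1.967, TG = 1,
#'                         CA = 1.078, CG = 0.907, AG = 2.902),
#'   frequencies = c(0.265, 0.225, 0.286, 0.224))
#' @export
substitution_model <- function(family = c("JC", "K2P", "HKY", "GTR", "MK_K", "CUSTOM"),
                               exchangeabilities = NULL, frequencies = NULL,
                               k = NULL, kappa = NULL, states = NULL) {
  family <- match.arg(family)

  if (family %in% c("JC", "K2P", "HKY", "GTR")) {
    states <- .DNA_STATES
    k <- 4L
  } else {
    if (is.null(k)) {
      if (!is.null(states)) k <- length(states)
      else if (!is.null(frequencies)) k <- length(frequencies)
      else stop("k (number of states) is required for family ", family)
    }
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2, got ", k)
    if (is.null(states)) states <- paste0("s", seq_len(k))
    if (length(states) != k) stop("length(states) != k")
  }

  R <- matrix(0, k, k, dimnames = list(states, states))

  if (family %in% c("JC", "MK_K")) {
    if (!is.null(exchangeabilities) &&
        length(unique(exchangeabilities)) > 1L)
      stop(family, " requires all exchangeabilities equal")
    R[] <- 1
    diag(R) <- 0
    pi <- rep(1 / k, k)
  } else if (family %in% c("K2P", "HKY")) {
    if (is.null(kappa)) {
      ex <- .resolve_dna_exchangeabilities(exchangeabilities)
      tv <- ex[setdiff(.DNA_PAIRS, .TRANSITIONS)]
      tr <- ex[.TRANSITIONS]
      if (diff(range(tv)) > 1e-12)
        stop(family, " forces a single transversion rate class; got unequal ",
             "transversion exchangeabilities (", paste(signif(tv, 6), collapse = ", "), ")")
      if (diff(range(tr)) > 1e-12)
        stop(family, " forces a single transition rate class; got unequal ",
             "transition exchangeabilities")
      kappa <- tr[[1]] / tv[[1]]
    }
    if (kappa < 0) stop("kappa must be nonnegative")
    R[] <- 1
    diag(R) <- 0
    R["T", "C"] <- R["C", "T"] <- kappa
    R["A", "G"] <- R["G", "A"] <- kappa
    if (family == "K2P") {
      if (!is.null(frequencies) && any(abs(frequencies - 0.25) > 1e-12))
        stop("K2P forces uniform base frequencies")
      pi <- rep(0.25, 4)
    } else {
      if (is.null(frequencies)) stop("HKY requires frequencies")
      pi <- frequencies
    }
  } else { # GTR, CUSTOM
    if (family == "GTR") {
      ex <- .resolve_dna_exchangeabilities(exchangeabilities)
      R["T", "C"] <- ex[["TC"]]; R["T", "A"] <- ex[["TA"]]
      R["T", "G"] <- ex[["TG"]]; R["C", "A"] <- ex[["CA"]]
      R["C", "G"] <- ex[["CG"]]; R["A", "G"] <- ex[["AG"]]
      R <- R + t(R)
    } else {
      if (is.null(exchangeabilities)) stop("CUSTOM requires exchangeabilities")
      if (is.matrix(exchangeabilities)) {
        if (!all(dim(exchangeabilities) == k))
          stop("exchangeability matrix must be ", k, " x ", k)
        if (max(abs(exchangeabilities - t(exchangeabilities))) > 1e-12)
          stop("exchangeability matrix must be symmetric")
        R[] <- exchangeabilities
        diag(R) <- 0
      } else {
        if (length(exchangeabilities) != k * (k - 1) / 2)
          stop("expected ", k * (k - 1) / 2, " upper-triangular exchangeabilities, got ",
               length(exchangeabilities))
        R[upper.tri(R)] <- exchangeabilities[.upper_tri_rowmajor_order(k)]
        R <- R + t(R)
      }
    }
    if (is.null(frequencies)) stop(family, " requires frequencies")
    pi <- frequencies
  }

  if (any(R[upper.tri(R)] < 0)) stop("exchangeabilities must be nonnegative")
  if (all(R[upper.tri(R)] == 0)) stop("at least one exchangeability must be positive")
  if (length(pi) != k) stop("expected ", k, " frequencies, got ", length(pi))
  if (any(pi <= 0)) stop("all equilibrium frequencies must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-12)
    stop("equilibrium frequencies must sum to 1 (got ", format(sum(pi), digits = 15), ")")
  names(pi) <- states

  structure(list(family = family, states = states, R = R, pi = pi),
            class = "substitution_model")
}

## Map upper.tri's column-major fill order to the row-major (TC,TA,TG,CA,CG,AG)
## pair order users supply.
.upper_tri_rowmajor_order <- function(k) {
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  order(order(idx[, "row"], idx[, "col"]))
}

.resolve_dna_exchangeabilities <- function(ex) {
  if (is.null(ex)) stop("exchangeabilities are required")
  if (length(ex) != 6L) stop("expected 6 exchangeabilities (TC, TA, TG, CA, CG, AG)")
  if (!is.null(names(ex)) && all(nzchar(names(ex)))) {
    nm <- toupper(names(ex))
    nm <- vapply(nm, function(p) {
      if (p %in% .DNA_PAIRS) p else paste0(substr(p, 2, 2), substr(p, 1, 1))
    }, character(1))
    if (!setequal(nm, .DNA_PAIRS))
      stop("exchangeability names must be the pairs ", paste(.DNA_PAIRS, collapse = ", "))
    ex <- ex[match(.DNA_PAIRS, nm)]
  }
  ex <- as.numeric(ex)
  names(ex) <- .DNA_PAIRS
  ex
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("%s substitution model (%d states: %s)\n",
              x$family, length(x$states), paste(x$states, collapse = " ")))
  cat("Exchangeabilities (upper triangle):\n")
  print(signif(x$R, 6))
  cat("Equilibrium frequencies:\n")
  print(signif(x$pi, 6))
  invisible(x)
}

#' Named model presets estimated from the yeast ACT1 marker
#'
#' Returns one of the four nucleotide models (JC, K2P, HKY, GTR) with
#' exchangeabilities and base frequencies as estimated for the actin (ACT1)
#' marker in a 29-taxon *Candida* data set, widely used for comparing
#' predicted utility across model specifications.
#'
#' @param name One of `"act1-jc"`, `"act1-k2p"`, `"act1-hky"`, `"act1-gtr"`.
#' @return A [substitution_model()].
#' @examples
#' model_preset("act1-gtr")
#' @export
model_preset <- function(name = c("act1-jc", "act1-k2p", "act1-hky", "act1-gtr")) {
  name <- match.arg(name)
  switch(name,
    "act1-jc"  = substitution_model("JC"),
    "act1-k2p" = substitution_model("K2P", kappa = 4.493),
    "act1-hky" = substitution_model("HKY", kappa = 4.522,
                                    frequencies = c(0.336, 0.274, 0.235, 0.155)),
    "act1-gtr" = substitution_model("GTR",
      exchangeabilities = c(TC = 9.082, TA = 1.967, TG = 1,
                            CA = 1.078, CG = 0.907, AG = 2.902),
      frequencies = c(0.265, 0.225, 0.286, 0.224)))
}

#' Read a custom model from a plain-text file
#'
#' File format, whitespace-delimited: line 1 gives the ordered state
#' alphabet; the following k-1 lines give the upper-triangular
#' exchangeabilities row by row (k-1 values, then k-2, ...); the final line
#' gives the k equilibrium frequencies.
#'
#' @param path Path to the model file.
#' @return A CUSTOM [substitution_model()].
#' @export
read_model_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 3L) stop("model file must have alphabet, exchangeability and frequency lines")
  states <- strsplit(lines[[1]], "\\s+")[[1]]
  k <- length(states)
  if (length(lines) != k + 1L)
    stop("expected ", k + 1L, " lines for a ", k, "-state model, got ", length(lines))
  rows <- lapply(lines[2:k], function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  expect_len <- (k - 1):1
  got_len <- lengths(rows)
  if (!all(got_len == expect_len))
    stop("upper-triangular exchangeability rows must have lengths ",
         paste(expect_len, collapse = ", "))
  ex <- unlist(rows)
  if (anyNA(ex)) stop("non-numeric exchangeability value in model file")
  freqs <- as.numeric(strsplit(lines[[k + 1L]], "\\s+")[[1]])
  if (length(freqs) != k || anyNA(freqs))
    stop("final line must give ", k, " numeric frequencies")
  substitution_model("CUSTOM", exchangeabilities = ex, frequencies = freqs,
                     k = k, states = states)
}

#' Instantaneous rate matrix at a given average substitution rate
#'
#' Builds the rate matrix Q with off-diagonal entries proportional to
#' r_ij * pi_j (the GTR product convention) and rescales it so that the
#' average substitution rate at equilibrium, sum_i sum_{j != i} pi_i q_ij,
#' equals `lam` exactly. The diagonal is set to minus the row sums.
#'
#' @param model A [substitution_model()].
#' @param lam Average substitution rate, in events per unit time; must be
#'   nonnegative.
#' @return An object of class `"rate_matrix"`: list with `Q` (k x k matrix),
#'   `lam`, `pi`, `states` and the generating `model`.
#' @examples
#' rate_matrix(substitution_model("JC"), lam = 1)$Q
#' @export
rate_matrix <- function(model, lam) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single nonnegative rate, got ", lam)
  pi <- model$pi
  Q <- model$R * rep(pi, each = length(pi)) # q_ij proportional to r_ij * pi_j
  total <- sum(pi * rowSums(Q))
  Q <- if (lam == 0) Q * 0 else Q * (lam / total)
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, lam = lam, pi = pi, states = model$states, model = model),
            class = "rate_matrix")
}

#' Finite-time transition probability matrix
#'
#' Computes P = exp(Q t) for a reversible rate matrix by the pi^(1/2)
#' similarity transform: S = D Q D^-1 with D = diag(sqrt(pi)) is symmetric,
#' so its eigendecomposition is real and exact, and
#' P = D^-1 V exp(L t) V' D with S = V L V'.
#'
#' @param Q A [rate_matrix()].
#' @param t Duration (time units); must be nonnegative.
#' @return An object of class `"transition_matrix"`: list with `P`, `lam`,
#'   `t`, `pi`, `states`.
#' @examples
#' transition_matrix(rate_matrix(substitution_model("JC"), 1), t = 0.1)$P
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(inherits(Q, "rate_matrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single nonnegative duration, got ", t)
  P <- if (t == 0 || Q$lam == 0) diag(length(Q$pi)) # exp(0) = I exactly
       else .expm_reversible(Q$Q, Q$pi, t)
  dimnames(P) <- dimnames(Q$Q)
  rs <- rowSums(P)
  if (max(abs(rs - 1)) > 1e-8)
    stop("transition matrix row sums deviate from 1 by ",
         format(max(abs(rs - 1))), "; eigendecomposition failed")
  structure(list(P = P, lam = Q$lam, t = t, pi = Q$pi, states = Q$states),
            class = "transition_matrix")
}

## exp(Q t) for reversible Q with stationary distribution pi.
.expm_reversible <- function(Qm, pi, t) {
  d <- sqrt(pi)
  S <- Qm * (d / rep(d, each = length(d))) # D Q D^-1, symmetric
  S <- (S + t(S)) / 2                      # clean rounding asymmetry
  eig <- eigen(S, symmetric = TRUE)
  E <- exp(eig$values * t)
  V <- eig$vectors
  P <- V %*% (E * t(V))
  P <- P * (rep(d, each = length(d)) / d)  # D^-1 (.) D
  ## clamp tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  P
}

#' Jukes-Cantor transition matrix in closed form
#'
#' Analytic transition probabilities under the k=4 Jukes-Cantor model:
#' p_ii = 1/4 + (3/4) exp(-4 lam t / 3) and
#' p_ij = 1/4 - (1/4) exp(-4 lam t / 3). Serves as an independent oracle for
#' the eigendecomposition path.
#'
#' @param lam Average substitution rate (nonnegative).
#' @param t Duration (nonnegative).
#' @return A `"transition_matrix"` object.
#' @export
jc_closed_form <- function(lam, t) {
  if (lam < 0 || t < 0) stop("lam and t must be nonnegative")
  e <- exp(-4 * lam * t / 3)
  P <- matrix(1 / 4 - e / 4, 4, 4, dimnames = list(.DNA_STATES, .DNA_STATES))
  diag(P) <- 1 / 4 + 3 * e / 4
  structure(list(P = P, lam = lam, t = t,
                 pi = stats::setNames(rep(0.25, 4), .DNA_STATES),
                 states = .DNA_STATES),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix P(lam = %g, t = %g)\n", x$lam, x$t))
  print(signif(x$P, 6))
  invisible(x)
}

#' Convert between expected substitutions and JC p-length
#'
#' A branch's p-length is the probability that the states at its two ends
#' differ. Under Jukes-Cantor, p = 3/4 - (3/4) exp(-4 lam t / 3), so p ranges
#' over \[0, 0.75) as the expected number of substitutions lam*t ranges over
#' \[0, infinity). `lt_from_p` is the exact inverse,
#' lam*t = -(3/4) log(1 - 4p/3).
#'
#' @param lam Substitution rate (nonnegative).
#' @param t Duration (nonnegative).
#' @return `p_from_lt`: the p-length in \[0, 0.75).
#' @examples
#' p_from_lt(1, 0.3831)       # ~ 0.30
#' lt_from_p(p_from_lt(1, 2)) # 2
#' @export
p_from_lt <- function(lam, t) {
  if (any(lam < 0) || any(t < 0)) stop("lam and t must be nonnegative")
  3 / 4 - (3 / 4) * exp(-4 * lam * t / 3)
}

#' @rdname p_from_lt
#' @param p p-length(s) in \[0, 0.75).
#' @return `lt_from_p`: the expected number of substitutions lam*t.
#' @export
lt_from_p <- function(p) {
  if (any(p < 0) || any(p >= 0.75))
    stop("p-length must lie in the JC admissible range [0, 0.75); got ",
         paste(format(p[p < 0 | p >= 0.75]), collapse = ", "))
  -(3 / 4) * log(1 - 4 * p / 3)
}
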