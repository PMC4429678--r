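#' Utility-versus-rate curves
#'
#' A rate family is a one-parameter family of quartet trees: a template
#' quartet in which a designated subset of the five branch rates is bound to
#' a free rate lambda while the remaining rates stay fixed. Scanning lambda
#' yields the predicted-utility curve Pi - Max(x1, x2), whose maximum
#' defines the optimal substitution rate and whose zero crossing above the
#' optimum defines the threshold rate beyond which a character is expected
#' to mislead.
#'
#' @name qsn-curves
NULL

#' Construct a rate family
#'
#' @param t0,T1,T2,T3,T4 Branch durations of the template quartet.
#' @param bound Integer subset of 0:4 naming the branches whose rate is tied
#'   to the free rate lambda (0 = internode).
#' @param fixed_rates Named or positional rates `lam0..lam4` for the
#'   branches not in `bound` (values for bound branches are ignored).
#' @param model A [substitution_model()].
#' @param label Optional label carried into outputs.
#' @return An object of class `"rate_family"`; calling
#'   `tree_at(family, lambda)` instantiates the quartet at a rate.
#' @seealso [example_family()] for the built-in clock and rate-variation
#'   families.
#' @export
rate_family <- function(t0, T1, T2, T3, T4, bound = 0:4,
                        fixed_rates = rep(1, 5),
                        model = substitution_model("JC"),
                        label = NULL) {
  bound <- sort(unique(as.integer(bound)))
  if (length(bound) < 1L || any(bound < 0L | bound > 4L))
    stop("bound must be a nonempty subset of 0:4")
  if (any(fixed_rates < 0)) stop("fixed rates must be nonnegative")
  structure(list(durations = c(t0 = t0, T1 = T1, T2 = T2, T3 = T3, T4 = T4),
                 bound = bound, fixed_rates = rep_len(fixed_rates, 5),
                 model = model, label = label),
            class = "rate_family")
}

#' Instantiate a rate family at a free rate
#'
#' @param family A [rate_family()].
#' @param lambda Free substitution rate (nonnegative).
#' @return A [quartet_tree()].
#' @export
tree_at <- function(family, lambda) {
  stopifnot(inherits(family, "rate_family"))
  rates <- family$fixed_rates
  rates[family$bound + 1L] <- lambda
  d <- family$durations
  quartet_tree(d[["t0"]], d[["T1"]], d[["T2"]], d[["T3"]], d[["T4"]],
               lam0 = rates[1], lam1 = rates[2], lam2 = rates[3],
               lam3 = rates[4], lam4 = rates[5], model = family$model)
}

#' Built-in quartet families for rate scans
#'
#' * `"example2"` — asymmetrical topology under a molecular clock: all five
#'   rates equal lambda; t0 = 0.1, T1 = T3 = 0.4, T2 = T4 = 0.4 * scale
#'   (scale > 1 controls the topological asymmetry).
#' * `"example3"` — symmetric topology with rate variation across lineages:
#'   t0 = 0.1, T1..T4 = 0.1 * scale (internode depth multiplier); branches
#'   1 and 3 evolve at rate 1 while the internode and branches 2 and 4 share
#'   the free rate lambda.
#' * `"example3_alt"` — the alternative binding for the same tree: internode
#'   and branches 1 and 3 free, branches 2 and 4 fixed at 1.
#' * `"example4"` — the `"example3"` tree at scale = 2.5 (T1..T4 = 0.25),
#'   used for comparing model specifications.
#'
#' @param name Family name.
#' @param scale Asymmetry / depth multiplier (the captions' `l`; ignored for
#'   `"example4"`, which fixes it at 2.5).
#' @param model A [substitution_model()]; defaults to JC.
#' @return A [rate_family()].
#' @examples
#' example_family("example2", scale = 2)
#' @export
example_family <- function(name = c("example2", "example3", "example3_alt", "example4"),
                           scale = 2, model = substitution_model("JC")) {
  name <- match.arg(name)
  if (scale <= 0) stop("scale must be positive")
  switch(name,
    example2 = rate_family(0.1, 0.4, 0.4 * scale, 0.4, 0.4 * scale,
                           bound = 0:4, model = model,
                           label = sprintf("example2 (scale=%g)", scale)),
    example3 = rate_family(0.1, 0.1 * scale, 0.1 * scale, 0.1 * scale, 0.1 * scale,
                           bound = c(0L, 2L, 4L), fixed_rates = rep(1, 5),
                           model = model,
                           label = sprintf("example3 (scale=%g)", scale)),
    example3_alt = rate_family(0.1, 0.1 * scale, 0.1 * scale, 0.1 * scale, 0.1 * scale,
                               bound = c(0L, 1L, 3L), fixed_rates = rep(1, 5),
                               model = model,
                               label = sprintf("example3_alt (scale=%g)", scale)),
    example4 = rate_family(0.1, 0.25, 0.25, 0.25, 0.25,
                           bound = c(0L, 2L, 4L), fixed_rates = rep(1, 5),
                           model = model, label = "example4 (scale=2.5)"))
}

#' Default lambda grid for rate scans
#'
#' 200 log-spaced rates spanning \[1e-3, 50\], which comfortably contains
#' the optima and thresholds of the built-in families.
#'
#' @param n Number of grid points.
#' @param from,to Grid endpoints (positive).
#' @return Ascending numeric vector.
#' @export
default_lambda_grid <- function(n = 200, from = 1e-3, to = 50) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Evaluate a utility-versus-rate curve
#'
#' Computes u_conservative = Pi - Max(x1, x2) and u_parsimony =
#' y - Max(x1, x2) at each grid rate, locates the optimum of
#' u_conservative by golden-section refinement of the grid argmax, and the
#' threshold rate as the first zero crossing of u_conservative above the
#' optimum, refined by bisection to 1e-8 relative tolerance.
#'
#' @param family A [rate_family()].
#' @param lambdas Ascending nonnegative rate grid.
#' @return An object of class `"rate_curve"`: list with `lambdas`,
#'   `u_conservative`, `u_parsimony`, `y`, `x1`, `x2`, `pi_true`,
#'   `optimal_rate`, `optimal_value`, `threshold_rate` (NA when no zero
#'   crossing exists above the optimum within the grid), `family`.
#' @examples
#' curve <- evaluate_curve(example_family("example2", scale = 2),
#'                         default_lambda_grid(n = 60))
#' curve$optimal_rate
#' @export
evaluate_curve <- function(family, lambdas = default_lambda_grid()) {
  stopifnot(inherits(family, "rate_family"))
  if (length(lambdas) == 0) stop("empty lambda grid")
  if (is.unsorted(lambdas, strictly = TRUE) || any(lambdas < 0))
    stop("lambda grid must be strictly ascending and nonnegative")

  ucons <- function(lam) quartet_utility(tree_at(family, lam))$u_conservative

  n <- length(lambdas)
  y <- x1 <- x2 <- pit <- up <- uc <- numeric(n)
  for (i in seq_len(n)) {
    u <- quartet_utility(tree_at(family, lambdas[i]))
    uc[i] <- u$u_conservative; up[i] <- u$u_parsimony
    y[i] <- u$probs$y; x1[i] <- u$probs$x1; x2[i] <- u$probs$x2
    pit[i] <- u$probs$pi_true
  }

  i_max <- which.max(uc)
  lo <- lambdas[max(1L, i_max - 1L)]
  hi <- lambdas[min(n, i_max + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(ucons, c(lo, hi), maximum = TRUE, tol = 1e-10)
    optimal_rate <- opt$maximum
    optimal_value <- opt$objective
    if (optimal_value < uc[i_max]) { # grid point can beat the refined point at flat maxima
      optimal_rate <- lambdas[i_max]
      optimal_value <- uc[i_max]
    }
  } else {
    optimal_rate <- lambdas[i_max]
    optimal_value <- uc[i_max]
  }

  threshold_rate <- NA_real_
  if (i_max < n) {
    above <- i_max:n
    sgn <- sign(uc[above])
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flip) > 0) {
      a <- lambdas[above[flip[1]]]
      b <- lambdas[above[flip[1] + 1L]]
      threshold_rate <- .bisect_root(ucons, a, b, rel_tol = 1e-8)
    } else if (any(uc[above] == 0 & lambdas[above] > optimal_rate)) {
      threshold_rate <- lambdas[above[which(uc[above] == 0)[1]]]
    }
  }

  structure(list(lambdas = lambdas, u_conservative = uc, u_parsimony = up,
                 y = y, x1 = x1, x2 = x2, pi_true = pit,
                 optimal_rate = optimal_rate, optimal_value = optimal_value,
                 threshold_rate = threshold_rate, family = family),
            class = "rate_curve")
}

.bisect_root <- function(f, a, b, rel_tol = 1e-8, max_iter = 200L) {
  fa <- f(a); fb <- f(b)
  if (fa == 0) return(a)
  if (fb == 0) return(b)
  if (sign(fa) == sign(fb))
    stop("invalid bracket: f has the same sign at both endpoints; ",
         "scan a wider range to locate a sign change")
  for (i in seq_len(max_iter)) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm == 0 || (b - a) / max(abs(m), 1e-300) < rel_tol) return(m)
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m; fb <- fm }
  }
  (a + b) / 2
}

#' Find the threshold substitution rate of a family
#'
#' Locates the rate at which u_conservative = Pi - Max(x1, x2) crosses
#' zero. With a two-element `bracket` whose endpoints have opposite utility
#' signs, bisects directly; with a longer scan grid, finds the first sign
#' change above the curve's optimum.
#'
#' @param family A [rate_family()].
#' @param bracket Either `c(lo, hi)` bracketing a sign change, or an
#'   ascending scan grid (length > 2) to search.
#' @return The threshold rate, or `NA` when no sign change exists in the
#'   scanned range.
#' @export
find_threshold_rate <- function(family, bracket = default_lambda_grid()) {
  stopifnot(inherits(family, "rate_family"))
  ucons <- function(lam) quartet_utility(tree_at(family, lam))$u_conservative
  if (length(bracket) == 2L) {
    return(.bisect_root(ucons, bracket[1], bracket[2], rel_tol = 1e-8))
  }
  evaluate_curve(family, bracket)$threshold_rate
}

#' @export
print.rate_curve <- function(x, ...) {
  lab <- x$family$label
  cat("Utility-versus-rate curve",
      if (!is.null(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  cat(sprintf("  %d rates in [%g, %g], model %s\n", length(x$lambdas),
              min(x$lambdas), max(x$lambdas), x$family$model$family))
  cat(sprintf("  optimal rate  %.6g  (Pi - Max = %.6g)\n",
              x$optimal_rate, x$optimal_value))
  if (is.na(x$threshold_rate))
    cat("  threshold rate: none in the scanned range\n")
  else
    cat(sprintf("  threshold rate %.6g  (Pi - Max crosses 0)\n", x$threshold_rate))
  invisible(x)
}

#' Compare predicted utility across model specifications
#'
#' Evaluates the same rate family under several substitution models on a
#' shared lambda grid, as in the comparison of JC, K2P, HKY and GTR fits of
#' the ACT1 marker on the symmetric rate-variation quartet.
#'
#' @param family A [rate_family()] (its own model is replaced per entry).
#' @param models Named list of [substitution_model()] objects.
#' @param lambdas Shared ascending rate grid.
#' @return An object of class `"model_comparison"`: list with `curves`
#'   (one [rate_curve()] per model) and `summary` (data frame with
#'   optimal rate/value and the positive-lambda range per model).
#' @examples
#' cmp <- compare_models(example_family("example4"),
#'                       list(JC = model_preset("act1-jc"),
#'                            GTR = model_preset("act1-gtr")),
#'                       default_lambda_grid(n = 50))
#' cmp$summary
#' @export
compare_models <- function(family, models, lambdas = default_lambda_grid()) {
  stopifnot(inherits(family, "rate_family"))
  if (length(models) == 0) stop("at least one model is required")
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$family, character(1))
  curves <- lapply(models, function(m) {
    fam <- family
    fam$model <- m
    evaluate_curve(fam, lambdas)
  })
  summary <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    rng <- positive_lambda_range(cv)
    data.frame(model = nm, optimal_rate = cv$optimal_rate,
               optimal_value = cv$optimal_value,
               threshold_rate = cv$threshold_rate,
               positive_from = rng[1], positive_to = rng[2],
               positive_width = rng[2] - rng[1])
  }))
  structure(list(curves = curves, summary = summary, lambdas = lambdas),
            class = "model_comparison")
}

#' Positive-utility rate range of a curve
#'
#' The interval of lambda over which u_conservative > 0, with the upper end
#' refined to the threshold (zero-crossing) rate when available. Returns
#' `c(NA, NA)` when the curve is nowhere positive.
#'
#' @param curve A [rate_curve()].
#' @return Length-2 numeric vector `c(from, to)`.
#' @export
positive_lambda_range <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  pos <- which(curve$u_conservative > 0)
  if (length(pos) == 0) return(c(NA_real_, NA_real_))
  lo_i <- pos[1]
  lo <- curve$lambdas[lo_i]
  ## refine the lower crossing when the curve starts negative
  if (lo_i > 1L && curve$u_conservative[lo_i - 1L] < 0) {
    fam <- curve$family
    f <- function(lam) quartet_utility(tree_at(fam, lam))$u_conservative
    lo <- .bisect_root(f, curve$lambdas[lo_i - 1L], lo, rel_tol = 1e-8)
  }
  hi <- if (!is.na(curve$threshold_rate)) curve$threshold_rate
        else curve$lambdas[pos[length(pos)]]
  c(lo, hi)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d rates in [%g, %g]\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas)))
  print(x$summary, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Write a rate curve as CSV with a JSON sidecar
#'
#' Columns: lambda, u_conservative, u_parsimony, y, x1, x2, pi_true. The
#' sidecar records the family label, model, and the optimal and threshold
#' rates.
#'
#' @param curve A [rate_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "rate_curve"))
  df <- data.frame(lambda = curve$lambdas,
                   u_conservative = curve$u_conservative,
                   u_parsimony = curve$u_parsimony,
                   y = curve$y, x1 = curve$x1, x2 = curve$x2,
                   pi_true = curve$pi_true)
  df[] <- lapply(df, function(v) formatC(v, digits = 12, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(label = curve$family$label,
                            model = curve$family$model$family,
                            optimal_rate = curve$optimal_rate,
                            optimal_value = curve$optimal_value,
                            threshold_rate = curve$threshold_rate),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
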