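#' Branch-length-space scans: Felsenstein and Farris zones
#'
#' Two classic quartet parameterizations, each a two-parameter family in
#' JC p-length coordinates (the probability that the states at a branch's
#' two ends differ, in \[0, 0.75)):
#'
#' * `"huelsenbeck_hillis"`: the internode and subtending branches 1 and 3
#'   (on opposite sides of the internode) share the three-branch length
#'   `pa`; branches 2 and 4 share the two-branch length `pb`. Long
#'   non-sister branches at small `pa`, large `pb` put parsimony in the
#'   Felsenstein zone.
#' * `"siddall"`: the internode and subtending branches 1 and 2 (the same
#'   side) share `pa`; branches 3 and 4 share `pb`. The long branches are
#'   true sisters — the Farris zone, where parsimony succeeds largely
#'   through apparent synapomorphy.
#'
#' @name qsn-zones
NULL

.ZONE_KINDS <- c("huelsenbeck_hillis", "siddall")

.match_zone_kind <- function(kind) {
  kind <- tolower(kind)
  if (kind %in% c("hh", "huelsenbeck-hillis")) kind <- "huelsenbeck_hillis"
  match.arg(kind, .ZONE_KINDS)
}

#' Expand a zone-tree specification into a quartet tree
#'
#' Converts the two p-lengths into expected substitution counts via the JC
#' inverse mapping [lt_from_p()] and assigns them per the kind's branch
#' mapping, with all rates fixed at 1 (only the products rate x duration
#' matter under JC, so this loses no generality).
#'
#' @param kind `"huelsenbeck_hillis"` (alias `"hh"`) or `"siddall"`.
#' @param pa Three-branch p-length in \[0, 0.75).
#' @param pb Two-branch p-length in \[0, 0.75).
#' @return A [quartet_tree()] under the JC model.
#' @examples
#' expand_zone_tree("hh", pa = 0.05, pb = 0.60)
#' @export
expand_zone_tree <- function(kind, pa, pb) {
  kind <- .match_zone_kind(kind)
  la <- lt_from_p(pa)
  lb <- lt_from_p(pb)
  if (kind == "huelsenbeck_hillis")
    quartet_tree(t0 = la, T1 = la, T2 = lb, T3 = la, T4 = lb, lam = 1)
  else
    quartet_tree(t0 = la, T1 = la, T2 = la, T3 = lb, T4 = lb, lam = 1)
}

.GRID_QUANTITIES <- c("y_over_max", "pi_over_y", "pi_over_max",
                      "u_parsimony", "u_conservative")

#' Scan a quartet branch-length space
#'
#' Evaluates a chosen utility quantity on a rectangular grid over
#' (`pa`, `pb`) for one of the two zone trees. Rows index `pb` (vertical
#' axis), columns index `pa` (horizontal axis), following the usual
#' branch-length-space plotting convention.
#'
#' @param kind `"huelsenbeck_hillis"` or `"siddall"`.
#' @param quantity One of `"y_over_max"`, `"pi_over_y"`, `"pi_over_max"`,
#'   `"u_parsimony"`, `"u_conservative"`.
#' @param n_pa,n_pb Grid sizes (at least 2).
#' @param pa_range,pb_range Axis ranges, within \[0, 0.75). The defaults
#'   avoid the p = 0 ratio singularities and the p = 0.75 pole.
#' @return An object of class `"branch_space_grid"`: list with `kind`,
#'   `quantity`, `pa_axis`, `pb_axis` and `values` (an `n_pb` x `n_pa`
#'   matrix, `values[i, j]` at `pb_axis[i]`, `pa_axis[j]`). Undefined ratio
#'   cells hold `NaN`, infinite ratios `Inf`.
#' @examples
#' g <- scan_branch_space("siddall", "y_over_max", n_pa = 5, n_pb = 5)
#' g$values
#' @export
scan_branch_space <- function(kind, quantity = .GRID_QUANTITIES,
                              n_pa = 50, n_pb = 50,
                              pa_range = c(0.01, 0.74),
                              pb_range = c(0.01, 0.74)) {
  kind <- .match_zone_kind(kind)
  quantity <- match.arg(quantity)
  if (n_pa < 2 || n_pb < 2) stop("grid sizes must be at least 2")
  .check_p_range <- function(r, nm) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0 || r[2] >= 0.75)
      stop(nm, " must be an ascending range within the JC admissible ",
           "p-length interval [0, 0.75)")
  }
  .check_p_range(pa_range, "pa_range")
  .check_p_range(pb_range, "pb_range")
  pa_axis <- seq(pa_range[1], pa_range[2], length.out = n_pa)
  pb_axis <- seq(pb_range[1], pb_range[2], length.out = n_pb)

  values <- matrix(NA_real_, n_pb, n_pa,
                   dimnames = list(pb = format(pb_axis, digits = 6),
                                   pa = format(pa_axis, digits = 6)))
  for (i in seq_len(n_pb)) {
    for (j in seq_len(n_pa)) {
      u <- quartet_utility(expand_zone_tree(kind, pa_axis[j], pb_axis[i]))
      values[i, j] <- switch(quantity,
        y_over_max = u$ratio_y_max,
        pi_over_y = u$ratio_pi_y,
        pi_over_max = u$ratio_pi_max,
        u_parsimony = u$u_parsimony,
        u_conservative = u$u_conservative)
    }
  }
  structure(list(kind = kind, quantity = quantity,
                 pa_axis = pa_axis, pb_axis = pb_axis, values = values),
            class = "branch_space_grid")
}

#' @export
print.branch_space_grid <- function(x, ...) {
  cat(sprintf("Branch-space grid: %s over the %s tree, %d x %d nodes\n",
              x$quantity, x$kind, length(x$pb_axis), length(x$pa_axis)))
  cat(sprintf("  pa in [%g, %g], pb in [%g, %g]\n",
              min(x$pa_axis), max(x$pa_axis), min(x$pb_axis), max(x$pb_axis)))
  fin <- x$values[is.finite(x$values)]
  cat(sprintf("  finite values: %d of %d, range [%g, %g]\n",
              length(fin), length(x$values), min(fin), max(fin)))
  invisible(x)
}

#' Classify the inconsistency zone of a scanned grid
#'
#' For a ratio grid (`y_over_max`, `pi_over_max`) a node is inconsistent
#' when the ratio is below 1; for a utility grid (`u_parsimony`,
#' `u_conservative`) when the utility is below 0. The inconsistent region of
#' the Huelsenbeck-Hillis space is the Felsenstein zone.
#'
#' @param grid A [scan_branch_space()] result with a compatible quantity.
#' @return An object of class `"zone_mask"`: list with logical matrix
#'   `mask` (TRUE = inconsistent), `n_inconsistent`, `n_total` and the
#'   generating `kind`/`quantity`.
#' @export
classify_zone <- function(grid) {
  stopifnot(inherits(grid, "branch_space_grid"))
  threshold <- switch(grid$quantity,
    y_over_max = , pi_over_max = 1,
    u_parsimony = , u_conservative = 0,
    stop("zone classification needs a ratio-to-1 or utility quantity; got ",
         grid$quantity))
  mask <- is.finite(grid$values) & grid$values < threshold
  structure(list(mask = mask, n_inconsistent = sum(mask),
                 n_total = length(mask),
                 kind = grid$kind, quantity = grid$quantity),
            class = "zone_mask")
}

#' @export
print.zone_mask <- function(x, ...) {
  cat(sprintf("Zone classification (%s, %s): %d of %d nodes inconsistent (%.1f%%)\n",
              x$kind, x$quantity, x$n_inconsistent, x$n_total,
              100 * x$n_inconsistent / x$n_total))
  invisible(x)
}

#' Write a branch-space grid as CSV with a JSON sidecar
#'
#' The CSV has a header row of `pa` values (first cell `pb`), then one row
#' per `pb` value. Non-finite cells are written as `inf`, `-inf` or `nan`.
#' The sidecar (`<path>.json`) records kind, quantity and axes.
#'
#' @param grid A [scan_branch_space()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "branch_space_grid"))
  fmt <- function(v) {
    out <- formatC(v, digits = 12, format = "g")
    out[is.nan(v)] <- "nan"
    out[is.infinite(v) & v > 0] <- "inf"
    out[is.infinite(v) & v < 0] <- "-inf"
    out
  }
  lines <- c(paste(c("pb", fmt(grid$pa_axis)), collapse = ","),
             vapply(seq_along(grid$pb_axis), function(i) {
               paste(c(fmt(grid$pb_axis[i]), fmt(grid$values[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  jsonlite::write_json(list(kind = grid$kind, quantity = grid$quantity,
                            n_pa = length(grid$pa_axis), n_pb = length(grid$pb_axis),
                            pa_range = range(grid$pa_axis),
                            pb_range = range(grid$pb_axis)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
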