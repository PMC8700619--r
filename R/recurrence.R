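#' Cross-recurrence configuration
#'
#' Parameters governing how pairwise recurrence structure is quantified. Two
#' threshold (epsilon) rules are carried side by side, matching the two edge
#' definitions used downstream: `diameter_fraction` sets epsilon to a fixed
#' proportion of the joint phase-space diameter (used for recurrence-rate
#' edges), and `fixed_rr` calibrates epsilon so the recurrence rate hits a
#' target (used for diagonal-line-entropy edges, where comparable recurrence
#' density across pairs matters more than a common radius).
#'
#' @param diameter_fraction Proportion of the phase-space diameter used as
#'   epsilon under the diameter rule (default 0.10).
#' @param target_rr Target recurrence rate under the fixed-RR rule
#'   (default 0.1).
#' @param rr_tolerance Acceptable |achieved - target| after calibration
#'   (default 1e-3); a warning is raised when the distance spectrum is too
#'   coarse to get closer.
#' @param l_min Minimum diagonal line length counted by the histogram
#'   (default 2).
#' @param norm Distance norm in embedded space, `"euclidean"` (default) or
#'   `"maximum"`.
#' @param entropy_base Logarithm base for the diagonal entropy: `"natural"`
#'   (nats, default) or `"log2"` (bits).
#' @return An object of class `recurrence_config`.
#' @export
recurrence_config <- function(diameter_fraction = 0.10,
                              target_rr = 0.1,
                              rr_tolerance = 1e-3,
                              l_min = 2L,
                              norm = c("euclidean", "maximum"),
                              entropy_base = c("natural", "log2")) {
  if (diameter_fraction <= 0 || diameter_fraction >= 1)
    stop_invalid("invalid 'diameter_fraction': must lie in (0, 1)")
  if (target_rr <= 0 || target_rr >= 1)
    stop_invalid("invalid 'target_rr': must lie in (0, 1)")
  if (l_min < 2) stop_invalid("invalid 'l_min': must be >= 2")
  structure(list(diameter_fraction = diameter_fraction,
                 target_rr = target_rr,
                 rr_tolerance = rr_tolerance,
                 l_min = as.integer(l_min),
                 norm = match.arg(norm),
                 entropy_base = match.arg(entropy_base)),
            class = "recurrence_config")
}

as_points <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
}

check_same_dim <- function(a, b) {
  if (ncol(a) != ncol(b))
    stop_invalid("trajectories differ in embedding dimension (",
                 ncol(a), " vs ", ncol(b), ")")
}

#' Phase-space diameter of a trajectory pair
#'
#' Maximum pairwise distance over the union of the points of both
#' trajectories, by exact scan.
#'
#' @param a,b Trajectory matrices (points in rows) of equal dimension.
#' @param norm `"euclidean"` or `"maximum"`.
#' @return The diameter as a single distance.
#' @export
phase_space_diameter <- function(a, b, norm = "euclidean") {
  a <- as_points(a); b <- as_points(b)
  check_same_dim(a, b)
  u <- rbind(a, b)
  max(cpp_cross_dist(u, u, identical(norm, "maximum")))
}

#' Epsilon from the diameter rule
#'
#' @inheritParams phase_space_diameter
#' @param fraction Proportion of the diameter (default 0.10).
#' @return `fraction * diameter`.
#' @export
epsilon_from_diameter <- function(a, b, fraction = 0.10,
                                  norm = "euclidean") {
  d <- phase_space_diameter(a, b, norm)
  if (d <= 0)
    stop_invalid("degenerate input: zero phase-space diameter")
  fraction * d
}

#' Cross-recurrence matrix
#'
#' Binary N1 x N2 matrix with cell (i, j) = 1 iff the distance between point
#' i of `a` and point j of `b` is at most `epsilon` (inclusive threshold:
#' ties count as recurrent).
#'
#' @inheritParams phase_space_diameter
#' @param epsilon Threshold distance, >= 0.
#' @return An object of class `cross_recurrence`: list with `cells` (binary
#'   integer matrix), `epsilon`, and `achieved_rr`.
#' @export
cross_recurrence_matrix <- function(a, b, epsilon, norm = "euclidean") {
  a <- as_points(a); b <- as_points(b)
  check_same_dim(a, b)
  if (epsilon < 0) stop_invalid("epsilon must be >= 0")
  d <- cpp_cross_dist(a, b, identical(norm, "maximum"))
  cells <- matrix(as.integer(d <= epsilon), nrow(d), ncol(d))
  new_cross_recurrence(cells, epsilon)
}

new_cross_recurrence <- function(cells, epsilon) {
  structure(list(cells = cells, epsilon = epsilon,
                 achieved_rr = sum(cells) / length(cells)),
            class = "cross_recurrence")
}

#' @export
print.cross_recurrence <- function(x, ...) {
  cat("Cross-recurrence matrix ", nrow(x$cells), "x", ncol(x$cells),
      ", epsilon = ", format(x$epsilon), ", RR = ",
      format(x$achieved_rr), "\n", sep = "")
  invisible(x)
}

cr_cells <- function(cr) {
  if (inherits(cr, "cross_recurrence")) cr$cells else cr
}

#' Recurrence rate
#'
#' Fraction of recurrent (1) cells in a cross-recurrence matrix.
#'
#' @param cr A `cross_recurrence` object or binary matrix.
#' @return Proportion in `[0, 1]`.
#' @export
recurrence_rate <- function(cr) {
  cells <- cr_cells(cr)
  if (!length(cells)) stop_invalid("empty recurrence matrix")
  sum(cells) / length(cells)
}

#' Calibrate epsilon to a target recurrence rate
#'
#' The recurrence rate is a non-decreasing step function of epsilon jumping
#' exactly at the pairwise distances, so the achievable rates are
#' `k / (N1*N2)`. The calibration sorts all pairwise distances and returns
#' the smallest distance whose achievable rate is closest to the target -
#' an exact order-statistic solution, not iterative root-finding.
#'
#' @inheritParams phase_space_diameter
#' @param target_rr Target recurrence rate in (0, 1).
#' @param rr_tolerance Warn when |achieved - target| exceeds this.
#' @return List with `epsilon` and `achieved_rr`.
#' @export
calibrate_epsilon <- function(a, b, target_rr = 0.1, rr_tolerance = 1e-3,
                              norm = "euclidean") {
  if (target_rr <= 0 || target_rr >= 1)
    stop_invalid("target_rr must lie in (0, 1)")
  a <- as_points(a); b <- as_points(b)
  check_same_dim(a, b)
  d <- cpp_cross_dist(a, b, identical(norm, "maximum"))
  out <- cpp_calibrate(as.numeric(d), target_rr)
  if (abs(out$achieved_rr - target_rr) > rr_tolerance)
    warning("achieved recurrence rate ", format(out$achieved_rr),
            " misses target ", target_rr, " by more than ", rr_tolerance,
            call. = FALSE)
  out
}

#' Histogram of diagonal line lengths
#'
#' Scans every diagonal of the (possibly rectangular) matrix; a line is a
#' maximal run of consecutive recurrent cells along a diagonal, and runs of
#' length at least `l_min` are counted by length. No Theiler exclusion is
#' applied: cross-recurrence between distinct series has no trivial identity
#' line.
#'
#' @param cr A `cross_recurrence` object or binary matrix.
#' @param l_min Minimum counted line length (default 2).
#' @return Named integer vector: counts indexed by line length.
#' @export
diagonal_line_histogram <- function(cr, l_min = 2L) {
  if (l_min < 2) stop_invalid("l_min must be >= 2")
  cells <- cr_cells(cr)
  runs <- cpp_diag_runs(matrix(as.numeric(cells), nrow(cells)),
                        0.5, as.integer(l_min), FALSE)
  if (!length(runs)) return(setNames(integer(0), character(0)))
  tab <- table(runs)
  setNames(as.integer(tab), names(tab))
}

#' Shannon entropy of a diagonal line-length histogram
#'
#' With `p(l) = count(l) / sum(counts)`, returns `-sum p log p`. An empty
#' histogram has zero entropy. Low entropy indicates line lengths
#' concentrated in few classes (strict periodicity or pure noise); richer
#' length distributions indicate complex shared dynamics.
#'
#' @param h Named count vector from [diagonal_line_histogram()].
#' @param base `"natural"` for nats (default) or `"log2"` for bits.
#' @return Entropy, >= 0.
#' @export
diagonal_entropy <- function(h, base = c("natural", "log2")) {
  base <- match.arg(base)
  if (!length(h) || sum(h) == 0) return(0)
  p <- h / sum(h)
  ent <- -sum(p * log(p))
  if (base == "log2") ent <- ent / log(2)
  unname(ent)
}

#' Cross-recurrence metrics for one profile pair
#'
#' The composite CRQA step: both series are z-scored and embedded with the
#' shared parameters, then (i) the recurrence rate is computed under the
#' diameter rule (epsilon = `diameter_fraction` of the joint phase-space
#' diameter) and (ii) the diagonal-line entropy is computed under fixed-RR
#' calibration (epsilon tuned to `target_rr`). Both epsilon values are
#' recorded. The result is symmetric in the argument order.
#'
#' @param x_a,x_b Numeric value series of the two profiles (shared time
#'   grid assumed).
#' @param params Shared embedding parameters: list with `tau` and `m`, e.g.
#'   from [pair_embedding_params()].
#' @param config A [recurrence_config()].
#' @return An object of class `crqa_metrics`: list with `rr`, `entropy`,
#'   `epsilon_rr`, `epsilon_ent`, `achieved_rr`, `n_lines`.
#' @export
crqa_pair <- function(x_a, x_b, params, config = recurrence_config()) {
  za <- zscore(x_a)
  zb <- zscore(x_b)
  ta <- delay_embed(za, params$m, params$tau)
  tb <- delay_embed(zb, params$m, params$tau)
  crqa_trajectories(ta, tb, config)
}

# fast path shared by crqa_pair and the cohort sweep: one fused kernel
# serves both epsilon rules
crqa_trajectories <- function(ta, tb, config) {
  res <- tryCatch(
    cpp_crqa_full(ta, tb, config$diameter_fraction, config$target_rr,
                  config$l_min, identical(config$norm, "maximum")),
    error = function(e) stop_invalid(conditionMessage(e)))
  runs <- res$runs
  h <- if (length(runs)) table(runs) else integer(0)
  ent <- diagonal_entropy(setNames(as.integer(h), names(h)),
                          base = config$entropy_base)
  if (abs(res$achieved_rr - config$target_rr) > config$rr_tolerance)
    warning("achieved recurrence rate ", format(res$achieved_rr),
            " misses target ", config$target_rr, " by more than ",
            config$rr_tolerance, call. = FALSE)
  structure(list(rr = res$rr, entropy = ent,
                 epsilon_rr = res$epsilon_rr, epsilon_ent = res$epsilon_ent,
                 achieved_rr = res$achieved_rr,
                 n_lines = length(runs)),
            class = "crqa_metrics")
}

#' @export
print.crqa_metrics <- function(x, ...) {
  cat("CRQA metrics: RR =", format(x$rr),
      "(diameter rule), entropy =", format(x$entropy),
      "over", x$n_lines, "diagonal lines (fixed-RR rule)\n")
  invisible(x)
}
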