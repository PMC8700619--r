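#' Standardize a series to zero mean and unit variance
#'
#' All series are z-scored before embedding and distance computation so that
#' recurrence thresholds are comparable across element pairs.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return The standardized series.
#' @export
zscore <- function(x) {
  if (length(x) < 2L)
    stop_invalid("series too short to standardize")
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop_invalid("degenerate input: constant series cannot be standardized")
  (x - mean(x)) / s
}

#' Average mutual information by lag
#'
#' Plug-in mutual information between a series and its lagged copy, estimated
#' from an equal-width two-dimensional histogram whose bin grid is fixed from
#' the full series range (so the estimate is symmetric under time reversal).
#' Lag 0 gives the marginal entropy of the binned series. Values are in nats.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag; must be smaller than `length(x)/2`. Default
#'   `min(30, floor(length(x)/2) - 1)`.
#' @param n_bins Histogram bins per axis; default `min(32, floor(sqrt(N)))`.
#' @return Named numeric vector of AMI values for lags `0:max_lag`.
#' @seealso [select_delay()]
#' @export
average_mutual_information <- function(x, max_lag = NULL, n_bins = NULL) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(30L, n %/% 2L - 1L)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n / 2)
    stop_invalid("max_lag must be smaller than half the series length")
  if (max_lag < 1L) stop_invalid("max_lag must be at least 1")
  if (is.null(n_bins)) n_bins <- min(32L, floor(sqrt(n)))
  n_bins <- max(2L, as.integer(n_bins))

  rng <- range(x)
  if (rng[1] == rng[2])
    stop_invalid("degenerate input: constant series")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  b <- .bincode(x, breaks, include.lowest = TRUE)

  ami <- numeric(max_lag + 1L)
  for (k in 0:max_lag) {
    i1 <- b[seq_len(n - k)]
    i2 <- b[seq.int(1L + k, n)]
    joint <- tabulate(i1 + n_bins * (i2 - 1L), nbins = n_bins * n_bins)
    joint <- matrix(joint, n_bins) / (n - k)
    p1 <- rowSums(joint)
    p2 <- colSums(joint)
    pp <- outer(p1, p2)
    nz <- joint > 0
    ami[k + 1L] <- sum(joint[nz] * log(joint[nz] / pp[nz]))
  }
  names(ami) <- 0:max_lag
  ami
}

#' Select the embedding delay from an AMI curve
#'
#' Returns the first local minimum of the AMI curve over lags >= 1 (the
#' standard Fraser-Swinney rule): the smallest lag `k` whose AMI is below the
#' next lag's. If the curve never rises, the lag of the global minimum is
#' returned.
#'
#' @param ami Numeric AMI values for lags `0, 1, 2, ...` (at least 3 lags).
#' @return Integer delay in samples.
#' @export
select_delay <- function(ami) {
  if (length(ami) < 3L)
    stop_invalid("AMI curve needs at least 3 lags")
  lmax <- length(ami) - 1L            # largest lag present
  for (k in 1:(lmax - 1L)) {
    if (ami[k + 1L] < ami[k + 2L]) return(k)
  }
  as.integer(which.min(ami[-1L]))
}

#' False-nearest-neighbour fractions by embedding dimension
#'
#' Kennel criterion: for each candidate dimension `m`, each point's nearest
#' neighbour in the `m`-dimensional embedding is declared false if the extra
#' separation gained by the (m+1)-th coordinate exceeds `r_tol` times the
#' m-dimensional neighbour distance, or if the expanded distance exceeds
#' `a_tol` times the series standard deviation.
#'
#' @param x Numeric series.
#' @param tau Delay in samples.
#' @param m_max Largest candidate dimension (default 10, reduced so that at
#'   least 10 embedded points remain).
#' @param r_tol,a_tol Kennel thresholds (defaults 10 and 2).
#' @return Named numeric vector of false-neighbour fractions for
#'   `m = 1:m_max`.
#' @seealso [select_dimension()]
#' @export
false_nearest_neighbors <- function(x, tau, m_max = 10L, r_tol = 10,
                                    a_tol = 2) {
  n <- length(x)
  tau <- as.integer(tau)
  m_max <- as.integer(m_max)
  if (tau < 1L) stop_invalid("tau must be >= 1")
  if (n - m_max * tau < 2L)
    stop_invalid("series too short for m_max = ", m_max, " at tau = ", tau)
  frac <- cpp_fnn(as.numeric(x), tau, m_max, r_tol, a_tol)
  names(frac) <- seq_len(m_max)
  frac
}

#' Select the embedding dimension from an FNN curve
#'
#' The dimension minimizing the false-neighbour fraction; ties are broken
#' toward the smallest dimension.
#'
#' @param fnn Numeric false-neighbour fractions for dimensions `1, 2, ...`.
#' @return Integer embedding dimension.
#' @export
select_dimension <- function(fnn) {
  if (!length(fnn)) stop_invalid("empty FNN curve")
  as.integer(which.min(fnn))
}

#' Takens delay embedding
#'
#' Maps a scalar series to `N - (m-1)*tau` points in `m` dimensions, point
#' `i` being `(x[i], x[i+tau], ..., x[i+(m-1)*tau])`.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @return Numeric matrix with one embedded point per row and attributes
#'   `tau` and `m`.
#' @export
delay_embed <- function(x, m, tau) {
  n <- length(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop_invalid("need m >= 1 and tau >= 1")
  npts <- n - (m - 1L) * tau
  if (npts < 2L)
    stop_invalid("series too short: ", n, " samples give ", max(npts, 0L),
                 " embedded point(s) at m = ", m, ", tau = ", tau)
  out <- vapply(0:(m - 1L),
                function(j) x[seq.int(1L + j * tau, npts + j * tau)],
                numeric(npts))
  out <- matrix(out, nrow = npts)
  attr(out, "m") <- m
  attr(out, "tau") <- tau
  out
}

#' Select embedding parameters for one series
#'
#' Convenience wrapper: z-scores the series, chooses the delay at the first
#' local minimum of the average mutual information, then the dimension
#' minimizing the Kennel false-neighbour fraction at that delay. `m_max` is
#' reduced when the series is too short to probe large dimensions at the
#' selected delay.
#'
#' @inheritParams average_mutual_information
#' @inheritParams false_nearest_neighbors
#' @return An object of class `embedding_params`: list with `tau`, `m`,
#'   `ami_curve`, `fnn_curve`.
#' @export
embedding_params <- function(x, max_lag = NULL, n_bins = NULL, m_max = 10L,
                             r_tol = 10, a_tol = 2) {
  z <- zscore(x)
  ami <- average_mutual_information(z, max_lag = max_lag, n_bins = n_bins)
  tau <- select_delay(ami)
  m_hi <- max(1L, min(as.integer(m_max), (length(z) - 10L) %/% tau))
  fnn <- false_nearest_neighbors(z, tau, m_max = m_hi,
                                 r_tol = r_tol, a_tol = a_tol)
  structure(list(tau = tau, m = select_dimension(fnn),
                 ami_curve = ami, fnn_curve = fnn),
            class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  cat("Embedding parameters: tau =", x$tau, ", m =", x$m, "\n")
  invisible(x)
}

#' Shared embedding parameters for a series pair
#'
#' Cross-recurrence requires both series embedded with one (m, tau); the
#' pairwise maximum is used so that neither series is under-embedded.
#'
#' @param a,b `embedding_params` objects or lists with `tau` and `m`.
#' @return List with the shared `tau` and `m`.
#' @export
pair_embedding_params <- function(a, b) {
  structure(list(tau = max(a$tau, b$tau), m = max(a$m, b$m)),
            class = "embedding_params_pair")
}
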