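# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (double loops, exhaustive path
# enumeration, power iteration) distinct from the package's code paths.

oracle_diameter <- function(pts) {
  n <- nrow(pts)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

oracle_rr <- function(m) sum(m == 1) / length(m)

# per-diagonal run-length scan of a binary matrix
oracle_diag_hist <- function(m, l_min = 2L) {
  n1 <- nrow(m); n2 <- ncol(m)
  lens <- integer(0)
  for (off in (-(n1 - 1)):(n2 - 1)) {
    i <- if (off < 0) -off + 1L else 1L
    j <- if (off < 0) 1L else off + 1L
    run <- 0L
    while (i <= n1 && j <= n2) {
      if (m[i, j] == 1) run <- run + 1L
      else { if (run >= l_min) lens <- c(lens, run); run <- 0L }
      i <- i + 1L; j <- j + 1L
    }
    if (run >= l_min) lens <- c(lens, run)
  }
  if (!length(lens)) return(setNames(integer(0), character(0)))
  tab <- table(lens)
  setNames(as.integer(tab), names(tab))
}

# independent AMI estimator built on cut() + table()
oracle_ami <- function(x, lag, n_bins) {
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  f <- cut(x, br, include.lowest = TRUE)
  n <- length(x)
  f1 <- f[seq_len(n - lag)]
  f2 <- f[seq.int(1 + lag, n)]
  joint <- table(f1, f2) / (n - lag)
  p1 <- rowSums(joint); p2 <- colSums(joint)
  s <- 0
  for (i in seq_along(p1)) for (j in seq_along(p2)) {
    if (joint[i, j] > 0)
      s <- s + joint[i, j] * log(joint[i, j] / (p1[i] * p2[j]))
  }
  as.numeric(s)
}

# Floyd-Warshall on reciprocal-weight lengths
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n, dimnames = dimnames(w))
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# enumerate all simple paths between s and t, returning the shortest length
# and, for every interior node, the fraction of shortest paths through it
oracle_paths <- function(w, s, t) {
  n <- nrow(w)
  paths <- list()
  walk <- function(v, seen, len) {
    if (v == t) { paths[[length(paths) + 1L]] <<- list(seen = seen, len = len); return() }
    for (u in seq_len(n)) {
      if (w[v, u] > 0 && !(u %in% seen))
        walk(u, c(seen, u), len + 1 / w[v, u])
    }
  }
  walk(s, s, 0)
  if (!length(paths)) return(NULL)
  lens <- vapply(paths, `[[`, numeric(1), "len")
  best <- min(lens)
  sel <- which(abs(lens - best) < 1e-12)
  through <- matrix(0, nrow = length(sel), ncol = n)
  for (r in seq_along(sel))
    through[r, setdiff(paths[[sel[r]]]$seen, c(s, t))] <- 1
  list(len = best, frac = colMeans(through))
}

oracle_betweenness <- function(w) {
  n <- nrow(w)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    res <- oracle_paths(w, s, t)
    if (!is.null(res)) btw <- btw + res$frac
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness_ecc <- function(w) {
  d <- oracle_distances(w)
  n <- nrow(d)
  clo <- ecc <- numeric(n)
  for (i in seq_len(n)) {
    dd <- d[i, -i]; dd <- dd[is.finite(dd)]
    if (length(dd)) {
      r <- length(dd)
      clo[i] <- (r / (n - 1)) * (r / sum(dd))
      ecc[i] <- max(dd)
    }
  }
  list(closeness = clo, eccentricity = ecc)
}

oracle_eigenvector <- function(w, iter = 20000) {
  if (all(w == 0)) return(numeric(nrow(w)))
  # shift the spectrum positive so power iteration cannot oscillate between
  # the extreme eigenvalues of (near-)bipartite graphs
  ws <- w + diag(1 + max(rowSums(w)), nrow(w))
  v <- rep(1 / sqrt(nrow(w)), nrow(w))
  for (i in seq_len(iter)) {
    nv <- ws %*% v
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) return(numeric(nrow(w)))
    nv <- nv / nrm
    if (max(abs(nv - v)) < 1e-14) { v <- nv; break }
    v <- as.numeric(nv)
  }
  v <- as.numeric(v)
  if (sum(v) < 0) v <- -v
  pmax(v, 0)
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- if (max(w) > 0) w / max(w) else w
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (l in seq_len(n)) {
      if (j != i && l != i && j != l)
        s <- s + (wh[i, j] * wh[i, l] * wh[j, l])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# random weighted graph as an edge data frame over the first n network
# elements (padded to all 21 pairs with zeros when n = 7)
rand_weight_matrix <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) w[i, j] <- w[j, i] <- runif(1, 0.05, 1)
  }
  w
}

net_from_matrix <- function(w) {
  el <- network_elements()[seq_len(nrow(w))]
  dimnames(w) <- list(el, el)
  structure(list(weights = w, edge_definition = "rr",
                 threshold_applied = 0),
            class = "metabolic_network")
}

# standard noisy sine fixture
make_sine <- function(n, period, noise_sd = 0, phase = 0) {
  sin(2 * pi * seq_len(n) / period + phase) + rnorm(n, sd = noise_sd)
}

# full 21-pair edge table for one subject from a named value vector
full_edge_table <- function(values, subject = "S001", col = "rr") {
  pairs <- combn(network_elements(), 2L)
  out <- data.frame(subject_id = subject,
                    element_a = pairs[1L, ], element_b = pairs[2L, ],
                    stringsAsFactors = FALSE)
  out[[col]] <- values
  out
}

# simulate a metric table directly under the mixed model (for stats tests):
# element means + subject random intercept + iid noise + per-element group
# shifts
sim_metric_table <- function(n_subjects, delta = setNames(numeric(7), network_elements()),
                             sd_subject = 0.5, sd_resid = 1,
                             metric = "degree", edge_definition = "rr") {
  els <- network_elements()
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  groups <- setNames(rep_len(c("low", "high"), n_subjects), subjects)
  elmean <- setNames(seq_along(els) * 0.3, els)
  b <- setNames(rnorm(n_subjects, sd = sd_subject), subjects)
  rows <- expand.grid(subject_id = subjects, element = els,
                      stringsAsFactors = FALSE)
  rows$edge_definition <- edge_definition
  rows$metric <- metric
  shift <- ifelse(groups[rows$subject_id] == "high",
                  delta[rows$element], 0)
  rows$value <- elmean[rows$element] + b[rows$subject_id] + shift +
    rnorm(nrow(rows), sd = sd_resid)
  rows$pb_group <- unname(groups[rows$subject_id])
  class(rows) <- c("metric_table", class(rows))
  list(table = rows, groups = groups)
}
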