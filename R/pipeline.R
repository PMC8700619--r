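#' Embedding parameters for every (subject, element) series
#'
#' @param cohort An `elemental_cohort`.
#' @param elements Elements to process (default the seven network elements).
#' @param pool `"none"` (default: parameters per subject and element) or
#'   `"element"` (per-element median of the per-subject selections, applied
#'   cohort-wide).
#' @inheritParams embedding_params
#' @return Data frame with columns `subject_id`, `element`, `tau`, `m`.
#' @export
cohort_embedding_params <- function(cohort, elements = NETWORK_ELEMENTS,
                                    pool = c("none", "element"),
                                    max_lag = NULL, n_bins = NULL,
                                    m_max = 10L, r_tol = 10, a_tol = 2) {
  pool <- match.arg(pool)
  p <- cohort$profiles
  subjects <- unique(p$subject_id)
  rows <- vector("list", length(subjects) * length(elements))
  i <- 0L
  for (sid in subjects) {
    psub <- p[p$subject_id == sid, ]
    for (el in elements) {
      x <- psub$value[psub$element == el]
      ep <- embedding_params(x, max_lag = max_lag, n_bins = n_bins,
                             m_max = m_max, r_tol = r_tol, a_tol = a_tol)
      i <- i + 1L
      rows[[i]] <- data.frame(subject_id = sid, element = el,
                              tau = ep$tau, m = ep$m,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (pool == "element") {
    for (el in elements) {
      sel <- out$element == el
      out$tau[sel] <- as.integer(round(median(out$tau[sel])))
      out$m[sel] <- as.integer(round(median(out$m[sel])))
    }
  }
  out
}

#' Cross-recurrence edges for every subject and element pair
#'
#' For each subject, computes [crqa_pair()] metrics for all 21 unordered
#' pairs of network elements, sharing embedding parameters within a pair by
#' the pairwise-maximum rule.
#'
#' @param cohort An `elemental_cohort`.
#' @param params Data frame from [cohort_embedding_params()].
#' @param config A [recurrence_config()].
#' @return Data frame with columns `subject_id`, `element_a`, `element_b`,
#'   `rr`, `entropy`, `epsilon_rr`, `epsilon_ent`, `achieved_rr`.
#' @export
cohort_edges <- function(cohort, params, config = recurrence_config()) {
  p <- cohort$profiles
  subjects <- unique(p$subject_id)
  pairs <- utils::combn(NETWORK_ELEMENTS, 2L)
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sid <- subjects[si]
    psub <- p[p$subject_id == sid, ]
    series <- lapply(setNames(NETWORK_ELEMENTS, NETWORK_ELEMENTS),
                     function(el) zscore(psub$value[psub$element == el]))
    par_s <- params[params$subject_id == sid, ]
    ptau <- setNames(par_s$tau, par_s$element)
    pm <- setNames(par_s$m, par_s$element)
    missing_par <- setdiff(NETWORK_ELEMENTS, par_s$element)
    if (length(missing_par))
      stop_invalid("no embedding parameters for subject ", sid,
                   ", element(s) ", paste(missing_par, collapse = ", "))
    n_pairs <- ncol(pairs)
    rr <- ent <- e_rr <- e_ent <- arr <- numeric(n_pairs)
    for (k in seq_len(n_pairs)) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      tau <- max(ptau[a], ptau[b])
      m <- max(pm[a], pm[b])
      # never drop below 10 embedded points: cap m for short series
      nmin <- min(length(series[[a]]), length(series[[b]]))
      m <- max(1L, min(m, (nmin - 10L) %/% tau + 1L))
      mets <- crqa_trajectories(delay_embed(series[[a]], m, tau),
                                delay_embed(series[[b]], m, tau), config)
      rr[k] <- mets$rr; ent[k] <- mets$entropy
      e_rr[k] <- mets$epsilon_rr; e_ent[k] <- mets$epsilon_ent
      arr[k] <- mets$achieved_rr
    }
    out[[si]] <- data.frame(subject_id = sid,
                            element_a = pairs[1L, ], element_b = pairs[2L, ],
                            rr = rr, entropy = ent,
                            epsilon_rr = e_rr, epsilon_ent = e_ent,
                            achieved_rr = arr, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-subject networks and long-format node metrics for one edge definition
#'
#' Applies the cohort-global median threshold for the chosen edge
#' definition, builds every subject's network, and stacks the six node
#' metrics into long format.
#'
#' @param edges Data frame from [cohort_edges()].
#' @param edge_definition `"rr"` or `"entropy"`.
#' @param binarize Passed to [build_network()].
#' @return List with `table` (long data frame: `subject_id`, `element`,
#'   `edge_definition`, `metric`, `value`), `networks` (named list of
#'   `metabolic_network`), and `threshold`.
#' @export
network_metric_table <- function(edges, edge_definition = c("rr", "entropy"),
                                 binarize = FALSE) {
  edge_definition <- match.arg(edge_definition)
  thr <- global_edge_threshold(edges[[edge_definition]])
  subjects <- unique(edges$subject_id)
  nets <- vector("list", length(subjects))
  names(nets) <- subjects
  rows <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sid <- subjects[si]
    net <- build_network(edges[edges$subject_id == sid, ],
                         edge_definition, thr, binarize = binarize)
    nets[[sid]] <- net
    nm <- node_metrics(net)
    rows[[si]] <- data.frame(
      subject_id = sid,
      element = rep(nm$element, length(GRAPH_METRICS)),
      edge_definition = edge_definition,
      metric = rep(GRAPH_METRICS, each = nrow(nm)),
      value = unlist(nm[GRAPH_METRICS], use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), networks = nets, threshold = thr)
}

#' Run the full cross-recurrence network analysis
#'
#' The top-level fitting function: starting from a cohort of longitudinal
#' elemental profiles it (1) selects embedding parameters per series,
#' (2) computes CRQA metrics for all element pairs per subject, (3) builds
#' per-subject networks under the cohort-median edge threshold for each
#' requested edge definition and extracts six node metrics, and (4) fits
#' one element-by-exposure linear mixed model per (metric, edge definition)
#' with main-effect and per-element exposure tests.
#'
#' @param cohort An `elemental_cohort` (e.g. from [generate_cohort()] or
#'   [read_profiles()]).
#' @param groups Optional named exposure labels per subject; by default
#'   derived from the Pb profiles with [dichotomize_lead()].
#' @param config A [recurrence_config()].
#' @param edge_definitions Edge definitions to analyse (default both
#'   `"rr"` and `"entropy"`).
#' @param metrics Graph metrics to model (default all six).
#' @param binarize Binarize retained edges (default `FALSE`: weighted).
#' @param pool Embedding-parameter pooling, see
#'   [cohort_embedding_params()].
#' @param df_method P-value method for fixed-effect tests, see
#'   [fit_network_lmm()].
#' @param embed_options Named list overriding [embedding_params()] defaults
#'   (`max_lag`, `n_bins`, `m_max`, `r_tol`, `a_tol`).
#' @return An object of class `recurnet_fit` with components `params`,
#'   `edges`, `thresholds`, `networks`, `metric_table`, `fits` (named list
#'   of `network_lmm`), `tests` (data frame of all main-effect and
#'   per-element results), `groups`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_subjects = 8, n_timepoints = 60,
#'                                      seed = 42))
#' fit <- recurnet(coh)
#' summary(fit)
#' }
#' @export
recurnet <- function(cohort, groups = NULL,
                     config = recurrence_config(),
                     edge_definitions = c("rr", "entropy"),
                     metrics = GRAPH_METRICS,
                     binarize = FALSE,
                     pool = "none",
                     df_method = "wald",
                     embed_options = list()) {
  stopifnot(inherits(cohort, "elemental_cohort"))
  if (is.null(groups)) {
    groups <- if (!is.null(cohort$exposure)) cohort$exposure
              else dichotomize_lead(cohort)
  }
  params <- do.call(cohort_embedding_params,
                    c(list(cohort = cohort, pool = pool), embed_options))
  edges <- cohort_edges(cohort, params, config)

  tables <- list(); networks <- list(); thresholds <- c()
  for (ed in edge_definitions) {
    res <- network_metric_table(edges, ed, binarize = binarize)
    tables[[ed]] <- res$table
    networks[[ed]] <- res$networks
    thresholds[ed] <- res$threshold
  }
  mt <- assemble_metric_table(do.call(rbind, unname(tables)), groups)

  fits <- list(); tests <- list()
  for (ed in edge_definitions) {
    for (met in metrics) {
      key <- paste(ed, met, sep = ".")
      fit <- fit_network_lmm(mt, met, ed, df_method = df_method)
      fits[[key]] <- fit
      tst <- rbind(lead_main_effect(fit), per_element_contrasts(fit))
      tst <- cbind(edge_definition = ed, metric = met, tst)
      tests[[key]] <- tst
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL

  structure(list(params = params, edges = edges, thresholds = thresholds,
                 networks = networks, metric_table = mt, fits = fits,
                 tests = tests, groups = groups,
                 config = config, call = match.call()),
            class = "recurnet_fit")
}

#' @export
print.recurnet_fit <- function(x, ...) {
  ns <- length(unique(x$edges$subject_id))
  cat("Cross-recurrence network analysis\n")
  cat("  subjects:", ns, " (",
      sum(x$groups == "low"), "low /", sum(x$groups == "high"),
      "high lead exposure)\n")
  cat("  edge definitions:", paste(names(x$thresholds), collapse = ", "),
      "with global median thresholds",
      paste(format(x$thresholds, digits = 4), collapse = ", "), "\n")
  cat("  mixed models fitted:", length(x$fits), "\n")
  mains <- x$tests[x$tests$term == "pb_main", ]
  cat("  lead main-effect p-values:\n")
  print(data.frame(edge = mains$edge_definition, metric = mains$metric,
                   estimate = round(mains$estimate, 4),
                   p = signif(mains$p_value, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.recurnet_fit <- function(object, ...) {
  structure(list(tests = object$tests, thresholds = object$thresholds,
                 groups = object$groups,
                 singular = vapply(object$fits, `[[`, TRUE, "singular")),
            class = "summary.recurnet_fit")
}

#' @export
print.summary.recurnet_fit <- function(x, ...) {
  cat("Exposure-group tests on network metrics",
      "(Wald tests from element x Pb mixed models)\n\n")
  tt <- x$tests
  tt$estimate <- round(tt$estimate, 4)
  tt$se <- round(tt$se, 4)
  tt$statistic <- round(tt$statistic, 3)
  tt$p_value <- signif(tt$p_value, 3)
  print(tt, row.names = FALSE)
  if (any(x$singular))
    cat("\nNote: singular random-intercept fits:",
        paste(names(x$singular)[x$singular], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.recurnet_fit <- function(object, ...) {
  do.call(rbind, lapply(names(object$fits), function(k) {
    b <- object$fits[[k]]$beta
    data.frame(model = k, term = names(b), estimate = unname(b),
               stringsAsFactors = FALSE)
  }))
}

#' Plot one subject's metabolic network
#'
#' Draws the retained weighted graph for a subject and edge definition,
#' edge widths proportional to weight.
#'
#' @param x A `recurnet_fit`.
#' @param subject_id Subject to draw (default the first).
#' @param edge_definition `"rr"` or `"entropy"`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.recurnet_fit <- function(x, subject_id = NULL,
                              edge_definition = "rr", ...) {
  nets <- x$networks[[edge_definition]]
  if (is.null(subject_id)) subject_id <- names(nets)[1L]
  net <- nets[[subject_id]]
  g <- net_graph(net)
  ew <- igraph::E(g)$weight
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    edge.width = if (length(ew)) 1 + 4 * ew / max(ew) else 1,
    vertex.size = 28, vertex.color = "grey90",
    main = paste0(subject_id, " (", edge_definition, " edges)"), ...)
  invisible(x)
}
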