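#' Dichotomize lead exposure by median split
#'
#' Each subject is summarized by the mean of their Pb profile; subjects above
#' the cohort median are labelled `"high"`, the rest (including exact ties
#' at the median) `"low"`.
#'
#' @param cohort An `elemental_cohort`; every subject must have a Pb
#'   profile.
#' @return Named character vector of group labels per subject.
#' @export
dichotomize_lead <- function(cohort) {
  p <- cohort$profiles
  subjects <- unique(p$subject_id)
  pb <- p[p$element == "Pb", ]
  miss <- setdiff(subjects, unique(pb$subject_id))
  if (length(miss))
    stop_invalid("missing Pb profile for subject(s): ",
                 paste(miss, collapse = ", "))
  means <- as.numeric(tapply(pb$value, pb$subject_id, mean)[subjects])
  med <- median(means)
  if (all(means == means[1]))
    warning("all subject-mean Pb values are equal; ",
            "assigning every subject to the low group", call. = FALSE)
  setNames(ifelse(means > med, "high", "low"), subjects)
}

#' Assemble the long-format metric table
#'
#' Combines per-subject node metrics (both edge definitions) with exposure
#' groups into the table the mixed model consumes: one row per (subject,
#' element, metric, edge definition).
#'
#' @param metrics Data frame with columns `subject_id`, `element`,
#'   `edge_definition`, `metric`, `value` (from [network_metric_table()] or
#'   equivalent).
#' @param groups Named character vector of `"low"`/`"high"` labels per
#'   subject, e.g. from [dichotomize_lead()].
#' @return A data frame of class `metric_table` with an added `pb_group`
#'   column.
#' @export
assemble_metric_table <- function(metrics, groups) {
  if (is.null(groups))
    stop_invalid("no exposure groups supplied; ",
                 "derive them with dichotomize_lead()")
  need <- c("subject_id", "element", "edge_definition", "metric", "value")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop_invalid("metric table lacks column(s): ",
                 paste(miss, collapse = ", "))
  subjects <- unique(metrics$subject_id)
  nog <- setdiff(subjects, names(groups))
  if (length(nog))
    stop_invalid("no exposure group for subject(s): ",
                 paste(nog, collapse = ", "))

  # completeness: every subject x element cell per (metric, edge definition)
  for (ed in unique(metrics$edge_definition)) {
    for (mt in unique(metrics$metric)) {
      sub <- metrics[metrics$edge_definition == ed & metrics$metric == mt, ]
      have <- paste(sub$subject_id, sub$element)
      want <- as.vector(outer(subjects, NETWORK_ELEMENTS, paste))
      gap <- setdiff(want, have)
      if (length(gap))
        stop_invalid("missing metric cell(s) for ", mt, "/", ed, ": ",
                     paste(utils::head(gap, 5L), collapse = ", "))
    }
  }
  if (any(!is.finite(metrics$value)))
    stop_invalid("non-finite metric values present")
  metrics$pb_group <- unname(groups[metrics$subject_id])
  class(metrics) <- c("metric_table", class(metrics))
  metrics
}

#' Fit the element-by-exposure linear mixed model
#'
#' For one graph metric and one edge definition, fits by REML
#' `value ~ Element + Pb + Element:Pb + (1 | subject)` with Element
#' dummy-coded against a reference level (Ba by default) and Pb the
#' dichotomized exposure factor (reference `"low"`). The per-subject random
#' intercept absorbs the repeated measurement of all seven elements within a
#' subject. A singular fit (random-intercept variance estimated at zero) is
#' flagged, not fatal.
#'
#' @param table A `metric_table` from [assemble_metric_table()].
#' @param metric One of the six graph metrics.
#' @param edge_definition `"rr"` or `"entropy"`.
#' @param reference Reference element for dummy coding (default `"Ba"`);
#'   contrasts are invariant to this choice.
#' @param df_method `"wald"` (standard-normal Wald statistics, default) or
#'   `"satterthwaite"` (t statistics with Satterthwaite degrees of freedom,
#'   requires the lmerTest package).
#' @return An object of class `network_lmm`.
#' @export
fit_network_lmm <- function(table, metric, edge_definition,
                            reference = "Ba",
                            df_method = c("wald", "satterthwaite")) {
  df_method <- match.arg(df_method)
  sub <- table[table$metric == metric &
               table$edge_definition == edge_definition, ]
  if (!nrow(sub))
    stop_invalid("no rows for metric '", metric, "', edge definition '",
                 edge_definition, "'")
  if (length(unique(sub$pb_group)) < 2L)
    stop_invalid("need both exposure groups to fit the model")
  levs <- c(reference, setdiff(sort(unique(sub$element)), reference))
  sub$element <- factor(sub$element, levels = levs)
  sub$pb_group <- factor(sub$pb_group, levels = c("low", "high"))
  sub$subject_id <- factor(sub$subject_id)

  fit <- suppressMessages(
    lme4::lmer(value ~ element * pb_group + (1 | subject_id),
               data = sub, REML = TRUE))
  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))

  structure(list(fit = fit,
                 metric = metric,
                 edge_definition = edge_definition,
                 reference = reference,
                 elements = levs,
                 beta = lme4::fixef(fit),
                 vcov = as.matrix(stats::vcov(fit)),
                 sigma_subject = vc$sdcor[vc$grp == "subject_id"],
                 sigma_resid = vc$sdcor[vc$grp == "Residual"],
                 singular = singular,
                 df_method = df_method),
            class = "network_lmm")
}

#' @export
print.network_lmm <- function(x, ...) {
  cat("Element x exposure mixed model: ", x$metric, " (",
      x$edge_definition, " edges)\n", sep = "")
  cat("  random-intercept SD =", format(x$sigma_subject),
      "; residual SD =", format(x$sigma_resid),
      if (x$singular) " [singular fit]" else "", "\n")
  print(round(x$beta, 4))
  invisible(x)
}

# Wald (or Satterthwaite) test of a single linear combination c'beta
wald_contrast <- function(fit, cw, term) {
  est <- sum(cw * fit$beta)
  se <- sqrt(drop(t(cw) %*% fit$vcov %*% cw))
  stat <- est / se
  if (fit$df_method == "satterthwaite" &&
      requireNamespace("lmerTest", quietly = TRUE)) {
    ft <- lmerTest::as_lmerModLmerTest(fit$fit)
    ct <- lmerTest::contest1D(ft, cw, confint = FALSE)
    p <- ct[["Pr(>|t|)"]]
  } else {
    p <- 2 * pnorm(-abs(stat))
  }
  data.frame(term = term, estimate = est, se = se, statistic = stat,
             p_value = p, stringsAsFactors = FALSE)
}

#' Test the main effect of lead exposure
#'
#' Wald test of the marginal high-vs-low difference averaged over the seven
#' elements: the contrast `beta_Pb + mean(interaction terms) = 0`.
#'
#' @param fit A `network_lmm`.
#' @return One-row data frame: `term`, `estimate`, `se`, `statistic`,
#'   `p_value`.
#' @export
lead_main_effect <- function(fit) {
  cw <- setNames(numeric(length(fit$beta)), names(fit$beta))
  cw["pb_grouphigh"] <- 1
  inter <- grep(":pb_grouphigh$", names(fit$beta), value = TRUE)
  cw[inter] <- 1 / length(fit$elements)
  wald_contrast(fit, cw, "pb_main")
}

#' Per-element exposure contrasts
#'
#' Post-hoc Wald tests of the high-vs-low difference within each element:
#' `beta_Pb + beta_{element:Pb} = 0` (for the reference element simply
#' `beta_Pb = 0`). Raw p-values, no multiplicity correction; set
#' `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param fit A `network_lmm`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per element, terms `contrast_<element>`.
#' @export
per_element_contrasts <- function(fit, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(fit$elements, function(e) {
    cw <- setNames(numeric(length(fit$beta)), names(fit$beta))
    cw["pb_grouphigh"] <- 1
    if (e != fit$reference) {
      nm <- paste0("element", e, ":pb_grouphigh")
      cw[nm] <- 1
    }
    wald_contrast(fit, cw, paste0("contrast_", e))
  })
  out <- do.call(rbind, rows)
  ord <- order(sub("^contrast_", "", out$term))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out
}
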