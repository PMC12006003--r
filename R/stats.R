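#' Shapiro-Wilk normality gate
#'
#' Decides between the parametric and nonparametric branch of the testing
#' battery: parametric iff every group passes the Shapiro-Wilk test at
#' \code{alpha}. Degenerate (zero-variance) groups force the
#' nonparametric branch with a warning.
#'
#' @param groups named list of numeric vectors (one per time point), each
#'   of length >= 3.
#' @param alpha gate level (default 0.05).
#' @return \code{"parametric"} or \code{"nonparametric"}.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 3)) stop("every group needs n >= 3 for the normality gate")
  p <- vapply(groups, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (any(is.na(p))) {
    warning("zero-variance group: falling back to the nonparametric branch")
    return("nonparametric")
  }
  if (all(p > alpha)) "parametric" else "nonparametric"
}

#' Significance stars at the published thresholds
#'
#' @param p p value(s) in \[0, 1\].
#' @return character: \code{"***"} (p < 0.001), \code{"**"} (p < 0.01),
#'   \code{"*"} (p < 0.05), else \code{"ns"}.
#' @export
star_label <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  vapply(p, function(x)
    if (x < 0.001) "***" else if (x < 0.01) "**"
    else if (x < 0.05) "*" else "ns", character(1))
}

# Dunn's z post hoc comparisons of each group against the reference,
# mid-ranks with tie correction, multiplicity-adjusted over the performed
# comparisons only.
dunns_vs_reference <- function(groups, reference = 1L,
                               p_adjust_method = "bonferroni") {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  rk <- rank(x)                       # mid-ranks
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12
  rbar <- tapply(rk, g, mean)
  ni <- tabulate(g)
  others <- setdiff(seq_along(groups), reference)
  z <- vapply(others, function(j) {
    se <- sqrt((v0 - tie_corr) * (1 / ni[reference] + 1 / ni[j]))
    if (se == 0) return(0)
    (rbar[[j]] - rbar[[reference]]) / se
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = p_adjust_method)
  data.frame(comparison = paste0(names(groups)[others], " vs ",
                                 names(groups)[reference]),
             z = z, p_raw = p_raw, p_adj = pmin(p_adj, 1),
             stars = star_label(pmin(p_adj, 1)))
}

#' Omnibus test with Dunn's post hoc comparisons against baseline
#'
#' Parametric branch: one-way ANOVA; nonparametric branch: Kruskal-Wallis
#' (mid-ranks, tie-corrected). Either way, Dunn's z tests compare every
#' time point against the reference (t = 0) group, with multiplicity
#' adjustment over those comparisons only (Bonferroni by default, matching
#' the figure legends that star each time point against 0 s).
#'
#' @param groups named list of numeric vectors; the first (or
#'   \code{reference}) is the t = 0 baseline.
#' @param gate \code{"parametric"}, \code{"nonparametric"}, or NULL to run
#'   \code{\link{normality_gate}}.
#' @param reference index of the baseline group.
#' @param p_adjust_method passed to \code{\link[stats]{p.adjust}}.
#' @return list with \code{gate}, \code{omnibus} (test, statistic, p,
#'   stars) and \code{posthoc} (data.frame of Dunn comparisons).
#' @export
omnibus_with_dunns <- function(groups, gate = NULL, reference = 1L,
                               p_adjust_method = "bonferroni") {
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (is.null(gate)) gate <- normality_gate(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (stats::sd(x) == 0) {
    omni <- list(test = "degenerate (all values tied)",
                 statistic = NA_real_, p = 1, stars = "ns")
  } else if (gate == "parametric") {
    fit <- stats::aov(x ~ g)
    s <- summary(fit)[[1]]
    omni <- list(test = "one-way ANOVA", statistic = s[["F value"]][1],
                 p = s[["Pr(>F)"]][1], stars = star_label(s[["Pr(>F)"]][1]))
  } else {
    kt <- stats::kruskal.test(x, g)
    omni <- list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
                 p = kt$p.value, stars = star_label(kt$p.value))
  }
  ph <- if (stats::sd(x) == 0) NULL else
    dunns_vs_reference(groups, reference, p_adjust_method)
  list(gate = gate, omnibus = omni, posthoc = ph)
}

#' Paired change test against zero
#'
#' Tests whether per-cell morphometric changes are centred at zero: a
#' one-sample t test when the changes pass the Shapiro-Wilk gate, else the
#' Wilcoxon signed-rank test.
#'
#' @param changes numeric vector of per-cell change values, n >= 5.
#' @param alpha normality-gate level.
#' @return list with \code{gate}, \code{test}, \code{statistic}, \code{p},
#'   \code{stars}.
#' @export
paired_change_test <- function(changes, alpha = 0.05) {
  stopifnot(length(changes) >= 5)
  if (all(changes == 0)) {
    return(list(gate = "degenerate", test = "all-zero changes",
                statistic = NA_real_, p = 1, stars = "ns"))
  }
  sw_p <- if (stats::sd(changes) == 0) 0 else
    stats::shapiro.test(changes)$p.value
  if (sw_p > alpha) {
    tt <- stats::t.test(changes, mu = 0)
    list(gate = "parametric", test = "one-sample t",
         statistic = unname(tt$statistic), p = tt$p.value,
         stars = star_label(tt$p.value))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(changes, mu = 0, exact = FALSE))
    list(gate = "nonparametric", test = "Wilcoxon signed-rank",
         statistic = unname(wt$statistic), p = wt$p.value,
         stars = star_label(wt$p.value))
  }
}
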