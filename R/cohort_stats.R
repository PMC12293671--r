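#' Split a cohort table into group samples
#'
#' @param table data frame with a `group` column.
#' @param parameter name of the numeric column to extract.
#' @return named list of numeric vectors, one per group (NA dropped).
#' @export
split_groups <- function(table, parameter) {
  if (!parameter %in% names(table)) stop("missing column: ", parameter)
  if (!"group" %in% names(table)) stop("missing column: group")
  lapply(split(table[[parameter]], table$group), function(v) v[!is.na(v)])
}

check_groups <- function(groups, min_n = 2L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  invisible(groups)
}

#' Normality-gated choice of omnibus test
#'
#' Shapiro-Wilk is applied to each group separately; one-way ANOVA is
#' selected iff every group's p-value is at least `alpha`, otherwise
#' Kruskal-Wallis.  Zero-variance (constant) groups make Shapiro-Wilk
#' undefined and route to Kruskal-Wallis with a warning.
#'
#' @param groups named list of numeric vectors (each n >= 3).
#' @param alpha normality test level (default 0.05).
#' @return `"anova"` or `"kruskal_wallis"`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  check_groups(groups)
  ns <- lengths(groups)
  if (any(ns < 3L))
    stop("every group needs n >= 3 for the normality gate (got ",
         paste(ns, collapse = "/"), ")")
  if (any(vapply(groups, function(v) stats::sd(v) == 0, logical(1)))) {
    warning("constant group: Shapiro-Wilk undefined, using Kruskal-Wallis")
    return("kruskal_wallis")
  }
  p <- vapply(groups, function(v) stats::shapiro.test(v)$p.value, numeric(1))
  if (all(p >= alpha)) "anova" else "kruskal_wallis"
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA; `df = (k - 1, N - k)`.
#'
#' @param groups named list of numeric vectors.
#' @return object of class `omnibus_result` with `test`, `statistic`,
#'   `df`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  if (all(vapply(groups, function(v) stats::sd(v) == 0, logical(1))))
    stop("zero within-group variance everywhere: ANOVA undefined")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names_or_index(groups), lengths(groups)))
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(list(test = "anova",
                 statistic = unname(ft$statistic),
                 df = unname(ft$parameter),
                 p_value = unname(ft$p.value)),
            class = "omnibus_result")
}

names_or_index <- function(groups) {
  nm <- names(groups)
  if (is.null(nm) || any(nm == "")) as.character(seq_along(groups)) else nm
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with `df = k - 1` and chi-squared p-value.
#'
#' @param groups named list of numeric vectors.
#' @return object of class `omnibus_result`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values identical: Kruskal-Wallis undefined")
  g <- factor(rep(names_or_index(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  structure(list(test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = unname(kt$p.value)),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  if (x$test == "anova")
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
                x$df[1], x$df[2], x$statistic, x$p_value))
  else
    cat(sprintf("Kruskal-Wallis: H(%d) = %.4g, p = %.4g\n",
                x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on mean ranks of the pooled sample with
#' tie-corrected variance
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`,
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.  Adjusted
#' p-values are Bonferroni over all `k (k - 1) / 2` pairs, capped at 1
#' (emulating multiplicity-adjusted Dunn output of common statistical
#' software); Holm is available as an option.
#'
#' @param groups named list of numeric vectors.
#' @param adjust `"bonferroni"` (default) or `"holm"`.
#' @return data frame with columns `group_a`, `group_b`, `z`, `p_value`,
#'   `adjusted_p`, `method`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  check_groups(groups)
  nm <- names_or_index(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, g, mean)
  n <- lengths(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  z <- p <- numeric(m)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[a] + 1 / n[b]))
    z[j] <- (rbar[a] - rbar[b]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  adj <- if (adjust == "bonferroni") pmin(1, m * p) else stats::p.adjust(p, "holm")
  data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
             z = z, p_value = p, adjusted_p = adj,
             method = "dunn", stringsAsFactors = FALSE)
}

#' Tukey's multiple comparisons test
#'
#' Studentized-range based adjusted p-values with pooled mean-square error
#' and Tukey-Kramer standard errors for unbalanced group sizes.
#'
#' @param groups named list of numeric vectors.
#' @return data frame with columns `group_a`, `group_b`, `diff`,
#'   `adjusted_p`, `method`.
#' @export
tukey_posthoc <- function(groups) {
  check_groups(groups)
  nm <- names_or_index(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  if (all(vapply(groups, function(v) stats::sd(v) == 0, logical(1))))
    stop("zero pooled variance: Tukey test undefined")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  pairs_lab <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group_a = vapply(pairs_lab, `[`, character(1), 2),
             group_b = vapply(pairs_lab, `[`, character(1), 1),
             diff = -unname(tk[, "diff"]),
             adjusted_p = unname(tk[, "p adj"]),
             method = "tukey", stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average-tie) ranks; two-sided p-value from the
#' t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return object of class `correlation_result` with `rho`, `n`, `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, n = n, p_value = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rs(%d) = %.3f, p = %.4g\n",
              x$n - 2, x$rho, x$p_value))
  invisible(x)
}

#' Full cohort comparison across groups
#'
#' For each requested parameter: per-group Shapiro-Wilk gate, then one-way
#' ANOVA (all groups normal) or Kruskal-Wallis; when the omnibus p-value is
#' below `alpha`, the matching post hoc test (Tukey after ANOVA, Dunn after
#' Kruskal-Wallis) produces one adjusted p-value per unordered group pair
#' (6 pairs for 4 groups).  No correction is applied across parameters.
#'
#' @param table per-eye data frame with a `group` column.
#' @param parameters character vector of metric column names.
#' @param alpha significance level gating the post hoc stage (default 0.05).
#' @param dunn_adjust adjustment for Dunn's test (`"bonferroni"` or
#'   `"holm"`).
#' @return object of class `cohort_comparison`: a list with per-parameter
#'   `omnibus` results and `posthoc` tables (`NULL` where not run).
#' @export
run_full_comparison <- function(table, parameters, alpha = 0.05,
                                dunn_adjust = "bonferroni") {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c("group", parameters), names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  res <- lapply(parameters, function(par) {
    groups <- split_groups(table, par)
    branch <- normality_gate(groups, alpha = alpha)
    omni <- if (branch == "anova") one_way_anova(groups) else kruskal_wallis(groups)
    post <- NULL
    if (is.finite(omni$p_value) && omni$p_value < alpha) {
      post <- if (branch == "anova") tukey_posthoc(groups)
              else dunn_posthoc(groups, adjust = dunn_adjust)
    }
    list(parameter = par, omnibus = omni, posthoc = post)
  })
  names(res) <- parameters
  structure(list(results = res, alpha = alpha,
                 groups = names(split(table$group, table$group))),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Cohort comparison (alpha =", x$alpha, ")\n")
  for (r in x$results) {
    o <- r$omnibus
    lab <- if (o$test == "anova")
      sprintf("F(%d, %d) = %.4g", o$df[1], o$df[2], o$statistic)
    else sprintf("H(%d) = %.4g", o$df, o$statistic)
    cat(sprintf("%-24s %s, p = %.4g%s\n", r$parameter, lab, o$p_value,
                if (is.null(r$posthoc)) "  [post hoc not run]" else ""))
    if (!is.null(r$posthoc)) {
      ph <- r$posthoc
      for (i in seq_len(nrow(ph)))
        cat(sprintf("    %s vs %s: p adj = %.4g (%s)\n",
                    ph$group_a[i], ph$group_b[i], ph$adjusted_p[i], ph$method[i]))
    }
  }
  invisible(x)
}

#' Long-format export of a cohort comparison
#'
#' @param x a `cohort_comparison`.
#' @return data frame with one row per parameter x pair (omnibus rows have
#'   `NA` pair columns).
#' @export
comparison_table <- function(x) {
  stopifnot(inherits(x, "cohort_comparison"))
  rows <- lapply(x$results, function(r) {
    o <- r$omnibus
    base <- data.frame(parameter = r$parameter, test = o$test,
                       statistic = o$statistic,
                       df1 = o$df[1], df2 = if (length(o$df) > 1) o$df[2] else NA,
                       p_value = o$p_value,
                       group_a = NA_character_, group_b = NA_character_,
                       adjusted_p = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(r$posthoc)) {
      ph <- r$posthoc
      base <- rbind(base, data.frame(
        parameter = r$parameter, test = ph$method, statistic = NA_real_,
        df1 = NA, df2 = NA,
        p_value = if ("p_value" %in% names(ph)) ph$p_value else NA_real_,
        group_a = ph$group_a, group_b = ph$group_b,
        adjusted_p = ph$adjusted_p, stringsAsFactors = FALSE))
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
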