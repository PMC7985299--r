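#' Assign pooled quartile categories
#'
#' Cuts values into quartiles q1..q4 at the pooled 25th/50th/75th percentiles
#' (linear interpolation between closest ranks), with half-open intervals
#' `[low, high)`: a value equal to a cut point falls in the upper quartile.
#' Explicit `breaks` (three ascending cut points, interpreted as the lower
#' bounds of q2..q4) allow classification against published boundaries.
#'
#' @param values Numeric vector (>= 4 finite values when `breaks` is NULL).
#' @param breaks Optional numeric length-3 vector of cut points.
#' @return Tibble with `value`, `quartile` (factor q1..q4) and `q4`
#'   (logical, highest-vs-lower-three coding); the cut points are attached
#'   as attribute `"breaks"`.
#' @export
assign_quartiles <- function(values, breaks = NULL) {
  fin <- values[is.finite(values)]
  if (is.null(breaks)) {
    if (length(fin) < 4) stop("need >= 4 finite values", call. = FALSE)
    if (max(fin) == min(fin))
      stop("all values identical: quartiles undefined", call. = FALSE)
    breaks <- stats::quantile(fin, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  }
  stopifnot(length(breaks) == 3, !is.unsorted(breaks))
  q <- 1L + (values >= breaks[1]) + (values >= breaks[2]) + (values >= breaks[3])
  out <- tibble::tibble(value = values,
                        quartile = factor(paste0("q", q),
                                          levels = paste0("q", 1:4)),
                        q4 = q == 4L)
  attr(out, "breaks") <- breaks
  out
}

#' Menopausal-status proxy from age
#'
#' Age categories standing in for menopausal status: `< 45` premenopausal,
#' `>= 45` and `< 55` perimenopausal, `>= 55` postmenopausal.
#'
#' @param age_years Numeric vector of ages (> 0).
#' @return Factor with levels `premenopausal`, `perimenopausal`,
#'   `postmenopausal`.
#' @export
age_category <- function(age_years) {
  if (any(!is.finite(age_years) | age_years <= 0))
    stop("ages must be positive and finite", call. = FALSE)
  lv <- c("premenopausal", "perimenopausal", "postmenopausal")
  factor(lv[1L + (age_years >= 45) + (age_years >= 55)], levels = lv)
}

#' Two-sided group comparison and correlation tests
#'
#' Thin, uniform wrapper over the standard tests used to relate adipose
#' features to age categories and to each other: Mann-Whitney U
#' (`wilcox.test`), Kruskal-Wallis, Student's t, one-way ANOVA, and
#' Spearman's rho (with a Fisher-z 95\% confidence interval using the
#' Bonett-Wright standard error).
#'
#' @param x Numeric values; for `"spearman"` the first of two paired vectors.
#' @param g Grouping vector (two groups for `mann_whitney` / `t_test`, two
#'   or more for `kruskal_wallis` / `anova`); for `"spearman"` the second
#'   paired numeric vector.
#' @param method One of `"mann_whitney"`, `"kruskal_wallis"`, `"t_test"`,
#'   `"anova"`, `"spearman"`.
#' @return One-row tibble: `method`, `statistic`, `df` (NA where the test
#'   has none), `p_value`, and for Spearman `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
group_comparison <- function(x, g,
                             method = c("mann_whitney", "kruskal_wallis",
                                        "t_test", "anova", "spearman")) {
  method <- match.arg(method)
  if (method == "spearman") {
    ok <- is.finite(x) & is.finite(g)
    x <- x[ok]; y <- g[ok]
    if (length(x) < 4) stop("spearman needs >= 4 complete pairs", call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate)
    se <- sqrt((1 + rho^2 / 2) / (length(x) - 3))
    z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
    return(tibble::tibble(method = method, statistic = unname(ct$statistic),
                          df = NA_real_, p_value = ct$p.value, estimate = rho,
                          conf.low = tanh(z - 1.959964 * se),
                          conf.high = tanh(z + 1.959964 * se)))
  }
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs >= 2 observations", call. = FALSE)
  if (method %in% c("mann_whitney", "t_test") && nlevels(g) != 2)
    stop(method, " needs exactly 2 groups", call. = FALSE)
  switch(method,
    mann_whitney = {
      ht <- stats::wilcox.test(x ~ g, exact = FALSE)
      tibble::tibble(method = method, statistic = unname(ht$statistic),
                     df = NA_real_, p_value = ht$p.value)
    },
    kruskal_wallis = {
      ht <- stats::kruskal.test(x, g)
      tibble::tibble(method = method, statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p_value = ht$p.value)
    },
    t_test = {
      ht <- stats::t.test(x ~ g)
      tibble::tibble(method = method, statistic = unname(ht$statistic),
                     df = unname(ht$parameter), p_value = ht$p.value)
    },
    anova = {
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      tibble::tibble(method = method, statistic = s[["F value"]][1],
                     df = s[["Df"]][1], p_value = s[["Pr(>F)"]][1])
    })
}

#' Shapiro-Wilk normality screen per group
#'
#' @param x Numeric values.
#' @param g Grouping vector.
#' @return Tibble with one row per group: `group`, `n`, `statistic`,
#'   `p_value` (NA for groups with fewer than 3 observations).
#' @export
normality_screen <- function(x, g) {
  tibble::tibble(x = x, group = factor(g)) |>
    dplyr::filter(is.finite(x)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     statistic = if (dplyr::n() >= 3 && stats::sd(x) > 0)
                       unname(stats::shapiro.test(x)$statistic) else NA_real_,
                     p_value = if (dplyr::n() >= 3 && stats::sd(x) > 0)
                       stats::shapiro.test(x)$p.value else NA_real_,
                     .groups = "drop")
}
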