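# Conditional logistic regression for matched case-control sets.
# The conditional likelihood is prod over sets of
#   exp(x_case' beta) / sum_j exp(x_j' beta),
# maximised by Newton-Raphson with step-halving. Matching absorbs per-set
# nuisance effects, so no intercept is estimated.

#' Fit a conditional logistic regression on matched sets
#'
#' @param data Tibble with one row per subject.
#' @param formula One-sided formula naming the model terms (factors and
#'   interactions follow the usual `model.matrix` rules), e.g.
#'   `~ area_q4 + cox2_high` or a character vector of column names.
#' @param set,case Column names (strings) of the matched-set id and the
#'   case indicator (default `"set_id"`, `"is_case"`).
#' @param max_iter,tol Newton-Raphson controls: stop when the largest
#'   gradient component falls below `tol` (default 1e-8) or after
#'   `max_iter` (default 50) iterations.
#' @return An object of class `clr_fit`: coefficients (log odds ratios),
#'   model-based standard errors from the observed information, odds ratios
#'   with Wald 95\% confidence intervals, the maximised conditional
#'   log-likelihood, the null log-likelihood, and bookkeeping (sets used,
#'   sets dropped for missing covariates, convergence, separation flag).
#'   Subjects with missing model covariates drop their whole set. Terms
#'   constant within every set are non-identifiable and raise an error;
#'   terms aliased with earlier terms are dropped with a warning.
#' @export
clr_fit <- function(data, formula, set = "set_id", case = "is_case",
                    max_iter = 50L, tol = 1e-8) {
  if (is.character(formula))
    formula <- stats::as.formula(paste("~", paste(formula, collapse = " + ")))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  X <- stats::model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (!ncol(X)) stop("model has no terms", call. = FALSE)
  sid <- data[[set]]; cs <- as.logical(data[[case]])
  ok_row <- stats::complete.cases(X)
  bad_sets <- unique(sid[!ok_row])
  keep <- !(sid %in% bad_sets)
  X <- X[keep, , drop = FALSE]; sid <- sid[keep]; cs <- cs[keep]
  # keep only well-formed sets: exactly one case, at least one control
  tab <- table(sid, cs)
  good <- rownames(tab)[tab[, "TRUE"] == 1 & tab[, "FALSE"] >= 1]
  keep2 <- sid %in% good
  X <- X[keep2, , drop = FALSE]; sid <- sid[keep2]; cs <- cs[keep2]
  if (length(unique(sid)) < 2) stop("fewer than 2 informative sets", call. = FALSE)
  sf <- factor(sid)
  # within-set centering exposes non-identifiable structure
  Xc <- X - rowsum(X, sf)[as.integer(sf), , drop = FALSE] /
    as.vector(table(sf))[as.integer(sf)]
  const <- apply(Xc, 2, function(v) all(abs(v) < 1e-12))
  if (any(const))
    stop("non-identifiable term(s) constant within every set: ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  qrc <- qr(Xc)
  if (qrc$rank < ncol(Xc)) {
    dropped <- colnames(X)[qrc$pivot[-seq_len(qrc$rank)]]
    warning("dropping aliased term(s): ", paste(dropped, collapse = ", "))
    keep_col <- sort(qrc$pivot[seq_len(qrc$rank)])
    X <- X[, keep_col, drop = FALSE]
  }
  p <- ncol(X)
  beta <- rep(0, p)
  set_sizes <- as.vector(table(sf))
  ll_null <- -sum(log(set_sizes))
  score <- function(b) {
    eta <- drop(X %*% b)
    mx <- stats::ave(eta, sf, FUN = max)
    e <- exp(eta - mx)
    denom <- rowsum(e, sf)                      # one per set (sorted levels)
    w <- e / denom[as.integer(sf)]
    ll <- sum(eta[cs]) - sum(log(denom)) - sum(tapply(mx, sf, FUN = function(z) z[1]))
    wX <- w * X
    xbar <- rowsum(wX, sf)                      # set-wise weighted means
    grad <- colSums(X[cs, , drop = FALSE]) - colSums(xbar)
    hess <- crossprod(X, wX) - crossprod(xbar)  # observed information
    list(ll = ll, grad = grad, hess = hess)
  }
  sc <- score(beta)
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(sc$grad)) < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(sc$hess, sc$grad),
                      error = function(e) stop("singular information matrix",
                                               call. = FALSE))
    step <- 1
    repeat {
      cand <- beta + step * delta
      sc_new <- score(cand)
      if (sc_new$ll >= sc$ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * delta
    sc <- sc_new
  }
  if (max(abs(sc$grad)) < tol) converged <- TRUE
  separation <- any(abs(beta) > 15)
  if (separation)
    warning("possible separation: |log OR| > 15 for ",
            paste(colnames(X)[abs(beta) > 15], collapse = ", "))
  if (!converged)
    warning("Newton-Raphson did not converge in ", max_iter,
            " iterations (max |gradient| = ", format(max(abs(sc$grad))), ")")
  se <- sqrt(diag(solve(sc$hess)))
  zcrit <- 1.959964
  structure(list(
    terms = colnames(X), beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    or = exp(beta), ci_low = exp(beta - zcrit * se),
    ci_high = exp(beta + zcrit * se),
    loglik = sc$ll, loglik_null = ll_null,
    n_sets_used = length(unique(sid)), n_sets_dropped = length(bad_sets),
    set_ids_used = sort(unique(as.character(sid))),
    n_subjects = nrow(X), iterations = iter,
    converged = converged, separation = separation), class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat("Conditional logistic regression (", x$n_sets_used, " matched sets, ",
      x$n_subjects, " subjects)\n", sep = "")
  print(tidy(x), ...)
  cat("log-likelihood:", format(x$loglik), " (null:", format(x$loglik_null), ")\n")
  invisible(x)
}

#' Tidy a conditional logistic fit
#'
#' @param x A `clr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate` (log OR),
#'   `std.error`, `or`, `conf.low`, `conf.high` (Wald 95\% limits on the OR
#'   scale), `statistic` (Wald z), `p.value` (two-sided Wald).
#' @exportS3Method generics::tidy
tidy.clr_fit <- function(x, ...) {
  z <- x$beta / x$se
  tibble::tibble(term = x$terms, estimate = unname(x$beta),
                 std.error = unname(x$se), or = unname(x$or),
                 conf.low = unname(x$ci_low), conf.high = unname(x$ci_high),
                 statistic = unname(z),
                 p.value = 2 * stats::pnorm(-abs(z)))
}

#' Glance at a conditional logistic fit
#'
#' @inheritParams tidy.clr_fit
#' @return One-row tibble: `logLik`, `null.logLik`, LR statistic and p-value
#'   against the null model, `df`, `AIC`, `n.sets`, `n.subjects`,
#'   `converged`.
#' @exportS3Method generics::glance
glance.clr_fit <- function(x, ...) {
  stat <- 2 * (x$loglik - x$loglik_null)
  df <- length(x$beta)
  tibble::tibble(logLik = x$loglik, null.logLik = x$loglik_null,
                 lr.statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 AIC = -2 * x$loglik + 2 * df,
                 n.sets = x$n_sets_used, n.subjects = x$n_subjects,
                 converged = x$converged)
}

#' Likelihood-ratio test between nested conditional logistic fits
#'
#' @param fit_null,fit_full Two `clr_fit` objects fitted on the identical
#'   matched sets, with the null model's terms a subset of the full model's.
#' @return Tibble: `statistic` (`2 * (loglik_full - loglik_null)`), `df`
#'   (difference in parameter count), `p_value` (chi-square upper tail;
#'   1 when `df` is 0).
#' @export
likelihood_ratio_test <- function(fit_null, fit_full) {
  stopifnot(inherits(fit_null, "clr_fit"), inherits(fit_full, "clr_fit"))
  if (!identical(fit_null$set_ids_used, fit_full$set_ids_used))
    stop("models were fitted on different matched sets", call. = FALSE)
  if (!all(fit_null$terms %in% fit_full$terms))
    stop("models are not nested (null terms must be a subset of full terms)",
         call. = FALSE)
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  df <- length(fit_full$beta) - length(fit_null$beta)
  if (df < 0) stop("full model has fewer parameters than null", call. = FALSE)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

# LR p-value of a single fitted model against its own null (beta = 0).
lr_p_vs_null <- function(fit) {
  stat <- max(0, 2 * (fit$loglik - fit$loglik_null))
  stats::pchisq(stat, length(fit$beta), lower.tail = FALSE)
}

#' Build a multivariable model by univariate screening
#'
#' Fits each candidate term univariately, keeps those with a likelihood-ratio
#' p-value at or below `entry_p` (default 0.1), fits the multivariable model
#' on the kept terms, and optionally tests pairwise interaction terms by LR
#' against the main-effects model.
#'
#' @param data Subject tibble (see [clr_fit()]).
#' @param candidates Character vector of candidate term names (>= 1).
#' @param entry_p Univariate LR p-value threshold for inclusion.
#' @param interactions Optional character vector of `"a:b"` interaction terms
#'   between included main effects.
#' @param set,case As in [clr_fit()].
#' @return List with `fit` (the multivariable `clr_fit`, or `NULL` when
#'   nothing enters), `inclusion` (tibble: term, univariate LR p, included
#'   flag), and `interactions` (tibble of LR tests, when requested).
#' @export
build_multivariable <- function(data, candidates, entry_p = 0.1,
                                interactions = NULL,
                                set = "set_id", case = "is_case") {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  uni_p <- vapply(candidates, function(tm) {
    lr_p_vs_null(clr_fit(data, tm, set = set, case = case))
  }, numeric(1))
  included <- uni_p <= entry_p
  log_tbl <- tibble::tibble(term = candidates, p_lr_univariate = unname(uni_p),
                            included = unname(included))
  if (!any(included)) {
    warning("no candidate met entry_p = ", entry_p, "; multivariable model is empty")
    return(list(fit = NULL, inclusion = log_tbl, interactions = NULL))
  }
  main <- candidates[included]
  fit_main <- clr_fit(data, main, set = set, case = case)
  inter_tbl <- NULL
  if (length(interactions)) {
    inter_tbl <- dplyr::bind_rows(purrr::map(interactions, function(tm) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% main))
        return(tibble::tibble(interaction = tm, statistic = NA_real_,
                              df = NA_integer_, p_value = NA_real_,
                              note = "main effects not both included"))
      fit_int <- clr_fit(data, c(main, tm), set = set, case = case)
      lrt <- likelihood_ratio_test(fit_main, fit_int)
      tibble::tibble(interaction = tm, statistic = lrt$statistic,
                     df = lrt$df, p_value = lrt$p_value, note = "")
    }))
  }
  list(fit = fit_main, inclusion = log_tbl, interactions = inter_tbl)
}
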