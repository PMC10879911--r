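#' Tie-corrected Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (so the statistic is the
#' Pearson correlation of the rank vectors) and a p-value from the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on `n - 2` degrees
#' of freedom.  Used both for covariate independence screening and for the
#' richness-elevation and richness-effort relationships.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return a list with `rho`, `p_value` and `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Pairwise Spearman screening of model covariates
#'
#' @param table a data.frame (typically from [richness_per_site()]).
#' @param vars character vector of numeric column names to screen.
#' @return a data.frame of all unordered pairs with `rho` and `p_value`.
#' @export
correlation_screen <- function(table, vars) {
  stopifnot(all(vars %in% names(table)))
  pairs <- utils::combn(vars, 2)
  out <- apply(pairs, 2, function(v) {
    ct <- spearman_correlation(table[[v[1]]], table[[v[2]]])
    data.frame(var1 = v[1], var2 = v[2], rho = ct$rho,
               p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Quasipoisson log-link GLM of species richness
#'
#' Fits a Poisson-likelihood log-link regression of site richness on the
#' requested covariates, with a multiplicative dispersion parameter
#' \eqn{\phi} estimated from the Pearson chi-square,
#' \eqn{\hat\phi = \sum r_P^2 / (n - p)}.  Point estimates are identical to
#' the Poisson fit; standard errors are the Poisson ones scaled by
#' \eqn{\sqrt{\hat\phi}}, which guards inference against the overdispersion
#' typical of richness counts.  `study_area` (if present among `terms`)
#' enters as an unordered factor with treatment contrasts, reference level
#' first alphabetically.
#'
#' @param table a richness table (see [richness_per_site()]).
#' @param terms character vector of covariate names; empty for the
#'   intercept-only model.
#' @param response name of the count response column (default `"richness"`).
#' @return an object of class `count_glm_fit`: a list with `terms`,
#'   `coefficients`, `std_errors`, `dispersion`, `null_deviance`/`df_null`,
#'   `deviance`/`df_residual`, `n`, and the underlying `glm` object.
#' @export
fit_quasipoisson <- function(table, terms = character(0),
                             response = "richness") {
  stopifnot(response %in% names(table))
  missing_terms <- setdiff(terms, names(table))
  if (length(missing_terms)) {
    stop("terms not in table: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  data <- table
  if ("study_area" %in% terms) {
    data$study_area <- factor(data$study_area)
  }
  rhs <- if (length(terms)) terms else "1"
  fml <- stats::reformulate(rhs, response = response)
  fit <- glm(fml, family = quasipoisson(link = "log"), data = data,
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  if (!fit$converged) {
    stop("IRLS failed to converge for terms: ", paste(terms, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(coef(fit))) {
    stop("singular design (aliased coefficients): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(stats::model.frame(fit))
  p <- length(coef(fit))
  if (n <= p) stop("need more sites than parameters (n > p)", call. = FALSE)
  phi <- sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
  se <- sqrt(diag(stats::vcov(fit)))  # summary.glm scales quasi vcov by phi

  structure(list(
    terms = terms,
    response = response,
    formula = fml,
    coefficients = coef(fit),
    std_errors = se,
    dispersion = phi,
    null_deviance = fit$null.deviance,
    df_null = fit$df.null,
    deviance = fit$deviance,
    df_residual = df.residual(fit),
    n = n,
    data = data,
    glm = fit
  ), class = "count_glm_fit")
}

#' @export
print.count_glm_fit <- function(x, ...) {
  cat("Quasipoisson GLM:", deparse(x$formula), "\n")
  tab <- data.frame(estimate = x$coefficients, std_error = x$std_errors)
  print(round(tab, 4))
  cat(sprintf("dispersion (Pearson) = %.3f\n", x$dispersion))
  cat(sprintf("null deviance %.2f (df %d); residual deviance %.2f (df %d); n = %d\n",
              x$null_deviance, x$df_null, x$deviance, x$df_residual, x$n))
  invisible(x)
}

#' Analysis-of-deviance F-test between nested quasipoisson fits
#'
#' Compares a reduced model with the fuller model it is nested in, using
#' \deqn{F = \frac{(D_{reduced} - D_{full})/\Delta df}{\hat\phi_{full}}}
#' with the p-value from the F distribution on
#' \eqn{(\Delta df,\; df_{residual,full})}.  This is the test used after
#' each elimination step of [backwards_stepwise()].
#'
#' @param reduced,full `count_glm_fit` objects on the same data, with
#'   `reduced$terms` a subset of `full$terms`.
#' @return a one-row `data.frame` of class `deviance_test` with columns
#'   `term_tested`, `f_value`, `df_num`, `df_den`, `p_value`.
#' @export
anova_f <- function(reduced, full) {
  stopifnot(inherits(reduced, "count_glm_fit"), inherits(full, "count_glm_fit"))
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested: reduced terms must be a subset of full terms",
         call. = FALSE)
  }
  if (reduced$n != full$n) {
    stop("models were fitted to different data (n differs)", call. = FALSE)
  }
  dropped <- setdiff(full$terms, reduced$terms)
  ddf <- reduced$df_residual - full$df_residual
  if (ddf == 0) {
    res <- data.frame(term_tested = if (length(dropped)) paste(dropped, collapse = "+") else "<none>",
                      f_value = 0, df_num = 0L, df_den = full$df_residual,
                      p_value = 1)
    class(res) <- c("deviance_test", "data.frame")
    return(res)
  }
  f <- ((reduced$deviance - full$deviance) / ddf) / full$dispersion
  f <- max(f, 0)
  res <- data.frame(
    term_tested = paste(dropped, collapse = "+"),
    f_value = f, df_num = as.integer(ddf),
    df_den = full$df_residual,
    p_value = pf(f, ddf, full$df_residual, lower.tail = FALSE)
  )
  class(res) <- c("deviance_test", "data.frame")
  res
}

# Single-term deletion F-tests from a fitted model: one row per term.
drop_term_tests <- function(fit) {
  rows <- lapply(fit$terms, function(tm) {
    reduced <- fit_quasipoisson(fit$data, setdiff(fit$terms, tm),
                                response = fit$response)
    anova_f(reduced, fit)
  })
  out <- do.call(rbind, rows)
  out$term_tested <- fit$terms
  out
}

#' Backwards stepwise elimination by analysis-of-deviance F-tests
#'
#' Starting from the full model, repeatedly tests each remaining term by a
#' single-deletion F-test ([anova_f()]) and removes the term with the
#' largest p-value above `alpha`; the model is refitted and the comparison
#' recorded.  Two stopping rules are available:
#'
#' * `"deviance_guarded"` (default): a term is only removable when its
#'   deletion F-statistic is below `f_max` as well as non-significant, i.e.
#'   removal may not cost more than `f_max` units of scaled deviance per
#'   degree of freedom.  With the default `f_max = 2` this mirrors a
#'   quasi-AIC rule, and lets marginally informative covariates survive a
#'   strict significance cut.
#' * `"strict_alpha"`: any term with deletion p > `alpha` is removable.
#'
#' @param table richness table.
#' @param terms character vector: the full model's covariates.
#' @param alpha significance level for retention (default 0.05).
#' @param criterion stopping rule, see Details.
#' @param f_max scaled-deviance budget per df for `"deviance_guarded"`.
#' @param response count response column name.
#' @return an object of class `stepwise_fit`: list with the final
#'   `count_glm_fit` (`$fit`), the elimination `$trace` (one row per step:
#'   term dropped, F, df, p, residual deviance after refit), and the
#'   configuration.
#' @export
backwards_stepwise <- function(table, terms, alpha = 0.05,
                               criterion = c("deviance_guarded",
                                             "strict_alpha"),
                               f_max = 2, response = "richness") {
  criterion <- match.arg(criterion)
  current <- terms
  trace <- NULL
  step <- 0L
  repeat {
    fit <- fit_quasipoisson(table, current, response = response)
    if (!length(current)) break
    tests <- drop_term_tests(fit)
    removable <- tests$p_value > alpha
    if (criterion == "deviance_guarded") {
      removable <- removable & tests$f_value < f_max
    }
    if (!any(removable)) break
    victim <- which.max(ifelse(removable, tests$p_value, -Inf))
    dropped <- tests[victim, , drop = FALSE]
    current <- setdiff(current, dropped$term_tested)
    refit <- fit_quasipoisson(table, current, response = response)
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, dropped = dropped$term_tested,
      f_value = dropped$f_value, df_num = dropped$df_num,
      df_den = dropped$df_den, p_value = dropped$p_value,
      deviance_before = fit$deviance, deviance_after = refit$deviance,
      stringsAsFactors = FALSE
    ))
  }
  if (!length(current)) {
    warning("stepwise elimination reached the intercept-only model",
            call. = FALSE)
  }
  structure(list(fit = fit, trace = trace, alpha = alpha,
                 criterion = criterion, f_max = f_max,
                 full_terms = terms), class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Backwards stepwise quasipoisson GLM (", x$criterion,
      ", alpha = ", x$alpha, ")\n", sep = "")
  if (is.null(x$trace)) {
    cat("no terms eliminated\n")
  } else {
    print(x$trace)
  }
  print(x$fit)
  invisible(x)
}

#' Per-term F table for a fitted count GLM
#'
#' Analysis-of-deviance table in the publication style: one row per term with
#' its coefficient (for single-df terms), dispersion-scaled F-statistic,
#' degrees of freedom and p-value.  `type = "sequential"` adds terms in the
#' model's stated order and tests each addition (type-I);
#' `type = "deletion"` tests each term's removal from the full model
#' (type-II-like).  Both scale by the full model's Pearson dispersion.
#'
#' @param fit a `count_glm_fit`.
#' @param type `"sequential"` (default) or `"deletion"`.
#' @return a `data.frame` with columns `term`, `estimate`, `std_error`,
#'   `f_value`, `df_num`, `df_den`, `p_value`.
#' @export
term_f_table <- function(fit, type = c("sequential", "deletion")) {
  type <- match.arg(type)
  terms <- fit$terms
  if (!length(terms)) {
    return(data.frame(term = character(0), estimate = numeric(0),
                      std_error = numeric(0), f_value = numeric(0),
                      df_num = integer(0), df_den = integer(0),
                      p_value = numeric(0)))
  }
  if (type == "sequential") {
    fits <- lapply(0:length(terms), function(k) {
      fit_quasipoisson(fit$data, terms[seq_len(k)], response = fit$response)
    })
    rows <- lapply(seq_along(terms), function(k) {
      ddf <- fits[[k]]$df_residual - fits[[k + 1]]$df_residual
      f <- ((fits[[k]]$deviance - fits[[k + 1]]$deviance) / ddf) /
        fit$dispersion
      data.frame(term = terms[k], f_value = max(f, 0),
                 df_num = as.integer(ddf), df_den = fit$df_residual,
                 p_value = pf(max(f, 0), ddf, fit$df_residual,
                              lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  } else {
    tests <- drop_term_tests(fit)
    tab <- data.frame(term = tests$term_tested, f_value = tests$f_value,
                      df_num = tests$df_num, df_den = tests$df_den,
                      p_value = tests$p_value, stringsAsFactors = FALSE)
  }
  # attach estimates for terms that map to a single coefficient
  tab$estimate <- NA_real_
  tab$std_error <- NA_real_
  for (i in seq_len(nrow(tab))) {
    if (tab$term[i] %in% names(fit$coefficients)) {
      tab$estimate[i] <- fit$coefficients[[tab$term[i]]]
      tab$std_error[i] <- fit$std_errors[[tab$term[i]]]
    }
  }
  tab[, c("term", "estimate", "std_error", "f_value", "df_num", "df_den",
          "p_value")]
}
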