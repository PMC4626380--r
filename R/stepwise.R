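#' Stepwise linear regression with p-value entry and removal
#'
#' Forward-entry / backward-removal variable selection for a linear model:
#' at each step the candidate with the smallest Wald p-value is entered if
#' that p-value is below `p_enter`, then any included predictor whose
#' p-value exceeds `p_remove` is removed (worst first). Because
#' `p_remove > p_enter` the loop terminates. For single-predictor steps in
#' a linear model the Wald and partial-F p-values coincide. The reported
#' partial correlation of each retained predictor is the signed square root
#' of its partial R^2, `sign(beta) * sqrt(t^2 / (t^2 + df))`.
#'
#' @param data data.frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of candidate predictor columns.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10), must exceed `p_enter`.
#' @return An object of class `stepwise_model`: list with `terms` (a
#'   data.frame of coefficient, standard error, p-value and partial R per
#'   retained predictor), `adj_r2`, `selected`, `fit` (the final `lm`),
#'   and the thresholds.
#' @export
stepwise_regression <- function(data, response, predictors,
                                p_enter = 0.05, p_remove = 0.10) {
  if (p_remove <= p_enter)
    validation_error("p_remove must exceed p_enter for termination")
  if (!response %in% names(data))
    validation_error("response column not found")
  if (!all(predictors %in% names(data)))
    validation_error("predictor column(s) not found")
  n <- nrow(data)
  if (n <= length(predictors) + 2L)
    validation_error("need n > number of candidate predictors + 2")
  X <- as.matrix(data[predictors])
  if (!is.numeric(X)) validation_error("predictors must be numeric")
  Xs <- scale(X)
  Xs[is.nan(Xs)] <- 0  # constant columns
  if (kappa(cbind(1, Xs), exact = TRUE) > 1e10)
    validation_error("collinear design (condition number > 1e10)")

  wald_p <- function(fit, term) {
    sm <- summary(fit)$coefficients
    sm[term, "Pr(>|t|)"]
  }
  model_for <- function(vars) {
    fml <- stats::reformulate(if (length(vars)) vars else "1", response)
    stats::lm(fml, data = data)
  }

  included <- character(0)
  repeat {
    changed <- FALSE
    candidates <- setdiff(predictors, included)
    if (length(candidates)) {
      pv <- vapply(candidates, function(v) {
        wald_p(model_for(c(included, v)), v)
      }, numeric(1))
      best <- which.min(pv)
      if (pv[best] < p_enter) {
        included <- c(included, candidates[best])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(included)) break
      fit <- stats::lm(stats::reformulate(included, response), data = data)
      pv <- vapply(included, function(v) wald_p(fit, v), numeric(1))
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  fit <- model_for(included)
  sm <- summary(fit)
  terms <- data.frame(
    variable = character(0), coefficient = numeric(0),
    std_error = numeric(0), p_value = numeric(0), r_partial = numeric(0),
    stringsAsFactors = FALSE
  )
  if (length(included)) {
    co <- sm$coefficients[included, , drop = FALSE]
    df_res <- fit$df.residual
    tval <- co[, "t value"]
    terms <- data.frame(
      variable = included,
      coefficient = co[, "Estimate"],
      std_error = co[, "Std. Error"],
      p_value = co[, "Pr(>|t|)"],
      r_partial = sign(co[, "Estimate"]) * sqrt(tval^2 / (tval^2 + df_res)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  structure(
    list(terms = terms, adj_r2 = sm$adj.r.squared, selected = included,
         fit = fit, p_enter = p_enter, p_remove = p_remove,
         response = response, candidates = predictors),
    class = "stepwise_model"
  )
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("<stepwise_model> %s ~ {%s}, adj R^2 = %.4f (enter p<%.2g, remove p>%.2g)\n",
              x$response,
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(empty)",
              x$adj_r2, x$p_enter, x$p_remove))
  if (nrow(x$terms)) print(format(x$terms, digits = 4), row.names = FALSE)
  invisible(x)
}
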