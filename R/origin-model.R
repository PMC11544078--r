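#' Fit the cut-off based natal-origin classifier
#'
#' Fits the logistic model `P(continental origin) = plogis(b0 + b1 * ratio)`
#' on reference 87Sr/86Sr data by maximum likelihood (iteratively reweighted
#' least squares via [stats::glm()]), builds the ROC curve on the ratio
#' scale (equivalent to the probability scale by monotonicity of the
#' logistic), selects the closest-topleft cut-off, and computes the AUC with
#' a confidence interval and the confusion metrics at the cut-off.
#' Reference insects and their host plants are pooled in the fit.
#'
#' Complete separation of the two classes does not raise an error: the model
#' is returned with `separation = TRUE` (coefficients at the IRLS iteration
#' cap), and the ROC/cut-off machinery, which only uses score order, remains
#' fully valid.
#'
#' @param data data frame of reference records with a ratio column and a 0/1
#'   origin label column (1 = continental/Chinese origin, 0 =
#'   immigration-area origin).
#' @param ratio_col,label_col column names.
#' @param ci_method AUC confidence-interval method, `"delong"` or
#'   `"bootstrap"`.
#' @param conf confidence level for the AUC interval.
#' @param seed seed for the bootstrap interval (ignored for DeLong).
#' @return An object of class `"origin_model"`: a list with `coefficients`
#'   (`intercept`, `slope`), `glm_fit`, `converged`, `n_iterations`,
#'   `separation`, `roc` ([roc_curve()] result), `auc`, `auc_ci`, `cutoff`
#'   (ratio scale), `confusion` ([confusion_metrics()]), and the training
#'   `data`.
#' @examples
#' set.seed(1)
#' refs <- gen_reference_set(seed = 1)
#' m <- fit_origin_model(refs)
#' m$cutoff
#' @export
fit_origin_model <- function(data, ratio_col = "ratio",
                             label_col = "origin_label",
                             ci_method = c("delong", "bootstrap"),
                             conf = 0.95, seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (!all(c(ratio_col, label_col) %in% names(data)))
    stop("`data` must contain columns `", ratio_col, "` and `", label_col, "`")
  ratio <- data[[ratio_col]]
  label <- check_labels(data[[label_col]])
  if (any(ratio <= 0)) stop("ratios must be positive")

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(label ~ ratio, family = binomial(),
        control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) separation <- TRUE

  roc <- roc_curve(ratio, label)
  cutoff <- cutoff_closest_topleft(roc)
  ci <- auc_ci(ratio, label, method = ci_method, conf = conf, seed = seed)
  conf_m <- confusion_metrics(ratio, label, as.numeric(cutoff))

  structure(list(coefficients = c(intercept = unname(coef(fit)[1]),
                                  slope = unname(coef(fit)[2])),
                 glm_fit = fit,
                 converged = fit$converged,
                 n_iterations = fit$iter,
                 separation = separation,
                 roc = roc,
                 auc = roc$auc,
                 auc_ci = ci,
                 conf = conf,
                 cutoff = as.numeric(cutoff),
                 cutoff_point = c(sensitivity = attr(cutoff, "sensitivity"),
                                  specificity = attr(cutoff, "specificity")),
                 confusion = conf_m,
                 ratio_col = ratio_col, label_col = label_col,
                 data = data),
            class = "origin_model")
}

#' @export
print.origin_model <- function(x, ...) {
  cat("Natal-origin classifier (logistic + ROC cut-off)\n")
  cat(sprintf("  n = %d (%d class 0, %d class 1)%s\n",
              nrow(x$data), x$roc$n0, x$roc$n1,
              if (x$separation) "  [complete separation]" else ""))
  cat(sprintf("  coefficients: intercept %.3f, slope %.3f per unit ratio\n",
              x$coefficients[["intercept"]], x$coefficients[["slope"]]))
  cat(sprintf("  AUC = %.3f (%g%% CI %.3f-%.3f, %s)\n",
              x$auc, 100 * x$conf, x$auc_ci$lower, x$auc_ci$upper,
              x$auc_ci$method))
  cat(sprintf("  cut-off (ratio) = %.5f\n", x$cutoff))
  invisible(x)
}

#' @export
summary.origin_model <- function(object, ...) {
  structure(list(model = object,
                 glm_summary = summary(object$glm_fit)),
            class = "summary.origin_model")
}

#' @export
print.summary.origin_model <- function(x, ...) {
  print(x$model)
  cm <- x$model$confusion
  cat(sprintf("  at cut-off: sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              cm$sensitivity, cm$specificity, cm$ppv, cm$npv))
  cat("\nLogistic fit:\n")
  print(x$glm_summary$coefficients)
  invisible(x)
}

#' @export
coef.origin_model <- function(object, ...) object$coefficients

#' Predict method for origin models
#'
#' @param object an [fit_origin_model()] result.
#' @param newdata data frame with the model's ratio column, or a numeric
#'   vector of ratios; defaults to the training data.
#' @param type `"response"` (probability of continental origin), `"link"`,
#'   or `"class"` (cut-off call via [classify_by_cutoff()]).
#' @param ... unused.
#' @return Numeric vector, or for `type = "class"` a factor of calls.
#' @export
predict.origin_model <- function(object, newdata = NULL,
                                 type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  ratio <- if (is.null(newdata)) object$data[[object$ratio_col]]
           else if (is.numeric(newdata)) newdata
           else newdata[[object$ratio_col]]
  if (type == "class")
    return(classify_by_cutoff(ratio, object$cutoff)$call)
  eta <- object$coefficients[["intercept"]] +
    object$coefficients[["slope"]] * ratio
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' @export
residuals.origin_model <- function(object, ...) residuals(object$glm_fit, ...)

#' Simulate reference labels from the fitted logistic model
#'
#' Draws Bernoulli labels at the training ratios from the fitted
#' probabilities; one column per simulation.
#'
#' @param object an `origin_model`.
#' @param nsim number of simulated label sets.
#' @param seed integer seed.
#' @param ... unused.
#' @export
simulate.origin_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, type = "response")
  as.data.frame(replicate(nsim, rbinom(length(p), 1, p)))
}

#' Plot method for origin models
#'
#' Two panels: the fitted logistic curve over the reference ratios with the
#' cut-off marked, and the ROC curve.
#'
#' @param x an `origin_model`.
#' @param ... passed to the base plot calls.
#' @export
plot.origin_model <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  ratio <- x$data[[x$ratio_col]]
  label <- x$data[[x$label_col]]
  rr <- seq(min(ratio), max(ratio), length.out = 200)
  plot(ratio, label, pch = 16, col = ifelse(label == 1, "firebrick", "navy"),
       xlab = "87Sr/86Sr", ylab = "P(continental origin)",
       main = "Logistic origin model", ...)
  lines(rr, predict(x, rr), lwd = 2)
  abline(v = x$cutoff, lty = 2)
  plot(x$roc)
  abline(v = 1 - x$cutoff_point[["specificity"]], lty = 2, col = "grey50")
  invisible(x)
}

#' Write a JSON summary of an origin model
#'
#' Coefficients, AUC with its interval, cut-off and confusion metrics, in a
#' machine-readable report.
#'
#' @param model an `origin_model`.
#' @param path output JSON path.
#' @export
write_model_summary <- function(model, path) {
  stopifnot(inherits(model, "origin_model"))
  obj <- list(coefficients = as.list(model$coefficients),
              converged = model$converged,
              separation = model$separation,
              auc = model$auc,
              auc_ci = list(lower = model$auc_ci$lower,
                            upper = model$auc_ci$upper,
                            method = model$auc_ci$method),
              cutoff = model$cutoff,
              confusion = model$confusion[c("sensitivity", "specificity",
                                            "ppv", "npv", "tp", "fn", "tn",
                                            "fp")],
              n = c(n0 = model$roc$n0, n1 = model$roc$n1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
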