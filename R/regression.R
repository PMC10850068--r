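## Composition -> membrane property regression (area per lipid, thickness).

.feature_classes <- c("POPC", "POPE", "POPG", "POPS", "CHOL", "SM", "CL", "PI")

## universal molecule -> feature class; sphingomyelins, cardiolipins and PI
## lipids are grouped by headgroup regardless of acyl chains.
.class_map <- c(POPC = "POPC", POPE = "POPE", POPG = "POPG", POPS = "POPS",
                CHOL = "CHOL", PSM = "SM", SSM = "SM",
                TOCL = "CL", TMCL = "CL", POPI = "PI")

.chains_per_class <- c(POPC = 2, POPE = 2, POPG = 2, POPS = 2, CHOL = 2,
                       SM = 2, CL = 4, PI = 2)

#' Featurize a membrane composition
#'
#' Maps a composition to the normalized molar-fraction vector over the eight
#' feature classes: POPC, POPE, POPG, POPS, CHOL explicitly, plus the
#' headgroup groups SM (sphingomyelins), CL (cardiolipins) and PI. Water and
#' ions are ignored; salt concentration and temperature are not features.
#'
#' @param composition a \linkS4class{SimulationEntry}, or a named numeric
#'   vector of molecule counts or fractions (universal names or feature-class
#'   names).
#' @return Named numeric vector over the eight classes, summing to 1.
#' @export
featurizeComposition <- function(composition) {
  if (is(composition, "SimulationEntry")) {
    comp <- composition@composition
    composition <- stats::setNames(comp$count, comp$molecule)
  }
  composition <- composition[!(names(composition) %in%
                                 c(.water_names, .ion_names))]
  composition <- composition[composition > 0]
  cls <- ifelse(names(composition) %in% .feature_classes,
                names(composition), .class_map[names(composition)])
  if (anyNA(cls))
    stop("featurization error: no feature class for molecule(s): ",
         paste(names(composition)[is.na(cls)], collapse = ", "))
  x <- stats::setNames(numeric(length(.feature_classes)), .feature_classes)
  for (i in seq_along(cls)) x[cls[i]] <- x[cls[i]] + composition[i]
  x / sum(x)
}

#' Train a composition -> property regression model
#'
#' Splits the dataset 80/20 by seed, selects hyperparameters on the training
#' split by 5-fold cross validation, fits the final model on the training
#' split and reports test-split metrics. Two families are provided: ordinary
#' linear regression (fitted without intercept on the fraction vector, whose
#' components sum to one, so all class coefficients are identifiable) and
#' ridge regression (glmnet, alpha = 0, lambda grid searched by seeded
#' cross-validation).
#'
#' @param dataset data.frame with the eight feature-class columns and a
#'   target column.
#' @param target name of the target column (e.g. \code{"apl"} in Angstrom^2
#'   or \code{"thickness"} in nm).
#' @param family \code{"linear"} or \code{"ridge"}.
#' @param seed integer seed controlling the split and fold assignment.
#' @param split training fraction (default 0.8).
#' @param folds cross-validation folds (default 5).
#' @return Object of class \code{PropertyModel}: list with the fitted model,
#'   \code{coefficients}, \code{family}, \code{target}, \code{metrics}
#'   (test RMSE and R^2) and split metadata.
#' @export
trainPropertyModel <- function(dataset, target, family = c("linear", "ridge"),
                               seed = 1, split = 0.8, folds = 5) {
  family <- match.arg(family)
  if (nrow(dataset) < 10) stop("dataset must have at least 10 rows")
  miss <- setdiff(c(.feature_classes, target), names(dataset))
  if (length(miss)) stop("dataset missing column(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(dataset[, .feature_classes])
  y <- dataset[[target]]
  set.seed(seed)
  n <- nrow(X)
  idx_train <- sort(sample.int(n, size = round(split * n)))
  idx_test <- setdiff(seq_len(n), idx_train)
  Xtr <- X[idx_train, , drop = FALSE]; ytr <- y[idx_train]
  fit <- switch(family,
    linear = stats::lm(ytr ~ Xtr + 0),
    ridge = {
      foldid <- sample(rep_len(seq_len(folds), length(ytr)))
      ## explicit penalty grid searched by cross-validation
      cv <- glmnet::cv.glmnet(Xtr, ytr, alpha = 0, foldid = foldid,
                              lambda = 10^seq(2, -6, length.out = 80),
                              standardize = FALSE)
      cv
    })
  coefs <- switch(family,
    ## classes absent from the training data get an (unidentifiable) NA
    ## coefficient from lm; they contribute nothing to predictions
    linear = {
      b <- stats::setNames(stats::coef(fit), .feature_classes)
      b[is.na(b)] <- 0
      b
    },
    ridge = {
      b <- as.numeric(stats::coef(fit, s = "lambda.min"))
      stats::setNames(b, c("(Intercept)", .feature_classes))
    })
  predict_fun <- function(newX) switch(family,
    linear = drop(newX %*% coefs),
    ridge = drop(stats::predict(fit, newx = newX, s = "lambda.min")))
  metrics <- if (length(idx_test)) {
    pred <- predict_fun(X[idx_test, , drop = FALSE])
    res <- y[idx_test] - pred
    list(rmse = sqrt(mean(res^2)),
         r_squared = if (stats::var(y[idx_test]) > 0)
           1 - sum(res^2) / sum((y[idx_test] - mean(y[idx_test]))^2)
         else NA_real_,
         n_test = length(idx_test))
  } else list(rmse = NA_real_, r_squared = NA_real_, n_test = 0L)
  structure(list(fit = fit, family = family, target = target,
                 coefficients = coefs, metrics = metrics, seed = seed,
                 folds = folds, idx_train = idx_train, idx_test = idx_test),
            class = "PropertyModel")
}

#' @export
print.PropertyModel <- function(x, ...) {
  cat("PropertyModel [", x$family, "] for target:", x$target, "\n")
  print(round(x$coefficients, 3))
  cat(sprintf("test RMSE = %.3g (n = %d)\n", x$metrics$rmse, x$metrics$n_test))
  invisible(x)
}

#' @export
predict.PropertyModel <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  newX <- as.matrix(newdata[, .feature_classes, drop = FALSE])
  switch(object$family,
    linear = drop(newX %*% object$coefficients),
    ridge = drop(stats::predict(object$fit, newx = newX, s = "lambda.min")))
}

#' Predict membrane properties for a composition
#'
#' Point predictions for any valid composition. For cardiolipin-containing
#' systems an auxiliary per-acyl-chain area is reported for the area target:
#' cardiolipin carries four acyl chains where other lipids carry two, so the
#' per-chain value rescales the per-molecule area by 1/(1 + x_CL).
#'
#' @param models named list of \code{PropertyModel}s (e.g. \code{apl},
#'   \code{thickness}).
#' @param composition named counts/fractions or a
#'   \linkS4class{SimulationEntry} (see \code{\link{featurizeComposition}}).
#' @return Named list of predictions; with an \code{apl} model and
#'   cardiolipin present, also \code{apl_per_chain}.
#' @export
predictProperties <- function(models, composition) {
  x <- featurizeComposition(composition)
  out <- lapply(models, function(m) unname(predict(m, x)))
  if ("apl" %in% names(models) && x["CL"] > 0) {
    chain_factor <- 2 / sum(x * .chains_per_class[.feature_classes])
    out$apl_per_chain <- out$apl * chain_factor
  }
  out
}

#' Evaluate a model against a reference table
#'
#' Scores model predictions against an external reference of compositions
#' and measured values: per-row residuals, RMSE and Pearson correlation, and
#' a scatter table for plotting.
#'
#' @param model a \code{PropertyModel}.
#' @param reference data.frame with the eight feature-class columns, a
#'   \code{value} column and optionally an \code{error} column.
#' @return list with \code{residuals}, \code{rmse}, \code{correlation},
#'   \code{scatter} (data.frame predicted/observed).
#' @export
evaluateAgainstReference <- function(model, reference) {
  X <- as.matrix(reference[, .feature_classes, drop = FALSE])
  pred <- predict(model, X)
  obs <- reference$value
  res <- obs - pred
  list(residuals = res, rmse = sqrt(mean(res^2)),
       correlation = if (stats::sd(pred) > 0 && stats::sd(obs) > 0)
         stats::cor(pred, obs) else NA_real_,
       scatter = data.frame(predicted = pred, observed = obs,
                            error = if ("error" %in% names(reference))
                              reference$error else NA_real_))
}
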