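# Linear blockade model: ordinary least squares from per-residue features
# to observed (z-scored) consensus blockade signals, with two-fold
# cross-validation over peptides.

#' Build a residue dataset
#'
#' Pairs the encoded features of a peptide with observed per-residue
#' consensus signals (one row per residue), tagged with a fold label
#' (peptide of origin) for cross-validation.
#'
#' @param peptide Peptide string.
#' @param observed Numeric vector of observed signals, one per residue
#'   (typically from [extract_residue_datapoints()]).
#' @param method Encoding name.
#' @param table Volume table.
#' @param fold Fold label (default the peptide string).
#' @return Object of class `residue_dataset`: list with `features`
#'   (matrix), `observed`, `fold`, `method`.
#' @export
residue_dataset <- function(peptide, observed, method = "1AAV",
                            table = load_volume_table(), fold = peptide) {
  X <- encode_peptide(peptide, method, table)
  if (length(observed) != nrow(X))
    stop("observed must have one value per residue")
  structure(list(features = X, observed = as.numeric(observed),
                 fold = rep(fold, nrow(X)), method = attr(X, "method")),
            class = "residue_dataset")
}

#' Combine residue datasets
#' @param ... `residue_dataset` objects with the same encoding.
#' @return A single `residue_dataset`.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  methods <- unique(vapply(ds, function(d) d$method, character(1L)))
  if (length(methods) != 1L) stop("datasets use different encodings")
  structure(list(features = do.call(rbind, lapply(ds, `[[`, "features")),
                 observed = unlist(lapply(ds, `[[`, "observed")),
                 fold = unlist(lapply(ds, `[[`, "fold")),
                 method = methods), class = "residue_dataset")
}

#' Fit a linear blockade model
#'
#' Ordinary least squares with intercept, mapping residue features to
#' observed blockade signals.
#'
#' @param dataset A `residue_dataset`.
#' @return Object of class `blockade_model` with `coefficients` (named,
#'   per feature column), `intercept`, `method`, `training_meta`
#'   (fold labels, n) and the fitted `lm` in `fit`.
#' @export
#' @examples
#' tab <- load_volume_table()
#' v <- znormalize(peptide_volumes(peptide_ab42(), tab))
#' ds <- residue_dataset(peptide_ab42(), v, "1AAV", tab)
#' coef(fit_blockade_model(ds))
fit_blockade_model <- function(dataset) {
  stopifnot(inherits(dataset, "residue_dataset"))
  X <- dataset$features
  y <- dataset$observed
  if (nrow(X) <= ncol(X) + 1L)
    stop("too few rows to fit: need more rows than features + intercept")
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  structure(list(method = dataset$method,
                 coefficients = cf[-1L],
                 intercept = unname(cf[1L]),
                 training_meta = list(folds = unique(dataset$fold),
                                      n = nrow(X)),
                 fit = fit),
            class = "blockade_model")
}

#' Construct a blockade model from explicit weights
#'
#' Used for synthetic generating laws (e.g. blockade proportional to
#' residue volume) and for loading serialised models.
#'
#' @param method Encoding name.
#' @param coefficients Numeric weights, one per feature column.
#' @param intercept Intercept (default 0).
#' @return Object of class `blockade_model`.
#' @export
#' @examples
#' volume_model()
blockade_model <- function(method, coefficients, intercept = 0) {
  method <- match_encoding(method)
  p <- encoding_ncol(method)
  if (length(coefficients) != p)
    stop(sprintf("method %s needs %d coefficients, got %d", method, p,
                 length(coefficients)))
  structure(list(method = method,
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 training_meta = list(folds = character(0L), n = 0L),
                 fit = NULL),
            class = "blockade_model")
}

#' Volume-proportional generating model
#'
#' A `1AAV` blockade model with unit slope and zero intercept: the
#' predicted blockade equals the residue volume. The default generating
#' law of the simulator.
#' @return A `blockade_model`.
#' @export
volume_model <- function() blockade_model("1AAV", 1, 0)

#' @export
print.blockade_model <- function(x, ...) {
  cat(sprintf("blockade_model (%s): intercept %.4g, %d coefficient(s)\n",
              x$method, x$intercept, length(x$coefficients)))
  print(x$coefficients)
  invisible(x)
}

#' @export
#' @method coef blockade_model
coef.blockade_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
#' @method summary blockade_model
summary.blockade_model <- function(object, ...) {
  cat(sprintf("Linear blockade model, encoding %s\n", object$method))
  if (!is.null(object$fit)) {
    print(summary(object$fit))
  } else {
    print(coef(object))
  }
  invisible(object)
}

#' Predict per-residue blockade signals
#'
#' Applies a fitted (or constructed) blockade model row-wise to the encoded
#' features of a peptide: `t_hat_i = intercept + coefficients . features_i`.
#'
#' @param object A `blockade_model`.
#' @param peptide Peptide string.
#' @param table Volume table.
#' @param ... Unused.
#' @return Numeric vector of predicted signals, one per residue.
#' @export
predict.blockade_model <- function(object, peptide,
                                   table = load_volume_table(), ...) {
  X <- encode_peptide(peptide, object$method, table)
  as.numeric(object$intercept + X %*% object$coefficients)
}

model_mse <- function(model, dataset) {
  pred <- as.numeric(model$intercept +
                       dataset$features %*% model$coefficients)
  (dataset$observed - pred)^2
}

#' Two-fold cross-validation of an encoding
#'
#' Fits the model on fold A and evaluates on A (training) and B
#' (validation), swaps the folds, and reports the mean squared error pooled
#' over both folds' residuals, separately for training and validation.
#'
#' @param datasetA,datasetB `residue_dataset`s for the two folds (same
#'   encoding).
#' @param method Optional encoding override; when given, both folds are
#'   re-encoded (their peptides must be recoverable from the fold labels).
#' @return Named list `training_mse`, `validation_mse`, plus the two
#'   fitted `blockade_model`s (`model_A`, `model_B`).
#' @export
two_fold_cv <- function(datasetA, datasetB, method = NULL) {
  stopifnot(inherits(datasetA, "residue_dataset"),
            inherits(datasetB, "residue_dataset"))
  if (!is.null(method)) {
    method <- match_encoding(method)
    reenc <- function(d) residue_dataset(unique(d$fold)[1L], d$observed,
                                         method, fold = unique(d$fold)[1L])
    datasetA <- reenc(datasetA); datasetB <- reenc(datasetB)
  }
  if (datasetA$method != datasetB$method) stop("folds use different encodings")
  mA <- fit_blockade_model(datasetA)
  mB <- fit_blockade_model(datasetB)
  train <- c(model_mse(mA, datasetA), model_mse(mB, datasetB))
  valid <- c(model_mse(mA, datasetB), model_mse(mB, datasetA))
  list(training_mse = mean(train), validation_mse = mean(valid),
       model_A = mA, model_B = mB)
}

#' Serialise / load a blockade model as JSON
#' @param model A `blockade_model`.
#' @param path Output path.
#' @return `path` (write) or a `blockade_model` (read).
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(method = model$method,
                            column_names = names(model$coefficients),
                            coefficients = model$coefficients,
                            intercept = model$intercept,
                            training_meta = model$training_meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- blockade_model(j$method, j$coefficients, j$intercept)
  names(m$coefficients) <- j$column_names
  m
}
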