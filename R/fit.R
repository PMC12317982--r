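# The affinity predictor: feature selection + neural-network regression,
# wrapped in a classed model object with the usual methods.

#' Fit an EMC binding-affinity predictor to a ConMem-style dataset
#'
#' Runs the full pipeline: correlation-based feature selection on the
#' training split (\code{|r| > r_min}, \code{P < p_max}, both strict),
#' featurization under the chosen scheme (\code{"v1"}: scaled index value at
#' each mutated position; \code{"v2"}: mean scaled value over subsequences of
#' nine), and training of the single-hidden-layer ReLU network. The held-out
#' test split is never touched during selection or training.
#'
#' @param dataset A \code{conmem_dataset} (see \code{\link{simulate_conmem}},
#'   \code{\link{read_conmem}}) with train/test split labels.
#' @param indices Candidate \code{scaled_index_list}
#'   (default \code{\link{aaindex_core}()}).
#' @param version Featurization scheme; defaults to the dataset's
#'   \code{version_hint} if present, else \code{"v1"}.
#' @param r_min,p_max Selection thresholds (defaults 0.7 and 0.01).
#' @param control Regressor hyperparameters, \code{\link{mlp_control}()}.
#' @param seed Integer seed for weight initialization (recorded in the model).
#' @param select_on \code{"train"} (leakage-free default) or \code{"all"}.
#' @param transform Response transform for training: \code{"identity"}
#'   (default; affinities are already on the reference-normalized linear
#'   scale) or \code{"log2"}; predictions are returned on the original scale.
#' @return An object of class \code{"emc_fit"}.
#' @examples
#' ds <- simulate_conmem(seed = 7)
#' fit <- emc_fit(ds, seed = 7)
#' evaluate(fit)
#' @export
emc_fit <- function(dataset, indices = aaindex_core(),
                    version = NULL, r_min = 0.7, p_max = 0.01,
                    control = mlp_control(), seed = 1L,
                    select_on = c("train", "all"),
                    transform = c("identity", "log2")) {
  select_on <- match.arg(select_on)
  transform <- match.arg(transform)
  seed <- as.integer(seed)
  if (is.null(version))
    version <- attr(dataset, "version_hint") %||% "v1"
  d <- as.data.frame(dataset)
  train <- d[d$split == "train", , drop = FALSE]
  test <- d[d$split == "test", , drop = FALSE]
  if (nrow(train) == 0L) stop("training split is empty")

  spec <- select_features(dataset, indices, r_min = r_min, p_max = p_max,
                          version = version, select_on = select_on)
  used <- indices[unique(spec$accessions)]
  Xtr <- featurize(train$sequence, spec, used)
  ytr <- transform_affinity(train$affinity, transform)
  net <- mlp_fit(Xtr, ytr, control = control, seed = seed)

  fit <- structure(list(
    feature_spec = spec, indices = used, net = net, control = control,
    seed = seed, version = version, transform = transform,
    thresholds = list(r_min = r_min, p_max = p_max, select_on = select_on),
    train = train, test = test,
    meta = list(n_train = nrow(train), n_test = nrow(test),
                tmd_length = attr(dataset, "tmd_length"),
                fingerprint = dataset_fingerprint(d))),
    class = "emc_fit")
  fit$fitted_train <- predict(fit, train$sequence)
  fit
}

transform_affinity <- function(a, transform) {
  if (transform == "log2") log2(pmax(a, 1e-6)) else a
}
untransform_affinity <- function(y, transform) {
  if (transform == "log2") 2^y else y
}

dataset_fingerprint <- function(d) {
  sprintf("n%d-a%.10g", nrow(d), sum(d$affinity))
}

#' Predict binding affinities for new TMD sequences
#'
#' @param object An \code{emc_fit}.
#' @param newdata Character vector of sequences, or a \code{conmem_dataset};
#'   defaults to the model's training sequences.
#' @param ... Unused.
#' @return Numeric vector of predicted affinities (reference-normalized
#'   units), in input order. Sequences that cannot be featurized yield
#'   \code{NA} with a warning; the rest of the batch is still scored.
#' @export
predict.emc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$train$sequence
  if (inherits(newdata, "conmem_dataset") || is.data.frame(newdata))
    newdata <- newdata$sequence
  out <- rep(NA_real_, length(newdata))
  for (i in seq_along(newdata)) {
    X <- tryCatch(featurize(newdata[i], object$feature_spec, object$indices),
                  error = function(e) e)
    if (inherits(X, "error")) {
      warning("sequence ", i, " not featurizable: ", conditionMessage(X))
    } else {
      out[i] <- untransform_affinity(mlp_forward(object$net, X),
                                     object$transform)
    }
  }
  out
}

#' Held-out evaluation of a fitted predictor
#'
#' Pearson correlation (with two-sided t-distribution P-value) between
#' predicted and measured affinities on a held-out split.
#'
#' @param object A fitted model.
#' @param ... Method arguments.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @param dataset Optional \code{conmem_dataset}; by default the model's own
#'   recorded test split is used.
#' @param split Which split of \code{dataset} to evaluate on.
#' @return List with \code{pearson_r}, \code{p_value}, \code{n}.
#' @export
evaluate.emc_fit <- function(object, dataset = NULL, split = "test", ...) {
  d <- if (is.null(dataset)) object$test else {
    dd <- as.data.frame(dataset)
    dd[dd$split %in% split, , drop = FALSE]
  }
  if (nrow(d) < 3L)
    stop("evaluation split has fewer than 3 variants")
  pred <- predict(object, d$sequence)
  ok <- !is.na(pred)
  if (stats::sd(pred[ok]) == 0 || stats::sd(d$affinity[ok]) == 0)
    stop("constant predictions or affinities; correlation undefined")
  ct <- stats::cor.test(pred[ok], d$affinity[ok], method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' @export
print.emc_fit <- function(x, ...) {
  cat("EMC TMD binding-affinity predictor (", x$version, " featurization)\n",
      sep = "")
  cat(sprintf("  %d features over %s %s\n", length(x$feature_spec$slots),
              if (x$version == "v1") "positions" else "subsequences",
              paste(sort(unique(x$feature_spec$slots)), collapse = ", ")))
  status <- if (isTRUE(x$net$converged)) "converged after"
  else if (x$control$tol <= 0) "trained for the full"
  else "not converged within"
  cat(sprintf("  trained on %d variants (%d held out), seed %d, %s %d iterations\n",
              x$meta$n_train, x$meta$n_test, x$seed, status, x$net$n_iter))
  invisible(x)
}

#' @export
summary.emc_fit <- function(object, ...) {
  ev <- tryCatch(evaluate(object), error = function(e) NULL)
  sel <- attr(object$feature_spec, "selection")
  out <- list(fit = object, evaluation = ev,
              n_candidates = if (!is.null(sel)) nrow(sel) else NA_integer_,
              train_r = stats::cor(object$fitted_train,
                                   object$train$affinity))
  class(out) <- "summary.emc_fit"
  out
}

#' @export
print.summary.emc_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  selection: %d of %s candidate (slot, index) pairs retained\n",
              length(x$fit$feature_spec$slots),
              x$n_candidates))
  cat(sprintf("  training-set Pearson r: %.4f\n", x$train_r))
  if (!is.null(x$evaluation))
    cat(sprintf("  held-out Pearson r: %.4f (P = %.3g, n = %d)\n",
                x$evaluation$pearson_r, x$evaluation$p_value,
                x$evaluation$n))
  invisible(x)
}

#' @export
coef.emc_fit <- function(object, ...) {
  list(W1 = object$net$W1, b1 = object$net$b1,
       W2 = object$net$W2, b2 = object$net$b2)
}

#' @export
residuals.emc_fit <- function(object, ...) {
  object$train$affinity - object$fitted_train
}

#' Predicted-versus-observed plot for a fitted predictor
#'
#' @param x An \code{emc_fit}.
#' @param which \code{"test"} (default) or \code{"train"}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.emc_fit <- function(x, which = c("test", "train"), ...) {
  which <- match.arg(which)
  d <- if (which == "test" && nrow(x$test) > 0L) x$test else x$train
  pred <- predict(x, d$sequence)
  graphics::plot(d$affinity, pred,
                 xlab = "measured relative affinity",
                 ylab = "predicted relative affinity",
                 main = sprintf("%s split (n = %d)", which, nrow(d)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate response affinities from a fitted predictor
#'
#' Draws new affinity vectors as model prediction plus Gaussian noise with
#' the SD of the training residuals (truncated at 0), one column per
#' simulation.
#'
#' @param object An \code{emc_fit}.
#' @param nsim Number of simulated replicates.
#' @param seed Optional seed.
#' @param newdata Sequences to simulate for (default: training sequences).
#' @param ... Unused.
#' @return A data.frame with \code{nsim} columns.
#' @export
simulate.emc_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                             ...) {
  local_seed(seed)
  mu <- predict(object, newdata)
  sd_res <- stats::sd(residuals(object))
  out <- as.data.frame(replicate(nsim, pmax(mu + stats::rnorm(length(mu),
                                                              0, sd_res), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize a fitted predictor to a JSON model file
#'
#' The file is self-contained: feature spec, hyperparameters, layer weights,
#' the scaled index values the spec uses, and training metadata. Numbers are
#' written at full precision so predictions round-trip bit-exactly.
#'
#' @param object An \code{emc_fit}.
#' @param file Output path.
#' @export
write_emc_model <- function(object, file) {
  # doubles serialized as %.17g strings: 17 significant digits guarantee an
  # exact double round trip, which plain JSON number emission does not
  num17 <- function(x) {
    out <- sprintf("%.17g", x)
    if (is.matrix(x)) dim(out) <- dim(x)
    if (!is.null(names(x))) names(out) <- names(x)
    out
  }
  idx <- lapply(object$indices, function(s)
    list(values = as.list(num17(s$values)), scale_min = s$scale_min,
         scale_max = s$scale_max))
  doc <- list(
    format = "emcbind-model", format_version = 1L,
    version = object$version, transform = object$transform,
    feature_spec = list(slots = object$feature_spec$slots,
                        accessions = object$feature_spec$accessions,
                        n_chunks = object$feature_spec$n_chunks),
    thresholds = object$thresholds,
    control = unclass(object$control),
    seed = object$seed,
    weights = list(W1 = num17(object$net$W1), b1 = num17(object$net$b1),
                   W2 = num17(object$net$W2), b2 = num17(object$net$b2)),
    indices = idx,
    meta = object$meta)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Load a predictor from a JSON model file
#'
#' @param file Path written by \code{\link{write_emc_model}}.
#' @return An \code{emc_fit} (without the original training data attached).
#' @export
read_emc_model <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(doc$format, "emcbind-model"))
    stop("not an emcbind model file: ", file)
  spec <- feature_spec(doc$feature_spec$slots, doc$feature_spec$accessions,
                       doc$version, n_chunks = doc$feature_spec$n_chunks)
  indices <- structure(lapply(names(doc$indices), function(acc) {
    e <- doc$indices[[acc]]
    v <- unlist(e$values)
    structure(list(accession = acc,
                   values = stats::setNames(as.numeric(v), names(v)),
                   scale_min = e$scale_min, scale_max = e$scale_max),
              class = "scaled_index")
  }), names = names(doc$indices), class = "scaled_index_list")
  W1c <- as.matrix(doc$weights$W1)
  net <- structure(list(
    W1 = matrix(as.numeric(W1c), nrow(W1c)),
    b1 = matrix(as.numeric(doc$weights$b1), nrow = 1L),
    W2 = matrix(as.numeric(doc$weights$W2), ncol = 1L),
    b2 = matrix(as.numeric(doc$weights$b2), 1L, 1L),
    control = do.call(mlp_control, as.list(doc$control)),
    seed = doc$seed, converged = NA, n_iter = NA_integer_),
    class = "mlp_net")
  structure(list(
    feature_spec = spec, indices = indices, net = net,
    control = net$control, seed = doc$seed, version = doc$version,
    transform = doc$transform %||% "identity",
    thresholds = doc$thresholds,
    train = data.frame(sequence = character(), affinity = numeric(),
                       split = character()),
    test = data.frame(sequence = character(), affinity = numeric(),
                      split = character()),
    meta = doc$meta),
    class = "emc_fit")
}
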