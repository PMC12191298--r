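# mff_fit(): the user-facing fitting function and its S3 methods.

#' Fit the multi-domain feature-fusion CNN to a beat dataset
#'
#' Computes the frequency-domain (GAF-of-spectrum) and time-frequency
#' (S-transform) images for every beat as required by the active branches,
#' builds the fused network and trains it end to end with SGD + momentum
#' under the cross-entropy loss.
#'
#' @param ds A [beat_dataset] of segmented, preprocessed heartbeats carrying
#'   class labels.
#' @param branches Non-empty subset of `c("beat", "gaf", "st")`: which
#'   feature domains to use (time, frequency, time-frequency).
#' @param width_multiplier Stage-width scale; 1 is the full-size network,
#'   fractions give desk-scale models.
#' @param image_size Side length of the GAF and ST images.
#' @param f_max S-transform frequency cap in Hz.
#' @param sampling_rate Beat sampling rate in Hz.
#' @param config A [train_config()].
#' @param images Optional precomputed [dataset_images()] result (list with
#'   `gaf`/`st` arrays) to avoid recomputation.
#' @param verbose Print per-epoch mean loss.
#' @return An object of class `mff_cnn` with the trained network, the class
#'   levels, the per-epoch loss trace and the configuration; see
#'   [predict.mff_cnn()].
#' @export
mff_fit <- function(ds, branches = c("beat", "gaf", "st"),
                    width_multiplier = 1, image_size = 224, f_max = 45,
                    sampling_rate = 1000, config = train_config(),
                    images = NULL, verbose = FALSE) {
  stopifnot(inherits(ds, "beat_dataset"), inherits(config, "train_config"))
  branches <- match.arg(branches, c("beat", "gaf", "st"), several.ok = TRUE)
  if (length(ds) == 0) stop("empty training dataset")
  classes <- sort(unique(ds$label))
  if (length(classes) < 2) warning("single-class training set")
  y <- match(ds$label, classes)

  needs_images <- any(c("gaf", "st") %in% branches)
  if (needs_images && is.null(images))
    images <- dataset_images(ds, image_size, f_max, sampling_rate)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  net <- build_mff(max(length(classes), 2L), branches,
                   width_multiplier = width_multiplier,
                   image_size = image_size)
  data <- .prep_tensors(ds, images, seq_len(length(ds)), branches)
  data$y <- y
  loss_trace <- .train_loop(net, data, config, verbose = verbose)

  structure(list(net = net, classes = classes, branches = branches,
                 width_multiplier = width_multiplier,
                 image_size = image_size, f_max = f_max,
                 sampling_rate = sampling_rate, config = config,
                 loss_trace = loss_trace, n_train = length(ds),
                 n_params = net$n_params),
            class = "mff_cnn")
}

#' Predict from a fitted MFF-CNN
#'
#' @param object An `mff_cnn` fit.
#' @param newdata A [beat_dataset].
#' @param type `"class"` for hard labels, `"prob"` for the softmax
#'   probability matrix (beats x classes, rows summing to 1).
#' @param images Optional precomputed [dataset_images()] for `newdata`.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Character vector of class labels or a probability matrix.
#' @export
predict.mff_cnn <- function(object, newdata, type = c("class", "prob"),
                            images = NULL, batch_size = 64, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "beat_dataset"))
  n <- length(newdata)
  if (n == 0) stop("empty partition")
  if (any(c("gaf", "st") %in% object$branches) && is.null(images))
    images <- dataset_images(newdata, object$image_size, object$f_max,
                             object$sampling_rate)
  k <- length(object$classes)
  probs <- matrix(0, n, max(k, 2))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    inputs <- .prep_tensors(newdata, images, idx, object$branches)
    inputs$y <- NULL
    probs[idx, ] <- t(object$net$predict_probs(inputs))
  }
  probs <- probs[, seq_len(k), drop = FALSE]
  probs <- probs / rowSums(probs)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' Evaluate a fitted MFF-CNN on a test partition
#'
#' Builds the confusion matrix from argmax predictions and computes the full
#' metric suite. For 2-class (detection) tasks the MI-like class is treated
#' as positive; multi-class (localization) metrics are one-vs-rest
#' macro-averages plus the overall accuracy AccT.
#'
#' @param object An `mff_cnn`.
#' @param ds A [beat_dataset] with true labels.
#' @param positive Positive class for 2-class tasks (default: the non-"HC"
#'   class if present, else the second level).
#' @param images Optional precomputed images for `ds`.
#' @return A [metrics_from_confusion()] report.
#' @export
mff_evaluate <- function(object, ds, positive = NULL, images = NULL) {
  pred <- predict(object, ds, type = "class", images = images)
  lev <- object$classes
  cm <- table(factor(ds$label, levels = lev), factor(pred, levels = lev))
  cm <- matrix(cm, nrow = length(lev), dimnames = list(lev, lev))
  if (is.null(positive) && length(lev) == 2)
    positive <- if ("HC" %in% lev) setdiff(lev, "HC")[1] else lev[2]
  metrics_from_confusion(cm, positive = positive)
}

#' @export
print.mff_cnn <- function(x, ...) {
  cat("Multi-domain feature-fusion CNN\n")
  cat(sprintf("  branches: %s  (width x%g, images %dx%d)\n",
              paste(x$branches, collapse = " + "), x$width_multiplier,
              x$image_size, x$image_size))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  parameters: %s; trained on %d beats for %d epochs (final loss %.4f)\n",
              format(x$n_params, big.mark = ","), x$n_train, x$config$epochs,
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.mff_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("  optimizer: SGD lr=%g momentum=%g batch=%d seed=%d\n",
              object$config$lr, object$config$momentum,
              object$config$batch_size, object$config$seed))
  cat(sprintf("  loss trace: start %.4f -> end %.4f\n",
              object$loss_trace[1], utils::tail(object$loss_trace, 1)))
  invisible(object)
}

#' Plot the training loss trace
#'
#' @param x An `mff_cnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mff_cnn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "b",
                 xlab = "epoch", ylab = "mean cross-entropy loss", ...)
  invisible(x)
}

#' Ablation over feature-domain combinations
#'
#' Fits and evaluates one model per requested branch combination under the
#' inter-patient split; single-branch and pair models drop the unused
#' branches and shrink the fusion head accordingly.
#'
#' @param ds A [beat_dataset].
#' @param combinations List of character vectors, each a non-empty subset of
#'   `c("beat", "gaf", "st")`. Default: all 7 non-empty subsets.
#' @param split Optional precomputed [make_split()] result (inter-patient is
#'   used when omitted).
#' @param seed Seed for the split.
#' @param ... Passed on to [mff_fit()] (e.g. `width_multiplier`,
#'   `image_size`, `config`).
#' @return List with `results` (one `metrics_report` per combination) and
#'   `summary` (data frame of AccT/macro metrics per combination).
#' @export
run_ablation <- function(ds, combinations = NULL, split = NULL, seed = 1L, ...) {
  all_b <- c("beat", "gaf", "st")
  if (is.null(combinations)) {
    combinations <- unlist(lapply(1:3, function(k)
      utils::combn(all_b, k, simplify = FALSE)), recursive = FALSE)
  }
  if (any(vapply(combinations, length, 0L) == 0)) stop("empty combination")
  split <- split %||% make_split(ds, "inter_patient", seed = seed)
  tr <- subset_beats(ds, split$train)
  te <- subset_beats(ds, split$test)
  dots <- list(...)
  image_size <- dots$image_size %||% 224
  f_max <- dots$f_max %||% 45
  sampling_rate <- dots$sampling_rate %||% 1000
  needs <- any(vapply(combinations, function(cb) any(c("gaf", "st") %in% cb), TRUE))
  img_tr <- if (needs) dataset_images(tr, image_size, f_max, sampling_rate)
  img_te <- if (needs) dataset_images(te, image_size, f_max, sampling_rate)
  results <- list()
  for (cb in combinations) {
    fit <- do.call(mff_fit, c(list(ds = tr, branches = cb, images = img_tr), dots))
    results[[paste(cb, collapse = "+")]] <- mff_evaluate(fit, te, images = img_te)
  }
  summ <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(combination = nm, AccT = r$acc_t, t(r$macro), check.names = FALSE)
  }))
  list(results = results, summary = summ)
}

#' Cross-validate the MFF-CNN
#'
#' Fold assignment respects the paradigm (beat-level stratified folds intra,
#' patient-level folds inter); one model is fitted per fold on the remaining
#' folds and evaluated on the held-out fold.
#'
#' @param ds A [beat_dataset].
#' @param n_folds Number of folds (default 10).
#' @param paradigm As in [make_split()].
#' @param seed Seed for the fold assignment.
#' @param ... Passed on to [mff_fit()].
#' @return List with `folds` (assignment vector), `reports` (per-fold
#'   `metrics_report`), and `summary` (mean and sd of AccT and the macro
#'   metrics across folds).
#' @export
cross_validate <- function(ds, n_folds = 10,
                           paradigm = c("intra_patient", "inter_patient"),
                           seed = 1L, ...) {
  paradigm <- match.arg(paradigm)
  fold <- make_folds(ds, n_folds, paradigm, seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    fit <- mff_fit(subset_beats(ds, which(fold != f)), ...)
    reports[[f]] <- mff_evaluate(fit, subset_beats(ds, which(fold == f)))
  }
  mat <- t(vapply(reports, function(r) c(AccT = r$acc_t, r$macro), numeric(6)))
  list(folds = fold, reports = reports,
       summary = data.frame(metric = colnames(mat),
                            mean = colMeans(mat),
                            sd = apply(mat, 2, stats::sd)))
}
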