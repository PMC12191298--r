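# Split protocols, metric suite, training loop, ablation, cross-validation.

#' Classification metrics from a confusion matrix
#'
#' For a binary task with a designated positive class: accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' specificity `TN/(TN+FP)` and `F1 = 2*Sen*Pre/(Sen+Pre)`. For a
#' multi-class task the same quantities are computed per class one-vs-rest
#' and macro-averaged, and the overall accuracy `AccT` is the summed
#' per-class true positives over all evaluated beats (the confusion-matrix
#' trace over its total). All metrics are reported in percent.
#'
#' @param cm Square confusion matrix, rows = true class, columns = predicted.
#' @param positive For 2-class tasks, the positive class name (default the
#'   second row); ignored for more classes.
#' @return An object of class `metrics_report` with fields `confusion`,
#'   `per_class`, `macro` (named Acc/Sen/Pre/Spe/F1), `acc_t`, `n`.
#' @export
metrics_from_confusion <- function(cm, positive = NULL) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  if (is.null(rownames(cm))) {
    rownames(cm) <- colnames(cm) <- paste0("C", seq_len(nrow(cm)))
  }
  classes <- rownames(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  one_vs_rest <- function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sen <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    spe <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (sen + pre > 0) 2 * sen * pre / (sen + pre) else 0
    c(Acc = (tp + tn) / total, Sen = sen, Pre = pre, Spe = spe, F1 = f1) * 100
  }
  per_class <- t(vapply(classes, one_vs_rest, numeric(5)))
  acc_t <- sum(diag(cm)) / total * 100
  if (length(classes) == 2) {
    pos <- positive %||% classes[2]
    if (!pos %in% classes) stop("positive class not in confusion matrix")
    macro <- per_class[pos, ]
  } else {
    macro <- colMeans(per_class)
  }
  structure(list(confusion = cm, per_class = per_class, macro = macro,
                 acc_t = acc_t, n = total,
                 positive = if (length(classes) == 2) (positive %||% classes[2]) else NULL),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(sprintf("<metrics_report: %d samples, %d classes>\n", x$n, nrow(x$confusion)))
  cat(sprintf("  AccT %.2f%%  |  Acc %.2f  Sen %.2f  Pre %.2f  Spe %.2f  F1 %.2f\n",
              x$acc_t, x$macro["Acc"], x$macro["Sen"], x$macro["Pre"],
              x$macro["Spe"], x$macro["F1"]))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the study protocol: cross-entropy loss, stochastic
#' gradient descent with learning rate 0.001 and momentum 0.9, batch size 64,
#' 60 epochs.
#'
#' @param lr,momentum,batch_size,epochs Positive hyperparameters.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, momentum = 0.9, batch_size = 64,
                         epochs = 60, seed = 1L) {
  stopifnot(lr > 0, momentum >= 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Split a beat dataset for training and evaluation
#'
#' Intra-patient: beat-level stratified random split into train/validation/
#' test with ratios 7:2:1. Inter-patient: patient-level 7:3 train/test split
#' with no patient id shared across partitions and no separate validation
#' set. Both are deterministic given the seed. In inter mode, a class whose
#' patients cannot cover both partitions is kept wholly in training, with a
#' warning.
#'
#' @param ds A [beat_dataset].
#' @param paradigm `"intra_patient"` or `"inter_patient"`.
#' @param ratios Partition ratios (intra: length 3, default `c(7, 2, 1)`;
#'   inter: length 2, default `c(7, 3)`).
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `test` and (intra only)
#'   `val`.
#' @export
make_split <- function(ds, paradigm = c("intra_patient", "inter_patient"),
                       ratios = NULL, seed = 1L) {
  paradigm <- match.arg(paradigm)
  stopifnot(inherits(ds, "beat_dataset"))
  if (anyNA(ds$patient_id)) stop("every beat must carry a patient id")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  n <- length(ds)
  if (paradigm == "intra_patient") {
    ratios <- ratios %||% c(7, 2, 1)
    stopifnot(length(ratios) == 3)
    p <- ratios / sum(ratios)
    train <- val <- test <- integer(0)
    for (cl in unique(ds$label)) {
      idx <- sample(which(ds$label == cl))
      k <- length(idx)
      n_tr <- round(k * p[1]); n_va <- round(k * p[2])
      n_tr <- min(n_tr, k); n_va <- min(n_va, k - n_tr)
      train <- c(train, idx[seq_len(n_tr)])
      val <- c(val, idx[n_tr + seq_len(n_va)])
      test <- c(test, idx[setdiff(seq_len(k), seq_len(n_tr + n_va))])
    }
    list(train = sort(train), val = sort(val), test = sort(test))
  } else {
    ratios <- ratios %||% c(7, 3)
    stopifnot(length(ratios) == 2)
    p <- ratios[1] / sum(ratios)
    train_pat <- test_pat <- character(0)
    for (cl in unique(ds$label)) {
      pats <- unique(ds$patient_id[ds$label == cl])
      if (length(pats) < 2) {
        warning("class ", cl, " has fewer patients than partitions; kept in training")
        train_pat <- c(train_pat, pats)
        next
      }
      pats <- sample(pats)
      n_tr <- max(1, min(length(pats) - 1, round(length(pats) * p)))
      train_pat <- c(train_pat, pats[seq_len(n_tr)])
      test_pat <- c(test_pat, pats[-seq_len(n_tr)])
    }
    list(train = which(ds$patient_id %in% train_pat),
         test = which(ds$patient_id %in% test_pat))
  }
}

#' Assign cross-validation folds
#'
#' Intra-patient folds are beat-level and stratified by class; inter-patient
#' folds are patient-level (every beat of a patient lands in one fold).
#' Fold assignment exactly partitions the data and is deterministic given
#' the seed.
#'
#' @param ds A [beat_dataset].
#' @param n_folds Number of folds (default 10, >= 2).
#' @param paradigm Split paradigm as in [make_split()].
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..n_folds), one per beat.
#' @export
make_folds <- function(ds, n_folds = 10, paradigm = c("intra_patient", "inter_patient"),
                       seed = 1L) {
  paradigm <- match.arg(paradigm)
  stopifnot(n_folds >= 2)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  n <- length(ds)
  fold <- integer(n)
  if (paradigm == "intra_patient") {
    for (cl in unique(ds$label)) {
      idx <- sample(which(ds$label == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    pats <- unique(ds$patient_id)
    if (length(pats) < n_folds) stop("fewer patients than folds in inter-patient mode")
    pat_fold <- stats::setNames(rep_len(seq_len(n_folds), length(pats)), sample(pats))
    fold <- unname(pat_fold[ds$patient_id])
  }
  fold
}

# Internal: run the SGD loop on prepared tensors. `data` is a list with
# tensors named after the active branches plus integer labels y (1..K).
.train_loop <- function(net, data, config, verbose = FALSE) {
  n <- length(data$y)
  if (n == 0) stop("empty training partition")
  loss_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_batches <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      inputs <- list()
      for (b in net$branch_names) {
        x <- data[[b]]
        nd <- length(dim(x))
        inputs[[b]] <- if (nd == 3) x[, , idx, drop = FALSE] else x[, , , idx, drop = FALSE]
      }
      logits <- net$forward(inputs, train = TRUE)
      sx <- nn_softmax_xent(logits, data$y[idx])
      if (!is.finite(sx$loss)) stop("NaN/Inf loss at epoch ", ep, "; aborting")
      net$backward(sx$dlogits)
      nn_sgd_step(net$param_layers, config$lr, config$momentum)
      ep_loss <- ep_loss + sx$loss; n_batches <- n_batches + 1
    }
    loss_trace[ep] <- ep_loss / n_batches
    if (verbose) message(sprintf("epoch %d/%d: mean loss %.4f", ep, config$epochs, loss_trace[ep]))
  }
  # freeze-weight pass replacing the batch-norm running statistics with
  # exact aggregates under the final weights
  batches <- list()
  for (start in seq(1, n, by = config$batch_size)) {
    idx <- start:min(start + config$batch_size - 1, n)
    inputs <- list()
    for (b in net$branch_names) {
      x <- data[[b]]
      nd <- length(dim(x))
      inputs[[b]] <- if (nd == 3) x[, , idx, drop = FALSE] else x[, , , idx, drop = FALSE]
    }
    batches[[length(batches) + 1]] <- inputs
  }
  nn_bn_recalibrate(net, batches)
  loss_trace
}

# Internal: tensors for a beat subset. Beat arrays are (12, 651, n); images
# gain a leading singleton channel: (1, S, S, n).
.prep_tensors <- function(ds, images, idx, branches) {
  out <- list(y = NULL)
  if ("beat" %in% branches) out$beat <- ds$x[, , idx, drop = FALSE]
  if ("gaf" %in% branches) {
    g <- images$gaf[, , idx, drop = FALSE]
    out$gaf <- array(g, c(1, dim(g)))
  }
  if ("st" %in% branches) {
    s <- images$st[, , idx, drop = FALSE]
    out$st <- array(s, c(1, dim(s)))
  }
  out
}
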