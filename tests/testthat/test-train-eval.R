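# Brute-force tally oracle: recompute TP/TN/FP/FN per class directly from
# simulated (truth, prediction) pairs and form each metric from first
# principles.
brute_metrics <- function(cm) {
  classes <- rownames(cm)
  # reconstruct the (truth, prediction) pairs: cell (i, j) = truth i, pred j
  truth <- unlist(lapply(seq_along(classes), function(i)
    rep(classes[i], sum(cm[i, ]))))
  pred <- unlist(lapply(seq_along(classes), function(i)
    unlist(lapply(seq_along(classes), function(j) rep(classes[j], cm[i, j])))))
  per <- t(vapply(classes, function(k) {
    tp <- sum(truth == k & pred == k)
    fn <- sum(truth == k & pred != k)
    fp <- sum(truth != k & pred == k)
    tn <- sum(truth != k & pred != k)
    sen <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    spe <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (sen + pre > 0) 2 * sen * pre / (sen + pre) else 0
    c(Acc = (tp + tn) / length(truth), Sen = sen, Pre = pre, Spe = spe, F1 = f1) * 100
  }, numeric(5)))
  list(per_class = per, acc_t = mean(truth == pred) * 100)
}

random_cm <- function(k) {
  cm <- matrix(rpois(k * k, lambda = 8) + diag(k) * rpois(k, 30), k)
  while (sum(cm) == 0) cm <- matrix(rpois(k * k, 8), k)
  dimnames(cm) <- list(paste0("C", 1:k), paste0("C", 1:k))
  cm
}

test_that("metric suite matches brute-force tallies on random confusion matrices", {
  set.seed(11)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    cm <- random_cm(k)
    rep <- metrics_from_confusion(cm)
    oracle <- brute_metrics(cm)
    expect_equal(rep$per_class, oracle$per_class, tolerance = 1e-10)
    expect_equal(rep$acc_t, oracle$acc_t, tolerance = 1e-10)
    expect_true(all(rep$per_class >= 0 & rep$per_class <= 100))
    expect_equal(rep$n, sum(cm))
  }
})

test_that("hand-built binary confusion matrix yields the textbook values", {
  cm <- matrix(c(80, 10, 20, 90), 2, dimnames = list(c("HC", "MI"), c("HC", "MI")))
  # rows truth, cols predicted: TN=80 FP=20 FN=10 TP=90
  rep <- metrics_from_confusion(cm, positive = "MI")
  expect_equal(unname(rep$macro["Acc"]), 85)
  expect_equal(unname(rep$macro["Sen"]), 90)
  expect_equal(unname(rep$macro["Pre"]), 81.8182, tolerance = 1e-4)
  expect_equal(unname(rep$macro["Spe"]), 80)
  expect_equal(unname(rep$macro["F1"]), 85.7143, tolerance = 1e-4)
})

test_that("overall accuracy is the confusion trace over the total", {
  cm <- matrix(c(5, 1, 0, 1, 3, 0, 1, 1, 2), 3, byrow = TRUE,
               dimnames = list(paste0("K", 1:3), paste0("K", 1:3)))
  expect_equal(sum(cm), 14)
  cm[1, 2] <- 0  # adjust to the 12-beat example: diagonal 5,3,2, total 12
  cm[3, 1] <- 0
  expect_equal(sum(cm), 12)
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$acc_t, 10 / 12 * 100, tolerance = 1e-10)
  # perfect predictions: everything 100
  perfect <- diag(c(4, 5, 6))
  dimnames(perfect) <- list(paste0("K", 1:3), paste0("K", 1:3))
  rp <- metrics_from_confusion(perfect)
  expect_equal(unname(rp$acc_t), 100)
  expect_equal(unname(rp$macro), rep(100, 5), ignore_attr = TRUE)
})

test_that("intra-patient split is stratified 7:2:1 and deterministic", {
  ds <- small_beat_dataset(n_per_class = 2, duration = 8, seed = 3)
  sp <- make_split(ds, "intra_patient", seed = 5)
  n <- length(ds)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_len(n))
  expect_lt(abs(length(sp$train) / n - 0.7), 0.05)
  expect_lt(abs(length(sp$val) / n - 0.2), 0.05)
  sp2 <- make_split(ds, "intra_patient", seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, make_split(ds, "intra_patient", seed = 6)))
})

test_that("inter-patient split shares no patient ids across partitions", {
  ds <- small_beat_dataset(n_per_class = 4, duration = 5, seed = 4)
  sp <- make_split(ds, "inter_patient", seed = 2)
  expect_length(intersect(unique(ds$patient_id[sp$train]),
                          unique(ds$patient_id[sp$test])), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_len(length(ds)))
  # both classes represented in both partitions
  expect_setequal(unique(ds$label[sp$train]), c("HC", "MI"))
  expect_setequal(unique(ds$label[sp$test]), c("HC", "MI"))
  # a class with a single patient is kept in training, with a warning
  ds1 <- ds
  ds1$patient_id[ds1$label == "MI"] <- "Ponly"
  expect_warning(sp1 <- make_split(ds1, "inter_patient", seed = 2), "fewer patients")
  expect_true(all(which(ds1$label == "MI") %in% sp1$train))
})

test_that("fold assignment exactly partitions the data under both paradigms", {
  ds <- small_beat_dataset(n_per_class = 4, duration = 5, seed = 7)
  for (paradigm in c("intra_patient", "inter_patient")) {
    f <- make_folds(ds, n_folds = 4, paradigm = paradigm, seed = 3)
    expect_length(f, length(ds))
    expect_setequal(unique(f), 1:4)
    expect_identical(f, make_folds(ds, 4, paradigm, seed = 3))
    if (paradigm == "inter_patient") {
      # every patient's beats land in a single fold
      expect_true(all(tapply(f, ds$patient_id, function(v) length(unique(v))) == 1))
    }
  }
  expect_error(make_folds(ds, n_folds = 50, paradigm = "inter_patient"), "fewer patients")
})

test_that("training obeys degenerate hyperparameters", {
  set.seed(8)
  n <- 16
  y <- rep(1:2, each = n / 2)
  beat <- array(rnorm(12 * 32 * n, sd = 0.3), c(12, 32, n))
  beat[, 10:20, y == 2] <- beat[, 10:20, y == 2] + 2
  net <- build_mff(2, "beat", width_multiplier = 1 / 16)
  data <- list(beat = beat, y = y)
  # epsilon learning rate: parameters essentially unchanged after an epoch
  before <- lapply(net$param_layers, function(ly) ly$params)
  ecgmff:::.train_loop(net, data, train_config(lr = 1e-12, epochs = 1,
                                               batch_size = 8, seed = 1))
  after <- lapply(net$param_layers, function(ly) ly$params)
  delta <- max(unlist(Map(function(a, b) max(abs(unlist(a) - unlist(b))), before, after)))
  expect_lt(delta, 1e-9)
  # loss strictly decreases over the first epochs on separable data
  set.seed(8)
  net2 <- build_mff(2, "beat", width_multiplier = 1 / 16)
  tr <- ecgmff:::.train_loop(net2, data, train_config(lr = 0.01, epochs = 5,
                                                      batch_size = 8, seed = 1))
  expect_lt(tr[5], tr[1])
  # single-class degenerate optimum: loss falls toward zero, predictions collapse
  data1 <- list(beat = beat[, , y == 1, drop = FALSE], y = rep(1L, n / 2))
  set.seed(8)
  net3 <- build_mff(2, "beat", width_multiplier = 1 / 16)
  tr1 <- ecgmff:::.train_loop(net3, data1, train_config(lr = 0.05, epochs = 10,
                                                        batch_size = 8, seed = 1))
  expect_lt(tail(tr1, 1), 0.1)
  pred <- max.col(t(net3$predict_probs(list(beat = data1$beat))))
  expect_true(all(pred == 1))
})
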