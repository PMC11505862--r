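# Feedforward classifier under leave-one-subject-out (LOSO) validation.
# One dataset is built per subject: that subject's epochs form the test
# set; the remaining subjects' epochs are split 80/20 (row-level) into
# training and validation; feature standardisation is fitted on the
# training rows only. The network (four ReLU hidden layers of 128 units,
# 0.2 dropout, sigmoid output, binary cross-entropy, Adam, batch 32,
# 20 epochs) yields per-epoch case probabilities; a subject's diagnosis is
# the mean epoch probability compared with a 0.5 cutoff.

#' Feedforward network specification
#'
#' @param hidden_layers number of hidden layers.
#' @param width units per hidden layer.
#' @param dropout dropout rate after each hidden layer.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param standardize z-score features using training-row statistics
#'   (recommended; raw mode available).
#' @param seed base seed for weight initialisation, dropout and shuffling.
#' @return List of class `fnn_spec`.
#' @export
fnn_spec <- function(hidden_layers = 4, width = 128, dropout = 0.2,
                     epochs = 20, batch_size = 32, lr = 1e-3,
                     standardize = TRUE, seed = 1L) {
  structure(list(hidden_layers = as.integer(hidden_layers),
                 width = as.integer(width), dropout = dropout,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "fnn_spec")
}

#' Build leave-one-subject-out datasets
#'
#' One dataset per subject. The held-out subject's rows are the test set
#' and never enter training or validation; the remaining rows are split
#' 80/20 at the row level (seeded). The feature scaler (per-feature mean
#' and s.d.) is fitted on the training rows only.
#'
#' @param table feature table with `subject_id` and `group` columns.
#' @param feature_names feature columns; defaults to
#'   `attr(table, "feature_names")`.
#' @param val_fraction fraction of non-test rows used for validation.
#' @param seed split seed.
#' @return List of `loso_dataset` objects (test_subject, idx_train,
#'   idx_val, idx_test, center, scale, feature_names).
#' @export
make_loso_datasets <- function(table, feature_names = NULL,
                               val_fraction = 0.2, seed = 1L) {
  if (is.null(feature_names)) feature_names <- attr(table, "feature_names")
  if (is.null(feature_names)) stopf("feature_names required")
  subjects <- unique(table$subject_id)
  grp <- table$group[match(subjects, table$subject_id)]
  if (length(unique(grp)) < 2 || min(table(grp)) < 2)
    stopf("need at least two subjects per class")
  counts <- table(table$subject_id)
  if (any(counts == 0)) stopf("subject with zero rows")
  X <- as.matrix(table[, feature_names, drop = FALSE])
  if (any(!is.finite(X))) stopf("non-finite feature values")
  lapply(seq_along(subjects), function(k) {
    test_subject <- subjects[k]
    idx_test <- which(table$subject_id == test_subject)
    rest <- which(table$subject_id != test_subject)
    split_seed <- derive_seed(seed, k)
    idx_val <- with_seed(split_seed,
                         sort(sample(rest, round(val_fraction * length(rest)))))
    idx_train <- setdiff(rest, idx_val)
    ctr <- colMeans(X[idx_train, , drop = FALSE])
    scl <- apply(X[idx_train, , drop = FALSE], 2, sd)
    scl[scl < .Machine$double.eps] <- 1
    structure(list(test_subject = test_subject, idx_train = idx_train,
                   idx_val = idx_val, idx_test = idx_test,
                   center = ctr, scale = scl,
                   feature_names = feature_names, seed = split_seed),
              class = "loso_dataset")
  })
}

scale_rows <- function(table, ds, idx, spec) {
  X <- as.matrix(table[idx, ds$feature_names, drop = FALSE])
  if (spec$standardize)
    X <- sweep(sweep(X, 2, ds$center), 2, ds$scale, "/")
  X
}

labels01 <- function(table, idx) as.numeric(table$group[idx] == "case")

#' Train the feedforward network on one LOSO dataset
#'
#' Features are standardised with the dataset's training-row scaler, the
#' network is trained for exactly `spec$epochs` epochs, and train/val
#' accuracy at the 0.5 epoch-probability threshold is reported.
#'
#' @param ds a `loso_dataset`.
#' @param table the feature table the dataset indexes into.
#' @param spec an [fnn_spec()].
#' @return List of class `fnn_model` with weights, the spec and
#'   train/val accuracy.
#' @export
train_fnn <- function(ds, table, spec = fnn_spec()) {
  stopifnot(inherits(ds, "loso_dataset"), inherits(spec, "fnn_spec"))
  ytr <- labels01(table, ds$idx_train)
  if (length(unique(ytr)) < 2)
    stopf("training rows contain a single class")
  Xtr <- scale_rows(table, ds, ds$idx_train, spec)
  Xval <- scale_rows(table, ds, ds$idx_val, spec)
  fit <- .fnn_train_cpp(Xtr, ytr, Xval, labels01(table, ds$idx_val),
                        spec$hidden_layers, spec$width, spec$dropout,
                        spec$epochs, spec$batch_size, spec$lr,
                        derive_seed(spec$seed, length(ds$idx_train)))
  structure(list(W = fit$W, b = fit$b, spec = spec,
                 train_acc = fit$train_acc, val_acc = fit$val_acc,
                 test_subject = ds$test_subject), class = "fnn_model")
}

#' Epoch probabilities from a trained network
#'
#' @param model an `fnn_model`.
#' @param X numeric matrix of (already standardised) feature rows.
#' @return Case probabilities in (0, 1).
#' @export
predict_fnn <- function(model, X) {
  stopifnot(inherits(model, "fnn_model"))
  p <- .fnn_predict_cpp(model$W, model$b, as.matrix(X))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Diagnose the held-out subject
#'
#' Scores the test rows with the model; the subject-level diagnosis is the
#' mean epoch probability compared with the cutoff (an exact tie is called
#' a case and flagged).
#'
#' @param model an `fnn_model`.
#' @param ds the `loso_dataset` the model was trained on.
#' @param table the feature table.
#' @param cutoff decision threshold on the mean probability.
#' @return List of class `diagnosis_result`: subject_id, epoch_probs,
#'   mean_prob, predicted_label, true_label, tie flag.
#' @export
diagnose_subject <- function(model, ds, table, cutoff = 0.5) {
  if (!length(ds$idx_test)) stopf("empty test rows for subject %s",
                                  ds$test_subject)
  probs <- predict_fnn(model, scale_rows(table, ds, ds$idx_test, model$spec))
  mp <- mean(probs)
  structure(list(subject_id = ds$test_subject, epoch_probs = probs,
                 mean_prob = mp,
                 predicted_label = if (mp >= cutoff) "case" else "control",
                 true_label = table$group[ds$idx_test[1]],
                 tie = mp == cutoff,
                 train_acc = model$train_acc, val_acc = model$val_acc),
            class = "diagnosis_result")
}

results_confusion <- function(results) {
  pred <- vapply(results, `[[`, "", "predicted_label")
  truth <- vapply(results, `[[`, "", "true_label")
  confusion_table(TP = sum(pred == "case" & truth == "case"),
                  TN = sum(pred == "control" & truth == "control"),
                  FP = sum(pred == "case" & truth == "control"),
                  FN = sum(pred == "control" & truth == "case"))
}

#' Run the full leave-one-subject-out evaluation
#'
#' Trains one network per LOSO dataset and aggregates the subject-level
#' diagnoses into a confusion table.
#'
#' @param table feature table.
#' @param feature_names feature columns (default: recorded on the table).
#' @param spec an [fnn_spec()].
#' @param seed split seed passed to [make_loso_datasets()].
#' @param cutoff subject-level decision threshold.
#' @param verbose print one line per dataset.
#' @return List of class `loso_run`: `results` (per-subject
#'   `diagnosis_result`s), `confusion`, `subject_accuracy`, and a `summary`
#'   data.frame (one row per dataset with train/val accuracy and labels).
#' @export
run_loso <- function(table, feature_names = NULL, spec = fnn_spec(),
                     seed = 1L, cutoff = 0.5, verbose = FALSE) {
  datasets <- make_loso_datasets(table, feature_names, seed = seed)
  results <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    model <- train_fnn(datasets[[i]], table, spec)
    results[[i]] <- diagnose_subject(model, datasets[[i]], table, cutoff)
    if (verbose)
      message(sprintf("%s: train %.3f val %.3f mean prob %.3f -> %s",
                      results[[i]]$subject_id, model$train_acc,
                      model$val_acc, results[[i]]$mean_prob,
                      results[[i]]$predicted_label))
  }
  ct <- results_confusion(results)
  summary <- data.frame(
    subject_id = vapply(results, `[[`, "", "subject_id"),
    true_label = vapply(results, `[[`, "", "true_label"),
    predicted_label = vapply(results, `[[`, "", "predicted_label"),
    mean_prob = vapply(results, `[[`, 1, "mean_prob"),
    train_acc = vapply(results, `[[`, 1, "train_acc"),
    val_acc = vapply(results, `[[`, 1, "val_acc"),
    stringsAsFactors = FALSE)
  structure(list(results = results, confusion = ct,
                 subject_accuracy = (ct$TP + ct$TN) /
                   (ct$TP + ct$TN + ct$FP + ct$FN),
                 summary = summary, datasets = datasets),
            class = "loso_run")
}

#' Random-label (permutation) control
#'
#' Permutes the subject-to-group assignment (at the subject level) before
#' running the LOSO evaluation. With no true signal surviving the
#' permutation, subject-level accuracy should be at chance; the result also
#' reports whether the permuted model degenerates to predicting one class.
#'
#' @param table feature table.
#' @param feature_names feature columns.
#' @param spec an [fnn_spec()].
#' @param seed permutation (and split) seed.
#' @param permutation optional explicit permutation of the subjects'
#'   labels; the identity permutation reproduces [run_loso()] exactly.
#' @return A `loso_run` with extra fields `permutation` and
#'   `degenerate` (TRUE when every subject got the same predicted label).
#' @export
random_label_test <- function(table, feature_names = NULL, spec = fnn_spec(),
                              seed = 1L, permutation = NULL) {
  subjects <- unique(table$subject_id)
  if (is.null(permutation))
    permutation <- with_seed(derive_seed(seed, 97L),
                             sample(seq_along(subjects)))
  orig <- table$group[match(subjects, table$subject_id)]
  new_groups <- orig[permutation]
  shuffled <- table
  shuffled$group <- new_groups[match(table$subject_id, subjects)]
  run <- run_loso(shuffled, feature_names, spec, seed = seed)
  run$permutation <- permutation
  pred <- vapply(run$results, `[[`, "", "predicted_label")
  run$degenerate <- length(unique(pred)) == 1
  run
}
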