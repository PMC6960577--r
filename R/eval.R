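#' Root mean squared error
#'
#' @param y observed values.
#' @param yhat predicted values of the same length.
#' @return sqrt(mean((yhat - y)^2)).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) == 0L) stop("empty input")
  sqrt(mean((yhat - y)^2))
}

#' Mean absolute error
#'
#' Always no larger than [rmse()] on the same residuals.
#'
#' @inheritParams rmse
#' @return mean(abs(y - yhat)).
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) == 0L) stop("empty input")
  mean(abs(y - yhat))
}

#' Major-emotion match accuracy
#'
#' Fraction of windows whose predicted dominant emotion (argmax over the
#' five intensities) equals the target's dominant emotion. Ties are broken
#' by the lowest emotion index in the fixed order [EMOTIONS], applied
#' identically to targets and predictions.
#'
#' @param targets n x 5 target intensity matrix.
#' @param preds n x 5 predicted intensity matrix.
#' @return list with `accuracy` (fraction), `matched` and `total` counts.
#' @export
match_accuracy <- function(targets, preds) {
  targets <- as.matrix(targets); preds <- as.matrix(preds)
  if (!all(dim(targets) == dim(preds))) stop("shape mismatch")
  if (nrow(targets) == 0L) stop("empty input")
  a <- max.col(targets, ties.method = "first")
  b <- max.col(preds, ties.method = "first")
  matched <- sum(a == b)
  list(accuracy = matched / nrow(targets), matched = matched,
       total = nrow(targets))
}

# per-session preprocessing + windowing + (optional) feature extraction,
# shared by loocv and run_test
.session_samples <- function(session, spec, preproc) {
  if (isTRUE(spec$detrend) || isTRUE(spec$outliers)) {
    cfg <- preproc
    if (!isTRUE(spec$detrend)) cfg$detrend_method <- "constant"
    # outlier correction disabled by an unreachable threshold
    if (!isTRUE(spec$outliers)) cfg$abrupt_threshold <- Inf
    session <- preprocess_session(session, cfg)
  } else {
    norm <- function(ts) normalize_series(ts, preproc$normalization)
    session$hr_clean <- session$hr
    session$hr <- norm(session$hr)
    session$gsr <- norm(session$gsr)
    session$eeg <- lapply(session$eeg, norm)
  }
  windowize(session, preproc)
}

# concatenated normalized raw samples of one window (raw-data mode input)
.raw_row <- function(sample, modalities) {
  parts <- c(if (isTRUE(modalities[["hr"]])) list(sample$hr),
             if (isTRUE(modalities[["gsr"]])) list(sample$gsr),
             if (isTRUE(modalities[["eeg"]])) sample$eeg)
  unlist(parts, use.names = FALSE)
}

.raw_matrix <- function(samples, modalities) {
  rows <- lapply(samples, .raw_row, modalities = modalities)
  len <- min(lengths(rows))
  x <- do.call(rbind, lapply(rows, function(r) r[seq_len(len)]))
  colnames(x) <- paste0("raw", seq_len(len))
  targets <- do.call(rbind, lapply(samples, `[[`, "target"))
  colnames(targets) <- EMOTIONS
  structure(list(x = x, targets = targets,
                 session_id = vapply(samples, `[[`, character(1), "session_id"),
                 window = vapply(samples, `[[`, integer(1), "window"),
                 blocks = NULL, mode = "raw"),
            class = "feature_matrix")
}

#' Leave-one-flight-out cross-validation
#'
#' One fold per session: the network is trained on the remaining sessions'
#' windows and evaluated on the held-out flight. Feature selection (when
#' enabled) and column centering/scaling are re-fit on the training folds
#' only, so no information from the held-out flight leaks into training.
#' Sessions yielding zero windows are skipped with a warning.
#'
#' @param cohort named list of `flight_session` objects (>= 2).
#' @param spec a [test_spec()] describing the pipeline toggles.
#' @param preproc a [preproc_config()].
#' @param net_options list overriding [network_spec()] arguments (e.g.
#'   `hidden`, `epochs`, `lr`, `seed`).
#' @param rtor a [rtor_config()], or `NULL` to skip output correction.
#' @param wavelet a [wavelet_config()].
#' @return an `eval_report`: per-fold per-emotion RMSE/MAE, match counts,
#'   cohort-level means and sds, and the input width fed to the network.
#' @export
loocv <- function(cohort, spec = test_spec(), preproc = preproc_config(),
                  net_options = list(), rtor = rtor_config(),
                  wavelet = wavelet_config()) {
  if (length(cohort) < 2L) stop("LOOCV needs at least 2 sessions")
  ids <- vapply(cohort, `[[`, character(1), "session_id")
  names(cohort) <- ids
  modalities <- spec$modalities

  samples <- lapply(cohort, function(s)
    tryCatch(.session_samples(s, spec, preproc),
             error = function(e) {
               if (grepl("window longer than session", conditionMessage(e)))
                 list()
               else stop(e)
             }))
  n_windows <- lengths(samples)
  if (any(n_windows == 0L)) {
    warning("skipping sessions with zero windows: ",
            paste(ids[n_windows == 0L], collapse = ", "))
    samples <- samples[n_windows > 0L]
    ids <- names(samples)
  }

  fms <- if (isTRUE(spec$fe)) {
    lapply(samples, build_feature_matrix, wavelet = wavelet,
           modalities = modalities)
  } else {
    lapply(samples, .raw_matrix, modalities = modalities)
  }

  fold_rows <- list(); fold_match <- list(); fold_train <- list()
  input_width <- NA_integer_
  for (hold in ids) {
    train_fm <- Reduce(function(a, b) {
      a$x <- rbind(a$x, b$x); a$targets <- rbind(a$targets, b$targets)
      a$session_id <- c(a$session_id, b$session_id)
      a$window <- c(a$window, b$window); a
    }, fms[setdiff(ids, hold)])
    test_fm <- fms[[hold]]
    stopifnot(!hold %in% train_fm$session_id,
              all(test_fm$session_id == hold))
    fold_train[[hold]] <- unique(train_fm$session_id)

    if (isTRUE(spec$svd)) {
      sel <- fit_selection(train_fm)
      train_fm <- apply_selection(train_fm, sel)
      test_fm <- apply_selection(test_fm, sel)
    }

    X_train <- train_fm$x; X_test <- test_fm$x
    if (isTRUE(spec$cc)) {            # column centering, fit on train only
      ctr <- colMeans(X_train)
      X_train <- sweep(X_train, 2L, ctr)
      X_test <- sweep(X_test, 2L, ctr)
    }
    # unit-variance scaling keeps heterogeneous feature units comparable
    scl <- pmax(apply(X_train, 2L, stats::sd), 1e-12)
    X_train <- sweep(X_train, 2L, scl, `/`)
    X_test <- sweep(X_test, 2L, scl, `/`)
    input_width <- ncol(X_train)

    args <- utils::modifyList(
      list(input = ncol(X_train), hidden = c(83, 83), output = 5L,
           activation = spec$activation, optimizer = spec$optimizer,
           lr = if (spec$optimizer == "adam") 0.02 else 0.5,
           epochs = 500L, seed = 1L),
      net_options)
    model <- init_network(do.call(network_spec, args))
    model <- train_network(model, X_train, train_fm$targets)

    preds <- predict_emotions(model, X_test)
    if (!is.null(rtor) && nrow(preds) > rtor$batch_length)
      preds <- rtor_filter(preds, rtor)

    m <- match_accuracy(test_fm$targets, preds)
    fold_match[[hold]] <- data.frame(
      session = hold, matched = m$matched, total = m$total,
      accuracy = m$accuracy, stringsAsFactors = FALSE)
    fold_rows[[hold]] <- data.frame(
      session = hold, emotion = EMOTIONS,
      rmse = vapply(seq_len(5L), function(j)
        rmse(test_fm$targets[, j], preds[, j]), numeric(1)),
      mae = vapply(seq_len(5L), function(j)
        mae(test_fm$targets[, j], preds[, j]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, c(fold_rows, list(make.row.names = FALSE)))
  matches <- do.call(rbind, c(fold_match, list(make.row.names = FALSE)))
  summary <- do.call(rbind, lapply(split(folds, folds$emotion)[EMOTIONS],
    function(d) data.frame(emotion = d$emotion[1],
                           rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
                           mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae),
                           stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(folds = folds, matches = matches, summary = summary,
                 match_accuracy_mean = mean(matches$accuracy),
                 match_accuracy_sd = stats::sd(matches$accuracy),
                 input_width = input_width, spec = spec,
                 fold_train_sessions = fold_train),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds, input width %d\n",
              nrow(x$matches), x$input_width))
  cat("per-emotion cohort means:\n")
  print(x$summary, digits = 3)
  cat(sprintf("match accuracy: %.3f +/- %.3f\n",
              x$match_accuracy_mean, x$match_accuracy_sd))
  invisible(x)
}
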