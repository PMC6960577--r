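#' Singular value decomposition with contract checks
#'
#' Thin wrapper around [base::svd()] that validates the input and returns
#' factors satisfying A = U D V* with non-negative singular values sorted
#' in non-increasing order and orthonormal columns in U and V.
#'
#' @param a numeric matrix with finite entries.
#' @return list with `u`, `d` (vector of singular values) and `v`.
#' @export
svd_decompose <- function(a) {
  a <- as.matrix(a)
  if (!all(is.finite(a))) stop("matrix has non-finite entries")
  s <- svd(a)
  list(u = s$u, d = s$d, v = s$v)
}

#' Fit an SVD-based feature selection
#'
#' Per modality block (heart rate, electrodermal, and each EEG channel),
#' the column-centered block is decomposed as A = U D V*, and each original
#' column is scored by the norm of its loadings in the leading singular
#' directions weighted by the singular values:
#' score_j = sqrt(sum_k (d_k v_jk)^2) over the top k directions, where k is
#' the number of columns retained for that block. The top-scoring columns
#' are kept, in importance order; ties go to the lower original column
#' index. Selection is unsupervised (targets are never used) and invariant
#' to row order.
#'
#' @param fm a `feature_matrix` in all-features mode.
#' @param counts named retained counts: `hr`, `gsr`, `eeg_per_channel`
#'   (defaults 6, 4 and 5, i.e. 50 features in total).
#' @return a `svd_selection`: per-block singular values, scores, and kept
#'   column names, plus a `manifest` data.frame (block, feature, score,
#'   kept).
#' @export
fit_selection <- function(fm, counts = c(hr = 6, gsr = 4,
                                         eeg_per_channel = 5)) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!identical(fm$mode, "all"))
    stop("selection expects a feature matrix in all-features mode")
  keep_names <- character(0)
  manifest <- list()
  singular <- list()
  for (bn in names(fm$blocks)) {
    cols <- fm$blocks[[bn]]
    count <- if (bn == "hr") counts[["hr"]]
             else if (bn == "gsr") counts[["gsr"]]
             else counts[["eeg_per_channel"]]
    if (count > length(cols))
      stop(sprintf("requested %d features from block %s of width %d",
                   count, bn, length(cols)))
    a <- fm$x[, cols, drop = FALSE]
    a <- sweep(a, 2L, colMeans(a))       # column centering
    s <- svd_decompose(a)
    k <- min(count, length(s$d))
    load <- s$v[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)],
                                                     nrow = k)
    score <- sqrt(rowSums(load^2))
    ord <- order(-score, seq_along(score))   # ties: lower index wins
    kept_idx <- sort(ord[seq_len(count)])
    keep_names <- c(keep_names, colnames(a)[ord[seq_len(count)]])
    manifest[[bn]] <- data.frame(block = bn, feature = colnames(a),
                                 score = score,
                                 kept = seq_along(cols) %in% kept_idx,
                                 stringsAsFactors = FALSE)
    singular[[bn]] <- s$d
  }
  structure(list(keep = keep_names, counts = counts,
                 singular_values = singular,
                 manifest = do.call(rbind, manifest)),
            class = "svd_selection")
}

#' Apply a fitted selection to a feature matrix
#'
#' @param fm a `feature_matrix` in all-features mode with the same columns
#'   the selection was fitted on.
#' @param sel a `svd_selection` from [fit_selection()].
#' @return the reduced `feature_matrix` (mode `"selected"`).
#' @export
apply_selection <- function(fm, sel) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(sel, "svd_selection"))
  if (!all(sel$keep %in% colnames(fm$x)))
    stop("feature matrix is missing columns the selection was fitted on")
  keep <- intersect(colnames(fm$x), sel$keep)  # preserve original order
  fm$x <- fm$x[, keep, drop = FALSE]
  fm$blocks <- .feature_blocks(colnames(fm$x))
  fm$mode <- "selected"
  fm$selection <- sel
  fm
}

#' SVD feature selection (fit + apply)
#'
#' Convenience wrapper: fits the selection on `fm` and returns the reduced
#' matrix. `mode = "project"` instead replaces each block by its truncated
#' score matrix U D (feature identities are lost); column selection is the
#' default.
#'
#' @inheritParams fit_selection
#' @param mode `"select"` (default) or `"project"`.
#' @return a `feature_matrix` in `"selected"` (or `"projected"`) mode.
#' @export
select_features <- function(fm, counts = c(hr = 6, gsr = 4,
                                           eeg_per_channel = 5),
                            mode = c("select", "project")) {
  mode <- match.arg(mode)
  if (mode == "select") return(apply_selection(fm, fit_selection(fm, counts)))
  stopifnot(inherits(fm, "feature_matrix"))
  out <- list()
  for (bn in names(fm$blocks)) {
    cols <- fm$blocks[[bn]]
    count <- if (bn == "hr") counts[["hr"]]
             else if (bn == "gsr") counts[["gsr"]]
             else counts[["eeg_per_channel"]]
    a <- sweep(fm$x[, cols, drop = FALSE], 2L,
               colMeans(fm$x[, cols, drop = FALSE]))
    s <- svd_decompose(a)
    k <- min(count, length(s$d))
    sc <- s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], nrow = k)
    colnames(sc) <- paste0(bn, "_pc", seq_len(k))
    out[[bn]] <- sc
  }
  fm$x <- do.call(cbind, out)
  fm$blocks <- NULL
  fm$mode <- "projected"
  fm
}
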