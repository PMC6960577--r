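#' Specification of one recognition test
#'
#' Mirrors one row of the study's test matrix: preprocessing toggles
#' (detrend, outlier correction), feature extraction, SVD feature
#' selection, column centering, the hidden activation, the optimizer, and
#' the modality mask. Raw-data tests (no feature extraction) feed
#' fixed-length windows of normalized raw samples straight to the network.
#'
#' @param id optional test number.
#' @param detrend,outliers,fe,svd,cc logical toggles.
#' @param activation `"sigmoid"` or `"relu"`.
#' @param optimizer `"sgd"` or `"adam"`.
#' @param modalities named logical vector `c(hr=, gsr=, eeg=)`; at least
#'   one must be enabled.
#' @return a `test_spec` list.
#' @export
test_spec <- function(id = NA_integer_, detrend = TRUE, outliers = TRUE,
                      fe = TRUE, svd = FALSE, cc = TRUE,
                      activation = c("sigmoid", "relu"),
                      optimizer = c("adam", "sgd"),
                      modalities = c(hr = TRUE, gsr = TRUE, eeg = TRUE)) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  if (!any(unlist(modalities))) stop("at least one modality must be enabled")
  if (!fe && svd) stop("SVD selection requires feature extraction")
  structure(list(id = id, detrend = detrend, outliers = outliers, fe = fe,
                 svd = svd, cc = cc, activation = activation,
                 optimizer = optimizer,
                 modalities = modalities),
            class = "test_spec")
}

#' The 34-row recognition test matrix
#'
#' Tests 1--2 are raw-data runs (no preprocessing or feature extraction);
#' tests 3--18 use the full 90-column feature set; tests 19--34 add SVD
#' feature selection. Within each block of four, the activation/optimizer
#' pairs cycle ReLU+adam, sigmoid+sgd, sigmoid+adam, ReLU+sgd, and the
#' modality mask drops HR, GSR or EEG in the later families.
#'
#' @return data.frame with one row per test and the toggle columns of
#'   [test_spec()].
#' @export
paper_test_matrix <- function() {
  acts <- c("relu", "sigmoid", "sigmoid", "relu")
  opts <- c("adam", "sgd", "adam", "sgd")
  masks <- list(c(TRUE, TRUE, TRUE), c(FALSE, TRUE, TRUE),
                c(TRUE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
  rows <- list(
    data.frame(id = 1:2, detrend = FALSE, outliers = FALSE, fe = FALSE,
               svd = FALSE, cc = FALSE, activation = "sigmoid",
               optimizer = c("sgd", "adam"), hr = TRUE, gsr = TRUE,
               eeg = TRUE, stringsAsFactors = FALSE))
  id <- 3L
  for (svd in c(FALSE, TRUE)) {
    for (m in masks) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id:(id + 3L), detrend = TRUE, outliers = TRUE, fe = TRUE,
        svd = svd, cc = TRUE, activation = acts, optimizer = opts,
        hr = m[1], gsr = m[2], eeg = m[3], stringsAsFactors = FALSE)
      id <- id + 4L
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Test specification for a numbered test
#'
#' @param id test number, 1--34.
#' @return the corresponding [test_spec()].
#' @export
test_spec_for <- function(id) {
  tm <- paper_test_matrix()
  row <- tm[tm$id == id, ]
  if (nrow(row) != 1L) stop("unknown test id: ", id)
  test_spec(id = row$id, detrend = row$detrend, outliers = row$outliers,
            fe = row$fe, svd = row$svd, cc = row$cc,
            activation = row$activation, optimizer = row$optimizer,
            modalities = c(hr = row$hr, gsr = row$gsr, eeg = row$eeg))
}

#' Run one recognition test over a cohort
#'
#' Executes ingest -> (optional) preprocessing -> (optional) feature
#' extraction -> (optional) SVD selection -> leave-one-flight-out MLP
#' training -> RTOR -> evaluation with the spec's toggles.
#'
#' @param spec a [test_spec()], or a test number passed to
#'   [test_spec_for()].
#' @param cohort a named list of `flight_session` objects, or a directory
#'   written by [write_cohort()].
#' @param seed seed for weight initialization.
#' @param ... further arguments passed to [loocv()] (`preproc`,
#'   `net_options`, `rtor`, `wavelet`).
#' @return an `eval_report` with a `provenance` element recording the spec
#'   and seed.
#' @export
run_test <- function(spec, cohort, seed = 1L, ...) {
  if (is.numeric(spec)) spec <- test_spec_for(spec)
  stopifnot(inherits(spec, "test_spec"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (length(cohort) < 2L) stop("cohort must contain at least 2 sessions")
  dots <- list(...)
  net_options <- utils::modifyList(list(seed = as.integer(seed)),
                                   dots$net_options %||% list())
  dots$net_options <- net_options
  report <- do.call(loocv, c(list(cohort = cohort, spec = spec), dots))
  report$provenance <- list(spec = spec, seed = as.integer(seed),
                            n_sessions = length(cohort),
                            package_version =
                              as.character(utils::packageVersion("affectflight")))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
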