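#' Read a delimited dataset with one response column
#'
#' Expects a header row, a numeric response column and numeric feature
#' columns. Rows with missing values and non-numeric cells are rejected with
#' row/column diagnostics; duplicated column names are an error.
#'
#' @param path CSV file path.
#' @param response name of the response column (default `"y"`).
#' @return List of class `"mixreg_data"` with `X` (features, named columns),
#'   `y`, and `feature_names`.
#' @export
read_mixreg_csv <- function(path, response = "y") {
  df <- read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicated column names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  if (!response %in% names(df))
    stop("response column '", response, "' not found")
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column '", cn, "'")
    if (anyNA(df[[cn]]))
      stop("missing value in column '", cn, "', row ",
           which(is.na(df[[cn]]))[1L])
  }
  y <- df[[response]]
  Xdf <- df[setdiff(names(df), response)]
  X <- as.matrix(Xdf)
  structure(list(X = X, y = y, feature_names = colnames(X)),
            class = "mixreg_data")
}

#' Write a dataset as CSV plus a JSON truth sidecar
#'
#' The CSV has a `y` column followed by features `x1..xp`. If the dataset
#' carries ground truth (simulated data) it is written alongside as
#' `<stem>_truth.json`.
#'
#' @param data a `"mixreg_data"` (e.g. from [simulate_mixreg()]).
#' @param path output CSV path.
#' @return Invisibly, the paths written.
#' @export
write_mixreg_csv <- function(data, path) {
  X <- data$X
  colnames(X) <- data$feature_names %||% paste0("x", seq_len(ncol(X)))
  df <- data.frame(y = data$y, X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  paths <- path
  if (!is.null(data$truth)) {
    tp <- sub("\\.csv$", "", path)
    tp <- paste0(tp, "_truth.json")
    jsonlite::write_json(data$truth, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Train/test split schemes
#'
#' `"in-order"` takes the first `ceiling(fraction * n)` rows for training
#' (the convention of datasets published in a fixed order); `"shuffled"`
#' permutes rows first; `"k-fold"` returns disjoint folds covering all rows.
#'
#' @param n number of rows, or a `"mixreg_data"`/list with `y`.
#' @param fraction training fraction in (0, 1) (ignored for `"k-fold"`).
#' @param scheme `"in-order"`, `"shuffled"` or `"k-fold"`.
#' @param k number of folds for `"k-fold"`.
#' @param seed optional seed for the random schemes.
#' @return For the two holdout schemes, a list with integer index vectors
#'   `train` and `test`; for `"k-fold"`, a list of `k` fold index vectors.
#' @export
split_train_test <- function(n, fraction = 0.8,
                             scheme = c("in-order", "shuffled", "k-fold"),
                             k = 5L, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n)) n <- length(n$y)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "k-fold") {
    if (n < k) stop("n too small for ", k, " folds")
    idx <- sample.int(n)
    return(split(idx, rep_len(seq_len(k), n)))
  }
  stopifnot(fraction > 0, fraction < 1)
  ntr <- ceiling(fraction * n)
  if (ntr >= n || ntr < 1L) stop("n too small to split at fraction ", fraction)
  ord <- if (scheme == "shuffled") sample.int(n) else seq_len(n)
  list(train = ord[seq_len(ntr)], test = ord[(ntr + 1L):n])
}

#' Serialize a mixture regression model to JSON
#'
#' Stores K, mixing proportions, sigmas and each component's intercept plus
#' sparse slopes as an index/value map; [read_model_json()] inverts it.
#'
#' @param model a `"mixreg_model"`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(K = model$K, pi = model$pi, sigma = model$sigma,
              components = lapply(model$fits, function(f)
                list(intercept = f$intercept,
                     support = as.integer(f$support),
                     coef = as.numeric(f$coef))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fits <- lapply(seq_len(obj$K), function(k) {
    cmp <- if (is.data.frame(obj$components)) as.list(obj$components[k, ])
           else obj$components[[k]]
    new_sparse_fit(intercept = as.numeric(cmp$intercept),
                   coef = as.numeric(unlist(cmp$coef)),
                   support = as.integer(unlist(cmp$support)),
                   screened = integer(0), lambda = NA_real_,
                   converged = TRUE, n = NA_integer_)
  })
  mixreg_model(as.numeric(obj$pi), fits, as.numeric(obj$sigma))
}
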