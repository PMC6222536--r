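#' Train a support-vector machine on a feature matrix
#'
#' Thin, contract-enforcing wrapper around the libsvm C-classification
#' solver (via e1071). Features are not scaled by default: every feature
#' family in this package already lives on a bounded scale, and scaling is
#' exposed as an explicit option rather than a silent default.
#'
#' @param features A labelled `feature_matrix` containing both classes.
#' @param kernel `"linear"` or `"gaussian"` (radial basis).
#' @param C Soft-margin cost parameter (> 0).
#' @param gamma Kernel width; required for the gaussian kernel, ignored for
#'   the linear kernel.
#' @param scale Standardise columns before training (default `FALSE`).
#' @return A `cytorec_svm` model object.
#' @export
svm_train <- function(features, kernel = c("linear", "gaussian"), C = 1,
                      gamma = NULL, scale = FALSE) {
  stopifnot(inherits(features, "feature_matrix"))
  kernel <- match.arg(kernel)
  if (is.null(features$labels)) abort_training("feature matrix has no labels")
  if (length(unique(features$labels)) < 2L) {
    abort_training("training set contains a single class")
  }
  if (kernel == "gaussian" && is.null(gamma)) {
    abort_validation("gamma is required for the gaussian kernel")
  }
  if (C <= 0) abort_validation("C must be > 0")
  fit <- e1071::svm(
    x = features$values,
    y = factor(features$labels, levels = c(-1L, 1L)),
    type = "C-classification",
    kernel = if (kernel == "linear") "linear" else "radial",
    cost = C,
    gamma = gamma %||% (1 / ncol(features$values)),
    scale = scale
  )
  structure(list(fit = fit, kernel = kernel, C = C, gamma = gamma,
                 scale = scale, schema = features$schema,
                 feature_names = colnames(features$values)),
            class = "cytorec_svm")
}

#' @export
print.cytorec_svm <- function(x, ...) {
  cat(sprintf("<cytorec_svm> %s kernel, C=%g%s, schema '%s' (%d features), %d SVs\n",
              x$kernel, x$C,
              if (x$kernel == "gaussian") sprintf(", gamma=%g", x$gamma) else "",
              x$schema, length(x$feature_names), nrow(x$fit$SV)))
  invisible(x)
}

#' Predict class labels from a trained model
#'
#' @param object A `cytorec_svm`.
#' @param newdata A `feature_matrix` with the same schema/feature columns.
#' @param ... Unused.
#' @return Named integer vector of +1/-1 labels aligned with the ids.
#' @export
predict.cytorec_svm <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_matrix"))
  if (!identical(colnames(newdata$values), object$feature_names)) {
    abort_schema(sprintf(
      "prediction input schema '%s' does not match model schema '%s'",
      newdata$schema, object$schema))
  }
  p <- stats::predict(object$fit, newdata$values)
  stats::setNames(as.integer(as.character(p)), newdata$ids)
}

# ---- LIBSVM text-format persistence -----------------------------------------

#' Persist / load a model in the LIBSVM text format
#'
#' `write_svm_model()` serialises a trained `cytorec_svm` into the standard
#' LIBSVM model text layout (header, then one `coef idx:value ...` line per
#' support vector), interoperable with the libsvm command-line tools.
#' `read_svm_model()` parses such a file back into a `cytorec_svm` whose
#' decision function is evaluated from the stored support vectors; its
#' predictions match the original model's exactly. Only unscaled binary
#' C-classification models are supported.
#'
#' @param model A `cytorec_svm` trained with `scale = FALSE`.
#' @param path File path.
#' @param schema Schema name to record on load.
#' @return `write_svm_model()`: `path` invisibly; `read_svm_model()`: a
#'   `cytorec_svm` (with `$fit` replaced by the parsed support-vector set).
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "cytorec_svm"))
  if (isTRUE(model$scale)) {
    abort_validation("LIBSVM export supports unscaled models only")
  }
  fit <- model$fit
  SV <- fit$SV
  coefs <- as.vector(fit$coefs)
  # class values in libsvm-internal order; the decision-value sign selects
  # the first of these
  labels <- as.integer(fit$levels[fit$labels])
  con <- file(path, "w")
  on.exit(close(con))
  lines <- c(
    "svm_type c_svc",
    paste("kernel_type", if (model$kernel == "linear") "linear" else "rbf"))
  if (model$kernel == "gaussian") {
    lines <- c(lines, sprintf("gamma %.17g", fit$gamma))
  }
  lines <- c(lines,
    "nr_class 2",
    sprintf("total_sv %d", nrow(SV)),
    sprintf("rho %.17g", fit$rho),
    paste("label", paste(labels, collapse = " ")),
    paste("nr_sv", paste(fit$nSV, collapse = " ")),
    "SV")
  writeLines(lines, con)
  for (i in seq_len(nrow(SV))) {
    nz <- which(SV[i, ] != 0)
    writeLines(paste(sprintf("%.17g", coefs[i]),
                     paste(sprintf("%d:%.17g", nz, SV[i, nz]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path, schema = "custom") {
  if (!file.exists(path)) abort_parse(sprintf("model file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sv_at <- match("SV", lines)
  if (is.na(sv_at)) abort_parse(sprintf("'%s': no SV section", path))
  header <- lines[seq_len(sv_at - 1L)]
  get <- function(key) {
    hit <- grep(paste0("^", key, " "), header, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    strsplit(sub(paste0("^", key, " "), "", hit[1L]), " ")[[1L]]
  }
  kernel_type <- get("kernel_type")[1L]
  if (!(kernel_type %in% c("linear", "rbf"))) {
    abort_parse(sprintf("'%s': unsupported kernel_type '%s'", path, kernel_type))
  }
  gamma <- if (!is.null(get("gamma"))) as.numeric(get("gamma")[1L])
  rho <- as.numeric(get("rho")[1L])
  labels <- as.integer(get("label"))
  body <- lines[seq.int(sv_at + 1L, length(lines))]
  body <- body[nzchar(body)]
  coefs <- numeric(length(body))
  pairs <- vector("list", length(body))
  max_idx <- 0L
  for (i in seq_along(body)) {
    tk <- strsplit(trimws(body[[i]]), " +")[[1L]]
    coefs[i] <- as.numeric(tk[1L])
    kv <- do.call(rbind, strsplit(tk[-1L], ":", fixed = TRUE))
    pairs[[i]] <- cbind(as.integer(kv[, 1L]), as.numeric(kv[, 2L]))
    max_idx <- max(max_idx, as.integer(kv[, 1L]))
  }
  SV <- matrix(0, nrow = length(body), ncol = max_idx)
  for (i in seq_along(body)) SV[i, pairs[[i]][, 1L]] <- pairs[[i]][, 2L]
  structure(list(
    fit = NULL, kernel = if (kernel_type == "rbf") "gaussian" else "linear",
    C = NA_real_, gamma = gamma, scale = FALSE, schema = schema,
    feature_names = NULL,
    libsvm = list(SV = SV, coefs = coefs, rho = rho, labels = labels)
  ), class = "cytorec_libsvm")
}

#' @export
predict.cytorec_libsvm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values else
    as.matrix(newdata)
  m <- object$libsvm
  SV <- m$SV
  if (ncol(SV) > ncol(x)) {
    abort_schema("prediction input has fewer features than the stored model")
  }
  if (ncol(SV) < ncol(x)) {
    # sparse writer drops all-zero trailing columns; restore them
    SV <- cbind(SV, matrix(0, nrow(SV), ncol(x) - ncol(SV)))
  }
  K <- if (object$kernel == "linear") {
    x %*% t(SV)
  } else {
    d2 <- outer(rowSums(x^2), rowSums(SV^2), "+") - 2 * x %*% t(SV)
    exp(-object$gamma * pmax(d2, 0))
  }
  f <- as.vector(K %*% m$coefs) - m$rho
  labs <- ifelse(f > 0, m$labels[1L], m$labels[2L])
  stats::setNames(as.integer(labs),
                  if (inherits(newdata, "feature_matrix")) newdata$ids)
}
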