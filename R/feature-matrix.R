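#' Construct a labelled feature matrix
#'
#' The common currency of the package: an n x d numeric matrix of features,
#' one row per sequence, with unique ids, optional binary labels (+1
#' cytokine / -1 non-cytokine) and a named feature schema. When the schema
#' name is registered (see [schema_registry()]) the column names must match
#' the registered schema exactly; ad-hoc schema names are accepted for
#' user-defined tables.
#'
#' @param values n x d numeric matrix (column names are the feature names).
#' @param ids Character vector of n unique sequence ids; defaults to the
#'   matrix row names.
#' @param labels Optional integer vector in \{+1, -1\}, length n.
#' @param schema Schema name.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, ids = rownames(values), labels = NULL,
                           schema = "custom") {
  values <- as.matrix(values)
  if (!is.numeric(values) && nrow(values) > 0L) {
    abort_validation("feature values must be numeric")
  }
  if (is.null(ids)) abort_validation("feature matrix needs sequence ids")
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) {
    abort_validation(sprintf("%d ids for %d rows", length(ids), nrow(values)))
  }
  if (anyDuplicated(ids)) {
    abort_validation(sprintf("duplicate id '%s'", ids[duplicated(ids)][1L]))
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) {
      abort_validation("labels length must match row count")
    }
    if (!all(labels %in% c(-1L, 1L))) {
      abort_validation("labels must be +1 or -1")
    }
  }
  if (schema %in% schema_registry()) {
    expected <- feature_schema(schema)
    if (ncol(values) != length(expected) ||
        !identical(colnames(values), expected)) {
      abort_schema(sprintf(
        "columns do not match registered schema '%s' (%d features)",
        schema, length(expected)))
    }
  } else if (is.null(colnames(values)) && ncol(values) > 0L) {
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  }
  rownames(values) <- ids
  structure(list(ids = ids, labels = labels, values = values, schema = schema),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> schema '%s': %d sequences x %d features%s\n",
              x$schema, nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(" (%d positive / %d negative)",
                        sum(x$labels == 1L), sum(x$labels == -1L))))
  invisible(x)
}

# row subset preserving class and schema
fm_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], ids = fm$ids[idx],
                 labels = if (!is.null(fm$labels)) fm$labels[idx],
                 schema = fm$schema)
}

#' Write / read a feature table
#'
#' Tab-separated text with a schema comment line (`#schema <name>`), one
#' header row of feature names and one row per sequence carrying the id, the
#' label (`NA` when unlabelled) and the feature values. Values are written
#' with 17 significant digits so that the numeric payload round-trips
#' bit-exactly.
#'
#' On read, a registered schema name is re-validated against the header; a
#' mismatch raises a schema error.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: a `feature_matrix`.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema ", fm$schema), con)
  writeLines(paste(c("id", "label", colnames(fm$values)), collapse = "\t"), con)
  labels <- fm$labels %||% rep(NA_integer_, nrow(fm$values))
  for (i in seq_len(nrow(fm$values))) {
    writeLines(paste(c(fm$ids[i], as.character(labels[i]),
                       sprintf("%.17g", fm$values[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("feature table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[[1L]], "#schema ")) {
    abort_parse(sprintf("'%s': missing '#schema' line", path))
  }
  schema <- sub("^#schema ", "", lines[[1L]])
  header <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "id" || header[2L] != "label") {
    abort_parse(sprintf("'%s': header must start with id, label", path))
  }
  feat_names <- header[-(1:2)]
  if (schema %in% schema_registry() &&
      !identical(feat_names, feature_schema(schema))) {
    abort_schema(sprintf("'%s': header does not match registered schema '%s'",
                         path, schema))
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  n <- length(body)
  values <- matrix(NA_real_, nrow = n, ncol = length(feat_names),
                   dimnames = list(NULL, feat_names))
  ids <- character(n)
  labels <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tk <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(tk) != length(header)) {
      abort_parse(sprintf("'%s' data row %d: %d fields, expected %d",
                          path, i, length(tk), length(header)))
    }
    ids[i] <- tk[1L]
    labels[i] <- suppressWarnings(as.integer(tk[2L]))
    values[i, ] <- as.numeric(tk[-(1:2)])
  }
  feature_matrix(values, ids = ids,
                 labels = if (n > 0L && !anyNA(labels)) labels,
                 schema = schema)
}

# ---- combination recipes ----------------------------------------------------

recipe_parts <- function(recipe) {
  switch(recipe,
    sp   = c("sss18", "pseaac30"),
    pssm = c("pssm20", "pssm380"),
    psp  = c("pssm400", "sp48"),
    pspn = c("ngram420", "psp448"),
    abort_schema(sprintf("unknown recipe '%s' (use sp, pssm, psp or pspn)",
                         recipe))
  )
}

recipe_schema <- function(recipe) {
  switch(recipe, sp = "sp48", pssm = "pssm400", psp = "psp448",
         pspn = "pspn868")
}

# find (or recursively build) the part with the given schema
resolve_part <- function(schema, parts) {
  have <- vapply(parts, function(p) p$schema, character(1))
  hit <- which(have == schema)
  if (length(hit) > 0L) return(parts[[hit[1L]]])
  sub_recipe <- switch(schema, sp48 = "sp", pssm400 = "pssm",
                       psp448 = "psp", pspn868 = "pspn", NULL)
  if (is.null(sub_recipe)) {
    abort_schema(sprintf("no part with schema '%s' supplied", schema))
  }
  combine_features(parts, sub_recipe)
}

#' Combine feature matrices with a named recipe
#'
#' Horizontally concatenates per-family feature matrices into the frozen
#' combination recipes: `sp` = sss18 + pseaac30 (48-D), `pssm` = pssm20 +
#' pssm380 (400-D), `psp` = pssm400 + sp48 (448-D), `pspn` = ngram420 +
#' psp448 (868-D). Missing composite parts are built recursively from the
#' supplied primitives, so e.g. `psp` can be assembled directly from the
#' four primitive families. All parts must share the same id order; labels
#' must agree wherever present.
#'
#' @param parts List of `feature_matrix` objects.
#' @param recipe One of `"sp"`, `"pssm"`, `"psp"`, `"pspn"`.
#' @return A `feature_matrix` with the recipe's registered schema.
#' @export
combine_features <- function(parts, recipe) {
  if (inherits(parts, "feature_matrix")) parts <- list(parts)
  stopifnot(all(vapply(parts, inherits, logical(1), "feature_matrix")))
  needed <- lapply(recipe_parts(recipe), resolve_part, parts = parts)
  ids <- needed[[1L]]$ids
  labels <- NULL
  for (p in needed) {
    if (!identical(p$ids, ids)) {
      abort_alignment(sprintf(
        "parts '%s' and '%s' do not share the same id order",
        needed[[1L]]$schema, p$schema))
    }
    if (!is.null(p$labels)) {
      if (!is.null(labels) && !identical(labels, p$labels)) {
        abort_alignment("parts carry conflicting labels")
      }
      labels <- p$labels
    }
  }
  values <- do.call(cbind, lapply(needed, function(p) p$values))
  feature_matrix(values, ids = ids, labels = labels,
                 schema = recipe_schema(recipe))
}
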