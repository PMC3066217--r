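#' Expression matrix container
#'
#' The universal currency of the pipeline: a genes x samples matrix of
#' log2 expression with unique gene and sample identifiers and an optional
#' per-sample batch (cohort) label.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must
#'   carry unique, non-empty row and column names and contain only finite
#'   values (no missing intensities; imputation is out of scope).
#' @param batch Optional character vector of per-sample batch labels,
#'   either named by sample id or in column order.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix) and `batch` (character or `NULL`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, batch = c("A", "A"))
#' dim(em)
#' @export
expression_matrix <- function(values, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have gene row names and sample column names")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(head(dup, 5), collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(head(dup, 5), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", gid[bad[1]],
         "', sample '", sid[bad[2]], "'")
  }
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (!is.null(names(batch))) {
      if (!setequal(names(batch), sid))
        stop("batch names do not match sample ids")
      batch <- batch[sid]
    } else if (length(batch) != ncol(values)) {
      stop("batch must have one label per sample")
    }
    names(batch) <- sid
  }
  structure(list(values = values, batch = batch), class = "ExpressionMatrix")
}

#' Coerce to an expression matrix
#'
#' Plain matrices are accepted anywhere an `ExpressionMatrix` is; this
#' normalizes the input.
#' @param x An `ExpressionMatrix` or a numeric matrix with dimnames.
#' @param batch Optional batch labels used when `x` is a bare matrix.
#' @return An `ExpressionMatrix`.
#' @export
as_expression_matrix <- function(x, batch = NULL) {
  if (inherits(x, "ExpressionMatrix")) {
    if (!is.null(batch)) return(expression_matrix(x$values, batch))
    return(x)
  }
  expression_matrix(as.matrix(x), batch)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$batch)) {
    tb <- table(x$batch)
    cat("batches:", paste(sprintf("%s(%d)", names(tb), tb), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  b <- if (is.null(x$batch)) NULL else x$batch[colnames(v)]
  expression_matrix(v, b)
}

# internal accessors: most numeric code works on the bare matrix
em_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
}

em_batch <- function(x, batch = NULL) {
  if (!is.null(batch)) {
    b <- as.character(batch)
    if (is.null(names(b))) names(b) <- colnames(em_values(x))
    return(b)
  }
  if (inherits(x, "ExpressionMatrix")) x$batch else NULL
}
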