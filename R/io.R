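#' Read an expression matrix from GCT or TSV
#'
#' GCT is the version 1.2 dialect: a `#1.2` header line, a dimensions line
#' (`n_genes<TAB>n_samples`), then a table whose first two columns are
#' `Name` and `Description` (the description may be empty). The plain TSV
#' layout is genes in rows with a header of sample ids and gene ids in the
#' first column. Values are expected on log2 scale; set `log2_transform`
#' for raw-scale inputs.
#'
#' @param path File to read.
#' @param format `"gct"` or `"tsv"`; default guesses from the extension.
#' @param batch Optional per-sample batch labels attached to the result.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the values.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, format = c("auto", "gct", "tsv"),
                            batch = NULL, log2_transform = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3 || !grepl("^#1\\.2", lines[1]))
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
    ng <- as.integer(dims[1]); ns <- as.integer(dims[2])
    tab <- read.delim(text = lines[-(1:2)], header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) != ng)
      stop("GCT dimension mismatch in ", path, ": header declares ", ng,
           " genes but file has ", nrow(tab), " data rows")
    if (ncol(tab) - 2L != ns)
      stop("GCT dimension mismatch in ", path, ": header declares ", ns,
           " samples but file has ", ncol(tab) - 2L, " value columns")
    ids <- as.character(tab[[1]])
    vals <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- read.delim(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    vals <- tab[, -1, drop = FALSE]
  }
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad))
      stop("non-numeric value '", v[bad[1]], "' at gene '", ids[bad[1]],
           "', column '", colnames(vals)[j], "' in ", path)
    m[, j] <- num
  }
  if (log2_transform) {
    if (any(m < 0)) stop("negative values cannot be log2(x+1) transformed")
    m <- log2(m + 1)
  }
  expression_matrix(m, batch = batch)
}

#' Write an expression matrix to GCT or TSV
#'
#' @param x An [expression_matrix()] or a named numeric matrix.
#' @param path Output file.
#' @param format `"gct"` or `"tsv"` (default from the extension).
#' @param description Optional per-gene descriptions for the GCT
#'   `Description` column (defaults to empty strings).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(x, path, format = c("auto", "gct", "tsv"),
                             description = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  m <- em_values(as_expression_matrix(x))
  if (format == "gct") {
    if (is.null(description)) description <- rep("", nrow(m))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    tab <- data.frame(Name = rownames(m), Description = description,
                      m, check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

DEBULKING_LEVELS <- c("optimal", "suboptimal", "grossly_visible",
                      "no_visible", "unknown")

#' Validate a clinical table
#'
#' Checks the invariants of the per-sample clinical data: unique sample
#' ids, non-negative overall-survival months, event indicator in `{0, 1}`
#' and categorical covariates in their allowed levels. Missing covariates
#' are retained as `NA`; only `sample_id`, `os_months` and `event` are
#' mandatory.
#'
#' @param df A data frame with at least `sample_id`, `os_months`, `event`;
#'   optional columns `age_years`, `stage` (1-4), `grade` (1-3),
#'   `debulking`, `histology`, `subtype`, `response`.
#' @return The validated data frame (classes coerced).
#' @export
clinical_table <- function(df) {
  req <- c("sample_id", "os_months", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table lacks required column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  df$os_months <- as.numeric(df$os_months)
  if (any(is.na(df$os_months))) stop("os_months must be numeric, no missing")
  if (any(df$os_months < 0)) {
    bad <- df$sample_id[df$os_months < 0][1]
    stop("negative os_months for sample '", bad, "'")
  }
  df$event <- as.numeric(df$event)
  if (any(is.na(df$event)) || !all(df$event %in% c(0, 1))) {
    stop("event must be 0 or 1 for every sample")
  }
  num_na <- function(v) suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  if ("age_years" %in% names(df)) df$age_years <- num_na(df$age_years)
  for (col in c("stage", "grade")) {
    if (col %in% names(df)) {
      df[[col]] <- num_na(df[[col]])
      lim <- if (col == "stage") 1:4 else 1:3
      ok <- is.na(df[[col]]) | df[[col]] %in% lim
      if (!all(ok)) stop(col, " outside allowed values ",
                         paste(range(lim), collapse = "-"))
    }
  }
  if ("debulking" %in% names(df)) {
    v <- as.character(df$debulking)
    v[is.na(v) | v == ""] <- "unknown"
    if (!all(v %in% DEBULKING_LEVELS))
      stop("debulking outside allowed levels: ",
           paste(setdiff(v, DEBULKING_LEVELS), collapse = ", "))
    df$debulking <- v
  }
  for (col in c("histology", "subtype", "response")) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      v[v == ""] <- NA
      df[[col]] <- v
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a clinical table from CSV/TSV
#'
#' @param path CSV (default) or TSV file; the header must include
#'   `sample_id`, `os_months` and `event`.
#' @param sep Field separator; `","` or `"\t"`.
#' @return A validated clinical data frame (see [clinical_table()]).
#' @export
load_clinical <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  clinical_table(df)
}

#' Write a clinical table to CSV
#' @param df Clinical data frame.
#' @param path Output file.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
write_clinical <- function(df, path, sep = ",") {
  write.table(clinical_table(df), path, sep = sep, quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`; every
#' set must contain at least one gene and set names must be unique.
#'
#' @param path GMT file.
#' @return A named list of character vectors with a `description`
#'   attribute per set (class `GeneSetCollection`).
#' @export
load_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) stop("duplicate gene set name(s): ",
                        paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("gene set '", p[1], "' contains no genes")
    genes
  })
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else "", ""), nm)
  class(sets) <- c("GeneSetCollection", "list")
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene id map
#'
#' Two-column TSV (`source`, `target`), many-to-one allowed: several
#' probes may map to one gene, but a probe mapped to two different genes
#' is an error.
#'
#' @param path TSV file with a header.
#' @return Named character vector: `map[source] == target`.
#' @export
load_id_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("id map needs source and target columns")
  src <- as.character(tab[[1]]); tgt <- as.character(tab[[2]])
  amb <- tapply(tgt, src, function(v) length(unique(v)))
  bad <- names(amb)[amb > 1]
  if (length(bad))
    stop("source id(s) mapped to multiple targets: ",
         paste(head(bad, 5), collapse = ", "))
  keep <- !duplicated(src)
  setNames(tgt[keep], src[keep])
}

#' Read a two-class CLS label file
#'
#' The three-line categorical CLS dialect: counts line
#' (`n n_classes 1`), a `#`-prefixed class-name line, then space-separated
#' labels (numeric codes or names).
#'
#' @param path CLS file.
#' @return Character vector of class labels, one per sample.
#' @export
load_cls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("CLS file must have 3 lines")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  cls_names <- strsplit(trimws(sub("^#\\s*", "", lines[2])), "\\s+")[[1]]
  labs <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  if (length(labs) != hdr[1])
    stop("CLS declares ", hdr[1], " samples but has ", length(labs),
         " labels")
  if (all(grepl("^[0-9]+$", labs))) {
    idx <- as.integer(labs)
    # numeric codes index class names in order of first appearance
    labs <- cls_names[match(idx, unique(idx))]
  }
  if (length(unique(labs)) != hdr[2])
    stop("CLS declares ", hdr[2], " classes but labels have ",
         length(unique(labs)))
  labs
}

#' Write class labels to a CLS file
#' @param labels Character vector of class labels.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_cls <- function(labels, path) {
  labels <- as.character(labels)
  u <- unique(labels)
  writeLines(c(paste(length(labels), length(u), 1),
               paste("#", paste(u, collapse = " ")),
               paste(match(labels, u) - 1L, collapse = " ")), path)
  invisible(path)
}
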