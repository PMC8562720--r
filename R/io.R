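#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene IDs and
#' whose header row holds sample IDs; the body must be fully numeric.
#' Malformed input is rejected, never coerced.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 2L) {
    stop("read_expression: need a gene-ID column plus at least one sample",
         call. = FALSE)
  }
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("read_expression: duplicate gene ID(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  body <- raw[, -1, drop = FALSE]
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad)) {
    stop("read_expression: non-numeric column(s): ",
         paste(names(body)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    coords <- apply(utils::head(miss, 5), 1L, function(rc) {
      paste0(ids[rc[1]], "/", colnames(m)[rc[2]])
    })
    stop("read_expression: missing value(s) at ",
         paste(coords, collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `gene`, one column per
#' sample.
#'
#' @param expr genes x samples matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival table from TSV
#'
#' Requires columns `sample_id`, `time` (> 0) and `event` (0/1); any
#' further columns are kept as covariates.
#'
#' @param path file path.
#' @param expr optional expression matrix; samples absent from it trigger
#'   a warning listing them.
#' @return validated data.frame.
#' @export
read_clinical <- function(path, expr = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_clinical: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time <= 0)) {
    stop("read_clinical: 'time' must be numeric and > 0", call. = FALSE)
  }
  if (anyNA(df$event) || !all(df$event %in% c(0, 1))) {
    stop("read_clinical: 'event' must be 0 or 1", call. = FALSE)
  }
  if (!is.null(expr)) {
    absent <- setdiff(df$sample_id, colnames(expr))
    if (length(absent)) {
      warning("read_clinical: sample(s) absent from the expression ",
              "matrix: ", paste(utils::head(absent, 5), collapse = ", "),
              call. = FALSE)
    }
  }
  df
}

#' Read a gene biotype table
#'
#' Two-column TSV (`gene`, `biotype`). Conflicting duplicate entries are
#' an error; consistent duplicates are collapsed.
#'
#' @param path file path.
#' @return data.frame with columns `gene` and `biotype`.
#' @export
read_biotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) {
    stop("read_biotypes: need gene and biotype columns", call. = FALSE)
  }
  names(df)[1:2] <- c("gene", "biotype")
  df <- unique(df[, c("gene", "biotype")])
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup)) {
    stop("read_biotypes: conflicting biotypes for gene(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' lncRNA universe from a biotype table
#'
#' @param biotypes data.frame from [read_biotypes()].
#' @return character vector of gene IDs annotated as `"lncRNA"`.
#' @export
lncrna_filter <- function(biotypes) {
  if (!all(c("gene", "biotype") %in% names(biotypes))) {
    stop("lncrna_filter: need columns gene and biotype", call. = FALSE)
  }
  biotypes$gene[biotypes$biotype == "lncRNA"]
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene IDs. Blank lines are skipped; duplicate genes
#' within a set are deduplicated with a warning; an empty set is an error.
#'
#' @param path file path.
#' @return named list of `"gene_set"` objects (`name`, `description`,
#'   `genes`).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_gene_sets: empty GMT file", call. = FALSE)
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || !length(genes)) {
      stop("read_gene_sets: set '", f[1], "' has no genes", call. = FALSE)
    }
    if (anyDuplicated(genes)) {
      warning("read_gene_sets: set '", f[1], "' contains duplicate genes; ",
              "deduplicated to ", length(unique(genes)), call. = FALSE)
      genes <- unique(genes)
    }
    structure(list(name = f[1], description = f[2], genes = genes),
              class = "gene_set")
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write a screen result as a parameter-annotated TSV
#'
#' Writes one row per gene, preceded by `#`-prefixed header lines echoing
#' the screen parameters, so the file is self-describing.
#'
#' @param result a `"screen_result"` from [run_screen()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(result, path) {
  params <- attr(result, "params")
  con <- file(path, "w")
  on.exit(close(con))
  for (p in names(params)) {
    writeLines(sprintf("# %s=%s", p, format(params[[p]])), con)
  }
  utils::write.table(as.data.frame(result), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
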