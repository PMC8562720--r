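#' Tumor-microenvironment summary score of a gene set
#'
#' Per-sample summary of a signature (e.g. hypoxia or cancer-associated
#' fibroblast gene lists): the median of the absolute expression values of
#' the signature genes present in the matrix. On nonnegative log
#' intensities the absolute value is the identity; it matters only for
#' signed (e.g. centered) inputs.
#'
#' @param expr genes x samples expression matrix.
#' @param gene_set a `"gene_set"` (see [read_gene_sets()]) or a list with
#'   `name` and `genes`.
#' @return named numeric vector of per-sample scores.
#' @export
summary_score <- function(expr, gene_set) {
  genes <- unique(gene_set$genes)
  if (!length(genes)) {
    stop("summary_score: empty gene set", call. = FALSE)
  }
  present <- intersect(genes, rownames(expr))
  absent <- setdiff(genes, present)
  if (!length(present)) {
    stop("summary_score: no gene of set '", gene_set$name,
         "' is present in the expression matrix", call. = FALSE)
  }
  if (length(absent)) {
    warning("summary_score: dropping ", length(absent),
            " absent gene(s) from set '", gene_set$name, "'",
            call. = FALSE)
  }
  apply(abs(expr[present, , drop = FALSE]), 2L, stats::median)
}

#' Compare a continuous variable between high and low risk groups
#'
#' Welch two-sample t-test of a per-sample value between the two risk
#' groups, as used to relate tumor-microenvironment scores to risk
#' strata.
#'
#' @param values named numeric vector (names = sample IDs) or a vector
#'   aligned with `groups`.
#' @param groups per-sample group labels with exactly two levels
#'   (e.g. "high"/"low").
#' @return list: `variable`, `test`, `statistic`, `p_value`, and
#'   `summary` (per-group n, mean, sd).
#' @export
associate_continuous <- function(values, groups) {
  if (!is.null(names(values)) && !is.null(names(groups))) {
    groups <- groups[names(values)]
  }
  g <- as.character(groups)
  lev <- sort(unique(g))
  if (length(lev) != 2L || min(table(g)) < 2L) {
    stop("associate_continuous: need two groups with >= 2 samples each",
         call. = FALSE)
  }
  x <- values[g == lev[1]]
  y <- values[g == lev[2]]
  p <- welch_p(x, y)
  stat <- tryCatch(unname(stats::t.test(x, y)$statistic),
                   error = function(e) 0)
  list(
    variable = deparse(substitute(values))[1],
    test = "welch_t",
    statistic = stat,
    p_value = p,
    summary = data.frame(group = lev,
                         n = c(length(x), length(y)),
                         mean = c(mean(x), mean(y)),
                         sd = c(stats::sd(x), stats::sd(y)),
                         stringsAsFactors = FALSE)
  )
}

#' Association of a binary label with high/low risk groups
#'
#' Fisher's exact test (two-sided) on the 2x2 contingency table of a
#' binary per-sample label (e.g. mutation present) against the risk
#' groups; Pearson's chi-square statistic is reported alongside when all
#' expected counts are at least 5.
#'
#' @param labels per-sample binary labels (2 levels).
#' @param groups per-sample group labels (2 levels).
#' @return list: `test`, `table` (2x2 counts), `p_value` (Fisher),
#'   `odds_ratio`, and `chisq` (statistic + p, or NULL when expected
#'   counts are too small).
#' @export
associate_categorical <- function(labels, groups) {
  if (!is.null(names(labels)) && !is.null(names(groups))) {
    groups <- groups[names(labels)]
  }
  l <- if (is.factor(labels)) labels else factor(labels)
  g <- if (is.factor(groups)) groups else factor(groups)
  tab <- table(l, g)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("associate_categorical: need a 2x2 table (two label levels, two ",
         "groups)", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("associate_categorical: a margin of the 2x2 table is zero",
            call. = FALSE)
    return(list(test = "fisher_exact", table = tab, p_value = 1,
                odds_ratio = NA_real_, chisq = NULL))
  }
  ft <- stats::fisher.test(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- NULL
  if (all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chisq <- list(statistic = unname(ct$statistic),
                  p_value = ct$p.value)
  }
  list(test = "fisher_exact", table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate), chisq = chisq)
}
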