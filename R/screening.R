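#' Per-cell-type mean expression profile
#'
#' Averages an immune reference panel within cell types, producing the
#' gene x cell-type profile on which decile ranking and the tissue
#' specificity index operate.
#'
#' @param panel genes x samples expression matrix (rownames = gene IDs,
#'   colnames = sample IDs).
#' @param labels data.frame with columns `sample_id` and `cell_type`
#'   covering every column of `panel`.
#' @return An object of class `"cell_type_profile"`: list with `genes`,
#'   `cell_types`, and `means` (gene x cell-type matrix).
#' @export
#' @examples
#' m <- matrix(c(2, 4, 1, 3), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' lab <- data.frame(sample_id = paste0("s", 1:4),
#'                   cell_type = c("A", "A", "B", "B"))
#' cell_type_means(m, lab)$means
cell_type_means <- function(panel, labels) {
  if (!is.matrix(panel) || is.null(rownames(panel)) ||
      is.null(colnames(panel))) {
    stop("cell_type_means: 'panel' must be a matrix with gene rownames and ",
         "sample colnames", call. = FALSE)
  }
  if (!is.data.frame(labels) ||
      !all(c("sample_id", "cell_type") %in% names(labels))) {
    stop("cell_type_means: 'labels' needs columns sample_id and cell_type",
         call. = FALSE)
  }
  idx <- match(colnames(panel), labels$sample_id)
  if (anyNA(idx)) {
    stop("cell_type_means: unlabeled sample(s): ",
         paste(colnames(panel)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  type <- labels$cell_type[idx]
  types <- unique(type)
  if (any(!nzchar(type)) || anyNA(type)) {
    stop("cell_type_means: empty cell-type label", call. = FALSE)
  }
  means <- matrix(
    vapply(types, function(ct) {
      rowMeans(panel[, type == ct, drop = FALSE])
    }, numeric(nrow(panel))),
    nrow = nrow(panel), ncol = length(types),
    dimnames = list(rownames(panel), types))
  structure(list(genes = rownames(panel), cell_types = types, means = means),
            class = "cell_type_profile")
}

#' Top-decile candidate lncRNAs per cell type
#'
#' For each cell type, selects the `ceiling(top_fraction * G)` genes with
#' the highest mean expression; genes tied with the cutoff value are all
#' included. The union over cell types is the candidate set passed on to
#' TSI filtering.
#'
#' @param profile a [cell_type_means()] profile.
#' @param top_fraction fraction of genes kept per type (default 0.10).
#' @return list with `per_type` (named list of gene-ID vectors) and
#'   `candidates` (their union, in gene-universe order).
#' @export
top_decile_candidates <- function(profile, top_fraction = 0.10) {
  stopifnot(inherits(profile, "cell_type_profile"))
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction >= 1) {
    stop("top_decile_candidates: top_fraction must be in (0, 1)",
         call. = FALSE)
  }
  G <- length(profile$genes)
  if (G == 0L) stop("top_decile_candidates: empty profile", call. = FALSE)
  k <- ceiling(top_fraction * G)
  per_type <- lapply(profile$cell_types, function(ct) {
    v <- profile$means[, ct]
    cutoff <- sort(v, decreasing = TRUE)[k]
    profile$genes[v >= cutoff]
  })
  names(per_type) <- profile$cell_types
  candidates <- profile$genes[profile$genes %in% unique(unlist(per_type))]
  list(per_type = per_type, candidates = candidates)
}

#' Tissue specificity index (TSI)
#'
#' For each gene, per-type means are normalized by their maximum,
#' `x_i = mean_i / max_j mean_j`, and the index is
#' `TSI = sum(1 - x_i) / (N - 1)` over the `N` cell types. TSI is 0 for a
#' gene expressed uniformly across all types and 1 for a gene expressed in
#' exactly one type.
#'
#' @param profile a [cell_type_means()] profile (nonnegative means,
#'   N >= 2 cell types).
#' @param genes optional gene subset to score (default: all).
#' @return An object of class `"tsi_table"`: list with `tsi` (named
#'   numeric in \[0,1\]), `x` (max-normalized gene x type matrix), and
#'   `dropped` (genes whose means are all zero, excluded with a message).
#' @export
#' @examples
#' m <- matrix(c(4, 2, 0), 1, 3, dimnames = list("g1", c("A", "B", "C")))
#' prof <- structure(list(genes = "g1", cell_types = c("A", "B", "C"),
#'                        means = m), class = "cell_type_profile")
#' compute_tsi(prof)$tsi  # (0 + 0.5 + 1) / 2 = 0.75
compute_tsi <- function(profile, genes = NULL) {
  stopifnot(inherits(profile, "cell_type_profile"))
  N <- length(profile$cell_types)
  if (N < 2L) stop("compute_tsi: need at least 2 cell types", call. = FALSE)
  m <- profile$means
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop("compute_tsi: genes absent from profile: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    m <- m[genes, , drop = FALSE]
  }
  if (any(m < 0)) {
    stop("compute_tsi: negative mean expression", call. = FALSE)
  }
  mx <- apply(m, 1L, max)
  dropped <- rownames(m)[mx == 0]
  if (length(dropped)) {
    message("compute_tsi: excluding ", length(dropped),
            " gene(s) with all-zero means")
  }
  keep <- mx > 0
  x <- m[keep, , drop = FALSE] / mx[keep]
  tsi <- rowSums(1 - x) / (N - 1)
  structure(list(tsi = tsi, x = x, dropped = dropped), class = "tsi_table")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR; a validating wrapper
#' around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return adjusted values, each in `[p, 1]`.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("bh_adjust: p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# Welch two-sample test robust to degenerate (zero-variance) inputs:
# equal constants on both sides give p = 1, different constants p = 0.
welch_p <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value,
           error = function(e) {
             if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
           })
}

#' Immune-versus-tumor differential screen
#'
#' Welch two-sample tests comparing each candidate gene's expression
#' across all pooled immune samples against the tumor cell lines, with
#' Benjamini-Hochberg FDR over the candidate set. A gene is flagged as a
#' tumor-infiltrating immune-related lncRNA (Ti-lncRNA) when its FDR is
#' below `fdr_threshold` (strict) and its immune mean exceeds its tumor
#' mean.
#'
#' @param immune genes x samples immune expression matrix.
#' @param tumor genes x lines tumor expression matrix (same gene
#'   universe).
#' @param candidates gene IDs to test.
#' @param fdr_threshold FDR cutoff (default 0.05, strict inequality).
#' @return data.frame with columns `gene`, `mean_immune`, `mean_tumor`,
#'   `diff`, `p_value`, `fdr`, `is_ti_lncrna`.
#' @export
differential_screen <- function(immune, tumor, candidates,
                                fdr_threshold = 0.05) {
  if (ncol(immune) < 2L || ncol(tumor) < 2L) {
    stop("differential_screen: need at least 2 samples on each side",
         call. = FALSE)
  }
  missing <- setdiff(candidates, intersect(rownames(immune), rownames(tumor)))
  if (length(missing)) {
    stop("differential_screen: candidates absent from a matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  mi <- rowMeans(immune[candidates, , drop = FALSE])
  mt <- rowMeans(tumor[candidates, , drop = FALSE])
  p <- vapply(candidates, function(g) {
    welch_p(immune[g, ], tumor[g, ])
  }, numeric(1))
  fdr <- bh_adjust(p)
  data.frame(
    gene = candidates,
    mean_immune = unname(mi),
    mean_tumor = unname(mt),
    diff = unname(mi - mt),
    p_value = unname(p),
    fdr = unname(fdr),
    is_ti_lncrna = unname(fdr < fdr_threshold & mi > mt),
    stringsAsFactors = FALSE
  )
}

#' Run the full Ti-lncRNA screen
#'
#' Orchestrates the three screening stages: (1) per-cell-type averaging
#' and top-decile candidate selection, (2) tissue-specificity filtering at
#' `tsi > tsi_threshold` (strict), and (3) the immune-versus-tumor
#' differential screen at `fdr < fdr_threshold` (strict) with the
#' direction filter `mean_immune > mean_tumor`. An optional biotype table
#' restricts the universe to lncRNAs first.
#'
#' @param immune genes x samples immune expression matrix.
#' @param labels sample -> cell-type data.frame (see [cell_type_means()]).
#' @param tumor genes x lines tumor expression matrix.
#' @param biotypes optional data.frame (`gene`, `biotype`); only genes
#'   with biotype `"lncRNA"` are screened.
#' @param top_fraction per-type candidate fraction (default 0.10).
#' @param tsi_threshold TSI cutoff (default 0.1).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return A `"screen_result"` data.frame with one row per screened gene:
#'   `gene`, `in_top_decile`, `tsi`, `mean_immune`, `mean_tumor`, `diff`,
#'   `p_value`, `fdr`, `is_ti_lncrna`; screen parameters are attached as
#'   the `"params"` attribute. Genes eliminated before the differential
#'   stage carry `NA` statistics and `is_ti_lncrna = FALSE`.
#' @export
run_screen <- function(immune, labels, tumor, biotypes = NULL,
                       top_fraction = 0.10, tsi_threshold = 0.1,
                       fdr_threshold = 0.05) {
  if (!setequal(rownames(immune), rownames(tumor))) {
    stop("run_screen: immune and tumor matrices must share one gene ",
         "universe", call. = FALSE)
  }
  universe <- rownames(immune)
  if (!is.null(biotypes)) {
    lnc <- lncrna_filter(biotypes)
    universe <- intersect(universe, lnc)
    if (!length(universe)) {
      stop("run_screen: no lncRNA genes left after the biotype filter",
           call. = FALSE)
    }
    immune <- immune[universe, , drop = FALSE]
    tumor <- tumor[universe, , drop = FALSE]
  }

  profile <- cell_type_means(immune, labels)
  deciles <- top_decile_candidates(profile, top_fraction)
  in_top <- universe %in% deciles$candidates

  result <- data.frame(
    gene = universe,
    in_top_decile = in_top,
    tsi = NA_real_,
    mean_immune = NA_real_,
    mean_tumor = NA_real_,
    diff = NA_real_,
    p_value = NA_real_,
    fdr = NA_real_,
    is_ti_lncrna = FALSE,
    stringsAsFactors = FALSE
  )
  params <- list(top_fraction = top_fraction, tsi_threshold = tsi_threshold,
                 fdr_threshold = fdr_threshold)

  finish <- function(res, empty_after) {
    if (!is.null(empty_after)) {
      warning("run_screen: empty candidate set after ", empty_after,
              " stage", call. = FALSE)
      attr(res, "empty_after") <- empty_after
    }
    attr(res, "params") <- params
    class(res) <- c("screen_result", class(res))
    res
  }

  if (!length(deciles$candidates)) return(finish(result, "top-decile"))

  tsi_tab <- compute_tsi(profile, deciles$candidates)
  result$tsi[match(names(tsi_tab$tsi), universe)] <- tsi_tab$tsi
  specific <- names(tsi_tab$tsi)[tsi_tab$tsi > tsi_threshold]
  if (!length(specific)) return(finish(result, "TSI"))

  diff_tab <- differential_screen(immune, tumor, specific, fdr_threshold)
  i <- match(diff_tab$gene, universe)
  result$mean_immune[i] <- diff_tab$mean_immune
  result$mean_tumor[i] <- diff_tab$mean_tumor
  result$diff[i] <- diff_tab$diff
  result$p_value[i] <- diff_tab$p_value
  result$fdr[i] <- diff_tab$fdr
  result$is_ti_lncrna[i] <- diff_tab$is_ti_lncrna
  finish(result, NULL)
}
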