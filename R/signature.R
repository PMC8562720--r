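#' The published nine-lncRNA prognostic signature
#'
#' Returns the packaged head and neck squamous cell carcinoma risk model:
#' nine tumor-infiltrating immune-related lncRNAs with their multivariate
#' Cox regression coefficients, in the published order. The risk score of
#' a sample is the linear combination of its expression values weighted by
#' these coefficients (see [risk_score()]).
#'
#' @return A `"signature_model"` data.frame with columns `gene` and
#'   `weight` (nine rows); attribute `provenance = "published"`.
#' @export
#' @examples
#' published_signature()
published_signature <- function() {
  model <- data.frame(
    gene = c("ENSG00000265148", "ENSG00000281358", "ENSG00000262089",
             "ENSG00000240889", "ENSG00000253230", "ENSG00000261888",
             "ENSG00000235304", "ENSG00000226806", "ENSG00000260244"),
    weight = c(-0.724, -1.047, -0.159, -0.887, 2.137, -0.656, -0.556,
               -1.257, -0.195),
    stringsAsFactors = FALSE
  )
  structure(model, provenance = "published",
            class = c("signature_model", "data.frame"))
}

new_signature_model <- function(gene, weight, provenance) {
  if (anyDuplicated(gene)) {
    stop("signature model: duplicate gene IDs", call. = FALSE)
  }
  if (any(!is.finite(weight))) {
    stop("signature model: non-finite weights", call. = FALSE)
  }
  structure(data.frame(gene = gene, weight = weight,
                       stringsAsFactors = FALSE),
            provenance = provenance,
            class = c("signature_model", "data.frame"))
}

#' Linear risk score of a signature model
#'
#' `score(s) = sum_g weight_g * expr(g, s)`. All signature genes must be
#' present in the matrix; missing genes are an error, never a silent
#' zero-fill.
#'
#' @param expr genes x samples expression matrix.
#' @param model a `"signature_model"` (e.g. [published_signature()] or the
#'   output of [build_signature()]).
#' @return named numeric vector of per-sample scores.
#' @export
#' @examples
#' expr <- matrix(0, 9, 1,
#'                dimnames = list(published_signature()$gene, "s1"))
#' expr["ENSG00000253230", 1] <- 1
#' risk_score(expr, published_signature())  # 2.137
risk_score <- function(expr, model) {
  stopifnot(inherits(model, "signature_model"))
  if (!is.matrix(expr) || is.null(rownames(expr))) {
    stop("risk_score: 'expr' must be a matrix with gene rownames",
         call. = FALSE)
  }
  absent <- setdiff(model$gene, rownames(expr))
  if (length(absent)) {
    stop("risk_score: signature gene(s) absent from expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  stats::setNames(
    as.numeric(crossprod(expr[model$gene, , drop = FALSE], model$weight)),
    colnames(expr))
}

#' Median dichotomization of risk scores
#'
#' Splits samples at the sample median of the score: scores strictly above
#' the median are "high", scores at or below it are "low" (ties at the
#' threshold go to "low").
#'
#' @param scores named numeric vector of risk scores (>= 2 samples).
#' @return data.frame with columns `sample_id`, `score`, `group`
#'   (factor low/high); the threshold is attached as attribute
#'   `"threshold"`.
#' @export
dichotomize_median <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 2L) {
    stop("dichotomize_median: need at least 2 scores", call. = FALSE)
  }
  threshold <- stats::median(scores)
  group <- factor(ifelse(scores > threshold, "high", "low"),
                  levels = c("low", "high"))
  if (all(group == "low")) {
    warning("dichotomize_median: degenerate scores, all samples assigned ",
            "to the low group", call. = FALSE)
  }
  ids <- if (is.null(names(scores))) {
    as.character(seq_along(scores))
  } else {
    names(scores)
  }
  out <- data.frame(sample_id = ids, score = unname(scores),
                    group = group, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

align_survival <- function(survival, sample_ids) {
  if (!is.data.frame(survival) ||
      !all(c("sample_id", "time", "event") %in% names(survival))) {
    stop("survival table needs columns sample_id, time, event",
         call. = FALSE)
  }
  if (any(survival$time <= 0) || !all(survival$event %in% c(0, 1))) {
    stop("survival table: time must be > 0 and event in {0, 1}",
         call. = FALSE)
  }
  idx <- match(sample_ids, survival$sample_id)
  if (anyNA(idx)) {
    stop("survival records missing for sample(s): ",
         paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  survival[idx, , drop = FALSE]
}

#' Cox proportional-hazards fits for expression terms
#'
#' Fits Cox models (Efron tie handling, via [survival::coxph()]) of
#' survival on gene expression or other covariates: either one univariate
#' fit per term or a single joint multivariate fit.
#'
#' @param expr genes x samples expression matrix (terms are rows), or a
#'   samples x covariates numeric matrix/data.frame when
#'   `terms_are_rows = FALSE`.
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param terms character vector of terms to fit (default: all).
#' @param type `"univariate"` (one fit per term) or `"multivariate"`
#'   (one joint fit).
#' @param terms_are_rows whether terms index rows of `expr` (default TRUE,
#'   the expression-matrix orientation).
#' @return data.frame with one row per term: `term`, `coef`,
#'   `hazard_ratio`, `ci_low`, `ci_high` (95% Wald, hazard-ratio scale),
#'   `p_value`, `n`, `n_events`, and `converged`.
#' @export
fit_cox <- function(expr, survival, terms = NULL,
                    type = c("univariate", "multivariate"),
                    terms_are_rows = TRUE) {
  type <- match.arg(type)
  x <- if (terms_are_rows) t(expr) else as.matrix(expr)
  if (is.null(terms)) terms <- colnames(x)
  missing <- setdiff(terms, colnames(x))
  if (length(missing)) {
    stop("fit_cox: unknown term(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  surv <- align_survival(survival, rownames(x))
  if (sum(surv$event) < 2L) {
    stop("fit_cox: need at least 2 events", call. = FALSE)
  }
  const <- terms[apply(x[, terms, drop = FALSE], 2L, stats::sd) == 0]
  if (length(const)) {
    stop("fit_cox: constant covariate(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  y <- survival::Surv(surv$time, surv$event)

  one_fit <- function(cols) {
    dat <- as.data.frame(x[, cols, drop = FALSE])
    safe <- make.names(cols)
    names(dat) <- safe
    fit <- tryCatch(
      survival::coxph(stats::as.formula(paste("y ~", paste(safe, collapse = "+"))),
                      data = dat, ties = "efron"),
      warning = function(w) {
        f <- suppressWarnings(
          survival::coxph(stats::as.formula(
            paste("y ~", paste(safe, collapse = "+"))), data = dat,
            ties = "efron"))
        attr(f, "tilnc_flag") <- conditionMessage(w)
        f
      })
    s <- summary(fit)
    data.frame(
      term = cols,
      coef = unname(s$coefficients[, "coef"]),
      hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
      ci_low = unname(s$conf.int[, "lower .95"]),
      ci_high = unname(s$conf.int[, "upper .95"]),
      p_value = unname(s$coefficients[, "Pr(>|z|)"]),
      n = s$n,
      n_events = s$nevent,
      converged = is.null(attr(fit, "tilnc_flag")),
      stringsAsFactors = FALSE
    )
  }

  if (type == "univariate") {
    out <- do.call(rbind, lapply(terms, one_fit))
  } else {
    out <- one_fit(terms)
  }
  rownames(out) <- NULL
  out
}

#' Build a prognostic signature from screened Ti-lncRNAs
#'
#' Two-stage survival selection: a univariate Cox screen keeps genes with
#' Wald p strictly below `uni_p`; one multivariate Cox fit over the
#' survivors then supplies the signature weights.
#'
#' @param expr genes x samples expression matrix.
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param ti_lncrnas character vector of candidate gene IDs.
#' @param uni_p univariate p-value cutoff (default 0.01, strict).
#' @return A `"signature_model"` (provenance `"fitted"`) with the
#'   univariate screen attached as attribute `"univariate"`; when no gene
#'   survives the screen, a zero-row model with attribute
#'   `status = "no_signature"` and a warning.
#' @export
build_signature <- function(expr, survival, ti_lncrnas, uni_p = 0.01) {
  if (!length(ti_lncrnas)) {
    stop("build_signature: empty candidate set", call. = FALSE)
  }
  uni <- fit_cox(expr, survival, terms = ti_lncrnas, type = "univariate")
  keep <- uni$term[uni$p_value < uni_p]
  if (!length(keep)) {
    warning("build_signature: no gene passed the univariate screen at p < ",
            uni_p, call. = FALSE)
    out <- new_signature_model(character(0), numeric(0), "fitted")
    attr(out, "status") <- "no_signature"
    attr(out, "univariate") <- uni
    return(out)
  }
  multi <- fit_cox(expr, survival, terms = keep, type = "multivariate")
  out <- new_signature_model(multi$term, multi$coef, "fitted")
  attr(out, "univariate") <- uni
  attr(out, "multivariate") <- multi
  out
}

#' Random train/test split of samples
#'
#' Disjoint, exhaustive split with `floor(fraction * n)` training samples;
#' a pure function of the seed.
#'
#' @param samples character vector of sample IDs.
#' @param fraction training fraction in (0, 1) (default 0.6).
#' @param seed integer seed.
#' @return list with `train` and `test` ID vectors.
#' @export
random_split <- function(samples, fraction = 0.6, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("random_split: fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- floor(fraction * length(samples))
  train <- with_local_seed(seed, sample(samples, n_train))
  list(train = train, test = setdiff(samples, train))
}
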