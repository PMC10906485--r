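#' Enumerate all predictor subsets
#'
#' Returns every subset of the predictor names, including the empty
#' (intercept-only) model, in a deterministic order: by subset size, then
#' lexicographically. Categorical predictors are treated as atomic names; a
#' factor enters a model with its whole treatment-coded block or not at all.
#'
#' @param predictors character vector of predictor names (at most 16).
#' @return list of character vectors; the first element is `character(0)`.
#' @export
all_subsets <- function(predictors) {
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors)) {
    stop("duplicate predictor names: ",
         paste(unique(predictors[duplicated(predictors)]), collapse = ", "))
  }
  m <- length(predictors)
  if (m > 16L) stop("at most 16 predictors supported")
  sorted <- sort(predictors)
  out <- list(character(0))
  for (size in seq_len(m)) {
    combs <- utils::combn(sorted, size, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

# Build a treatment-coded model matrix for one predictor subset.
subset_design <- function(data, subset) {
  n <- nrow(data)
  if (length(subset) == 0L) {
    X <- matrix(1, n, 1, dimnames = list(rownames(data), "(Intercept)"))
    return(X)
  }
  fml <- stats::as.formula(paste("~", paste(subset, collapse = " + ")))
  X <- stats::model.matrix(fml, data = data)
  rownames(X) <- rownames(data)
  X
}

#' Fit every subset model by PGLS
#'
#' Fits `response ~ subset` by [fit_gls()] under `C` for each subset in
#' `subsets` (default: [all_subsets()] of the columns of `data`). Factor
#' columns enter as whole treatment-coded blocks.
#'
#' @param response named numeric vector, taxon-aligned with `C`.
#' @param data data.frame of predictor columns (numeric or factor), rows
#'   taxon-aligned with `C`.
#' @param C phylogenetic covariance matrix.
#' @param subsets optional list of character subsets of `names(data)`.
#' @return list of `gls_fit` objects, each with a `$subset` element.
#' @export
fit_subsets <- function(response, data, C, subsets = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(subsets)) subsets <- all_subsets(names(data))
  lapply(subsets, function(s) {
    fit <- fit_gls(subset_design(data, s), response, C)
    fit$subset <- s
    fit
  })
}

#' Rank models by AIC and compute Akaike weights
#'
#' For each fitted model i: `delta_i = AIC_i - min(AIC)`, relative
#' likelihood `l_i = exp(-delta_i / 2)`, and Akaike weight
#' `w_i = l_i / sum_j l_j` (the probability that model i is the best in the
#' set). Rows are sorted by ascending AIC.
#'
#' @param fits list of `gls_fit` objects (as from [fit_subsets()]); all must
#'   be fits of the same response under the same covariance.
#' @return a `model_table` data.frame with columns `model`, `k`, `loglik`,
#'   `aic`, `delta`, `rel_likelihood`, `weight`.
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0L) stop("empty model list")
  label <- vapply(fits, function(f) {
    s <- f$subset
    if (is.null(s) || length(s) == 0L) "(intercept only)"
    else paste(s, collapse = " + ")
  }, character(1))
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  loglik <- vapply(fits, function(f) f$loglik, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  delta <- aic - min(aic)
  rel <- exp(-delta / 2)
  w <- rel / sum(rel)
  tab <- data.frame(model = label, k = k, loglik = loglik, aic = aic,
                    delta = delta, rel_likelihood = rel, weight = w,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic, tab$model), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' @export
print.model_table <- function(x, ...) {
  cat(sprintf("Model selection table (%d models)\n", nrow(x)))
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 3)
  df$aic <- round(df$aic, 2)
  df$delta <- round(df$delta, 2)
  df$rel_likelihood <- round(df$rel_likelihood, 4)
  df$weight <- round(df$weight, 4)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("... and %d more models\n", nrow(df) - 10L))
  invisible(x)
}

# Cramer's V for two categorical vectors.
cramers_v <- function(x, y) {
  tab <- table(x, y)
  if (min(dim(tab)) < 2L) return(NA_real_)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1L)))
}

# Correlation ratio eta for a numeric vector grouped by a categorical one.
correlation_ratio <- function(num, cat) {
  cat <- factor(cat)
  grand <- mean(num)
  sst <- sum((num - grand)^2)
  if (sst == 0) return(NA_real_)
  means <- tapply(num, cat, mean)
  ns <- tabulate(cat)
  ssb <- sum(ns * (means - grand)^2)
  sqrt(ssb / sst)
}

#' Screen predictor pairs for collinearity
#'
#' Scores every pair of predictor columns with a type-appropriate
#' association measure -- Pearson r for numeric pairs, Cramer's V for
#' categorical pairs, the correlation ratio eta for mixed pairs -- and flags
#' pairs whose absolute score strictly exceeds `threshold`. Constant columns
#' yield an undefined score and are flagged `"undefined"`.
#'
#' @param data data.frame of predictor columns (numeric or factor).
#' @param threshold flagging threshold on the absolute association score
#'   (default 0.7; strict inequality).
#' @return data.frame with columns `var1`, `var2`, `measure`, `score`,
#'   `flagged` (`"yes"`, `"no"` or `"undefined"`).
#' @export
collinearity_screen <- function(data, threshold = 0.7) {
  stopifnot(is.data.frame(data))
  if (ncol(data) < 2L) stop("need at least 2 predictors to screen")
  nms <- names(data)
  is_num <- vapply(data, is.numeric, logical(1))
  is_const <- vapply(data, function(col) length(unique(col)) < 2L, logical(1))
  pairs <- utils::combn(nms, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    if (is_const[a] || is_const[b]) {
      return(data.frame(var1 = a, var2 = b, measure = "undefined",
                        score = NA_real_, flagged = "undefined",
                        stringsAsFactors = FALSE))
    }
    if (is_num[a] && is_num[b]) {
      measure <- "pearson"
      score <- stats::cor(data[[a]], data[[b]])
    } else if (!is_num[a] && !is_num[b]) {
      measure <- "cramers_v"
      score <- cramers_v(data[[a]], data[[b]])
    } else {
      measure <- "eta"
      num <- if (is_num[a]) data[[a]] else data[[b]]
      cat_ <- if (is_num[a]) data[[b]] else data[[a]]
      score <- correlation_ratio(num, cat_)
    }
    flagged <- if (is.na(score)) "undefined"
               else if (abs(score) > threshold) "yes" else "no"
    data.frame(var1 = a, var2 = b, measure = measure, score = score,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
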