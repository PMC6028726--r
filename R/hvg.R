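#' Genes adequately expressed for feature selection
#'
#' Keeps genes with an expression value above `min_expr` in at least
#' `min_cells` cells. Applied before highly-variable-gene selection in the
#' clustering recursion.
#'
#' @param expr An [expr_matrix()] or plain matrix.
#' @param min_expr Expression threshold (strict `>`).
#' @param min_cells Minimum number of cells exceeding it.
#' @return Character vector of retained gene names.
#' @export
prefilter_genes <- function(expr, min_expr = 1, min_cells = 3) {
  m <- .expr_of(expr)
  rownames(m)[Matrix::rowSums(m > min_expr) >= min_cells]
}

#' Fit the reciprocal CV-squared trend
#'
#' Least-squares fit of `cv2 = a0 + a1 / mu` across genes, the standard
#' model for the technical squared coefficient of variation of
#' molecule-count data as a function of mean expression.
#'
#' @param mean Per-gene means (linear scale), all > 0.
#' @param cv2 Per-gene squared coefficients of variation
#'   (`variance / mean^2`).
#' @return A list with coefficients `a0`, `a1`, the residual standard error
#'   `sigma`, their standard errors `se`, and `fitted` values.
#' @export
fit_cv2_trend <- function(mean, cv2) {
  ok <- is.finite(mean) & is.finite(cv2) & mean > 0
  if (sum(ok) < 3) stop("too few genes with positive mean for the CV2 fit")
  if (stats::var(1 / mean[ok]) == 0)
    stop("degenerate CV2 fit: all gene means equal")
  fit <- stats::lm(cv2[ok] ~ I(1 / mean[ok]))
  sm <- summary(fit)
  fitted <- rep(NA_real_, length(mean))
  fitted[ok] <- stats::coef(fit)[1] + stats::coef(fit)[2] / mean[ok]
  list(a0 = unname(stats::coef(fit)[1]), a1 = unname(stats::coef(fit)[2]),
       sigma = sm$sigma, se = unname(sm$coefficients[, "Std. Error"]),
       fitted = fitted)
}

#' Select highly variable genes by the CV-squared criterion
#'
#' For each gene, computes the squared coefficient of variation
#' `CV2 = variance / mean^2` of its normalized expression on the linear
#' TPM/10 scale (`2^expr - 1`), fits the reciprocal trend
#' `cv2 = a0 + a1/mu` over genes with positive mean, and selects genes whose
#' CV2 exceeds the fitted value by more than one residual standard error.
#' The trend is exact on the linear scale for overdispersed count data,
#' which is what makes the one-standard-error band discriminative; see the
#' methods vignette for the reasoning.
#'
#' @param expr An [expr_matrix()] or plain `log2(TPM/10 + 1)` matrix with at
#'   least 2 cells.
#' @param prefilter If `TRUE`, restrict to [prefilter_genes()] (expression
#'   > 1 in at least 3 cells) before fitting.
#' @return A list with `genes` (selected gene names) and `stats` (a
#'   `data.frame` with `gene`, `mean`, `var`, `cv2`, `fitted_cv2`,
#'   `selected`). Genes with zero mean are excluded from the fit and never
#'   selected.
#' @export
select_hvg_cv2 <- function(expr, prefilter = FALSE) {
  m <- .expr_of(expr)
  if (ncol(m) < 2) stop("need at least 2 cells")
  if (prefilter) {
    keep <- prefilter_genes(m)
    m <- m[keep, , drop = FALSE]
  }
  lin <- m
  lin@x <- 2^lin@x - 1
  st <- .row_stats(lin)
  mu <- st$mean
  cv2 <- ifelse(mu > 0, st$var / mu^2, NA_real_)
  if (sum(mu > 0, na.rm = TRUE) < 10)
    stop("need at least 10 genes with positive mean")
  trend <- fit_cv2_trend(mu, cv2)
  selected <- !is.na(cv2) & !is.na(trend$fitted) &
    cv2 > trend$fitted + trend$sigma
  stats <- data.frame(gene = rownames(m), mean = mu, var = st$var,
                      cv2 = cv2, fitted_cv2 = trend$fitted,
                      selected = selected, stringsAsFactors = FALSE,
                      row.names = NULL)
  list(genes = rownames(m)[selected], stats = stats, trend = trend)
}

#' Select highly variable genes by mean and dispersion thresholds
#'
#' Keeps genes whose mean expression exceeds `mean_min` and whose
#' dispersion (`variance / mean` of expression) exceeds `disp_min`; both
#' inequalities are strict, so a gene with mean exactly `mean_min` is
#' excluded.
#'
#' @param expr An [expr_matrix()] or plain matrix with at least 2 cells.
#' @param mean_min,disp_min Strict lower thresholds.
#' @return Character vector of selected gene names; per-gene statistics are
#'   attached as attribute `"stats"`.
#' @export
select_hvg_dispersion <- function(expr, mean_min = 1, disp_min = 1) {
  m <- .expr_of(expr)
  if (ncol(m) < 2) stop("need at least 2 cells")
  st <- .row_stats(m)
  disp <- ifelse(st$mean > 0, st$var / st$mean, 0)
  sel <- st$mean > mean_min & disp > disp_min
  out <- rownames(m)[sel]
  attr(out, "stats") <- data.frame(gene = rownames(m), mean = st$mean,
                                   dispersion = disp, selected = sel,
                                   stringsAsFactors = FALSE, row.names = NULL)
  out
}
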