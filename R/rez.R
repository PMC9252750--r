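#' Robust-regression Z-score (REZ) selective expression
#'
#' Scores how selectively each gene is expressed in each tissue or cell
#' type. For every column *t* the gene-wise response
#' `x = log2(CPM_t + 1)` is regressed on the leave-one-out baseline
#' `m = median over all other columns of log2(CPM + 1)` with a robust
#' linear fit (iteratively reweighted least squares with Huber weights,
#' tuning constant 1.345, at most 50 iterations). The selective-expression
#' score is the standardized residual
#' `z = (x - fit(m)) / (1.4826 * MAD(residuals))`, so a large positive
#' `z[g, t]` marks a gene expressed well above what its cross-tissue
#' baseline predicts for column *t*. The leave-one-out baseline prevents
#' the focal column from pulling its own reference level.
#'
#' Degenerate columns whose residual MAD is zero (e.g. all columns
#' identical) get `z = 0` with a warning.
#'
#' @param panel an [expression_panel] (or a CPM matrix) with at least three
#'   columns and ten genes.
#' @return numeric matrix of Z-scores, genes x columns, same dimnames as
#'   the panel.
#' @export
rez_scores <- function(panel) {
  cpm <- if (inherits(panel, "expression_panel")) panel$values else as.matrix(panel)
  if (ncol(cpm) < 3)
    pcga_stop("REZ needs at least 3 panel columns",
              "pcga_error_not_enough_columns")
  if (nrow(cpm) < 10)
    pcga_stop("REZ needs at least 10 genes", "pcga_error_format")
  lg <- log2(cpm + 1)
  z <- matrix(0, nrow(lg), ncol(lg), dimnames = dimnames(lg))
  degenerate <- character()
  for (t in seq_len(ncol(lg))) {
    x <- lg[, t]
    m <- apply(lg[, -t, drop = FALSE], 1, stats::median)
    res <- robust_residuals(x, m)
    s <- stats::mad(res)                # 1.4826 * median absolute deviation
    if (s <= .Machine$double.eps^0.5) {
      degenerate <- c(degenerate, colnames(lg)[t])
      next                              # z stays 0
    }
    z[, t] <- res / s
  }
  if (length(degenerate))
    pcga_warn(paste("zero residual scale; z set to 0 for column(s):",
                    paste(degenerate, collapse = ", ")),
              "pcga_warning_degenerate")
  z
}

# Residuals of a Huber IRLS regression of x on m (intercept + slope).
# Falls back to the OLS residuals when they are already (numerically) an
# exact fit or the covariate is constant.
robust_residuals <- function(x, m, k = 1.345, maxit = 50, acc = 1e-8) {
  if (stats::sd(m) == 0) return(x - stats::median(x))
  ols <- stats::lm.fit(cbind(1, m), x)
  if (stats::mad(ols$residuals) <= .Machine$double.eps^0.5)
    return(ols$residuals)
  fit <- MASS::rlm(cbind(1, m), x, psi = MASS::psi.huber, k = k,
                   maxit = maxit, acc = acc, scale.est = "MAD")
  as.numeric(fit$residuals)
}
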