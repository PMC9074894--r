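#' Methylation matrix container
#'
#' A light container for a samples x CpGs methylation matrix tagged with its
#' processing stage. Beta-values are methylation fractions in \[0, 1\];
#' M-values are their logit2 transform; M-value residuals are M-values with
#' estimated cell-type composition regressed out (the mediator scale used by
#' the screens).
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   CpGs in columns (colnames = CpG ids). Missing values allowed.
#' @param stage One of `"beta"`, `"M"`, `"M_residual"`.
#' @return An object of class `meth_matrix`: a list with elements `values`
#'   and `stage`.
#' @examples
#' m <- meth_matrix(matrix(0.5, 2, 3, dimnames = list(c("s1", "s2"),
#'                  c("cg1", "cg2", "cg3"))), stage = "beta")
#' cpg_ids(m)
#' @export
meth_matrix <- function(values, stage = c("beta", "M", "M_residual")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x CpGs)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and CpG ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("sample ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("CpG ids must be unique")
  v <- values[is.finite(values)]
  if (stage == "beta") {
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("beta-values must lie in [0, 1]")
  }
  if (any(is.infinite(values)))
    stop("values must be finite or NA")
  structure(list(values = values, stage = stage), class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d samples x %d CpGs, stage = %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @rdname meth_matrix
#' @param m A `meth_matrix`.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname meth_matrix
#' @export
cpg_ids <- function(m) colnames(m$values)

is_meth_matrix <- function(m) inherits(m, "meth_matrix")
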