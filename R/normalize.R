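#' Quantile normalization of profile matrices
#'
#' Forces every serum (row) to share a common intensity distribution — the
#' reference, defined as the mean of the sorted per-serum vectors — thereby
#' removing array-level multiplicative and additive effects while
#' preserving within-serum rank order. Tied values within a serum receive
#' the mean of the reference quantiles they span (midrank interpolation),
#' which matters for integer 0--255 data where ties are guaranteed.
#'
#' `qn_reference` and `qn_apply` expose the fit/transform split so the
#' reference can be learned on training sera only and applied to held-out
#' sera without information leakage (as done inside [cross_validate()]).
#'
#' @param x Numeric matrix, sera as rows, antigens as columns.
#' @param ref Reference distribution: sorted numeric vector of length
#'   `ncol(x)` as returned by `qn_reference`.
#' @return `quantile_normalize` and `qn_apply` return a real-valued matrix
#'   of the same shape and dimnames; `qn_reference` the sorted reference
#'   vector. A single-row matrix is returned unchanged with a warning.
#' @examples
#' x <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(x)  # both rows become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) {
    warning("quantile normalization needs >= 2 sera; returning input unchanged",
            call. = FALSE)
    return(x)
  }
  qn_apply(x, qn_reference(x))
}

#' @rdname quantile_normalize
#' @export
qn_reference <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  rowMeans(apply(x, 1L, sort))
}

#' @rdname quantile_normalize
#' @export
qn_apply <- function(x, ref) {
  stopifnot(is.matrix(x), length(ref) == ncol(x))
  out <- t(apply(x, 1L, function(v) {
    r <- rank(v, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r)$y
  }))
  dimnames(out) <- dimnames(x)
  out
}
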