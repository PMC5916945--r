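#' Annotation-completeness score omega
#'
#' For a kinases-by-variables count matrix, each column is normalized by its
#' maximum over all kinases and the row sums are returned:
#' `omega_i = sum_j v_ij / max(v_j)`. A column whose maximum is 0 contributes
#' 0 for every kinase. Omega is therefore cohort-relative: it lies in
#' `[0, n_variables]` and is invariant to rescaling any column by a positive
#' constant.
#'
#' @param matrix data frame with an `accession` column and one nonnegative
#'   numeric column per annotation variable, or a numeric matrix with row
#'   names as accessions.
#' @return data frame: accession, omega. Attribute `column_maxima` records
#'   the per-variable maxima used for normalization.
#' @export
omega_scores <- function(matrix) {
  if (is.data.frame(matrix)) {
    acc <- matrix$accession
    if (is.null(acc)) input_error("annotation matrix needs an accession column")
    V <- as.matrix(matrix[, setdiff(names(matrix), "accession"), drop = FALSE])
  } else {
    acc <- rownames(matrix)
    V <- matrix
  }
  if (!nrow(V) || !ncol(V)) input_error("annotation matrix must be non-empty")
  if (anyNA(V)) input_error("annotation matrix contains missing values")
  if (any(V < 0)) input_error("annotation matrix values must be nonnegative")
  cmax <- apply(V, 2, max)
  denom <- ifelse(cmax > 0, cmax, Inf) # zero-max column contributes 0
  omega <- as.numeric(V %*% (1 / denom))
  out <- data.frame(accession = acc, omega = omega)
  attr(out, "column_maxima") <- cmax
  out
}

#' Cross-classify kinases: NIH under-studied criteria vs omega
#'
#' A kinase is under-studied (US) when Jensen PubMed score < 50 AND it has no
#' R01 grants AND PubTator score < 150 (all strict, as the criteria are
#' stated); otherwise better-studied (BS). Annotation is Low when
#' `omega < omega_threshold` and High otherwise, so a kinase sitting exactly
#' on the 1.00 threshold is classified High (documented tie-break).
#'
#' @param scores data frame with accession and omega (from [omega_scores()]).
#' @param nih data frame with accession, jensen_score, r01_count,
#'   pubtator_score.
#' @param omega_threshold High/Low cutoff on omega (default 1.00).
#' @return data frame: accession, omega, jensen_score, r01_count,
#'   pubtator_score, understudied (logical), category (one of "BS/High",
#'   "BS/Low", "US/High", "US/Low").
#' @export
classify_kinases <- function(scores, nih, omega_threshold = 1.00) {
  i <- match(scores$accession, nih$accession)
  if (anyNA(i)) {
    input_error(sprintf("no NIH metrics for accession %s",
                        scores$accession[is.na(i)][1]))
  }
  nih <- nih[i, , drop = FALSE]
  us <- nih$jensen_score < 50 & nih$r01_count == 0 & nih$pubtator_score < 150
  high <- scores$omega >= omega_threshold
  data.frame(accession = scores$accession, omega = scores$omega,
             jensen_score = nih$jensen_score, r01_count = nih$r01_count,
             pubtator_score = nih$pubtator_score, understudied = us,
             category = paste0(ifelse(us, "US", "BS"), "/",
                               ifelse(high, "High", "Low")))
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties. A constant input vector makes
#' rho undefined: the function returns `NA` with a warning rather than
#' silently reporting 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return rho in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    input_error("spearman_rho needs two equal-length vectors of length >= 2")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("Spearman rho undefined for a constant vector; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
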