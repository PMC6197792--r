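#' Pearson similarity of entities stored in columns
#'
#' Standard Pearson correlation between every pair of columns (e.g. cell
#' lines described by gene-expression profiles).  Pairs involving a
#' constant profile have undefined correlation and are recorded as 0, so
#' the neighbor ranking stays total.
#'
#' @param X Features x entities numeric matrix (no missing values).
#' @return A symmetric similarity matrix of class `ncfger_similarity`
#'   (variant `"COEF"`).
#' @export
pearson_similarity <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2L) stop("need at least 2 feature rows", call. = FALSE)
  S <- suppressWarnings(stats::cor(X))
  S[!is.finite(S)] <- 0
  p <- ncol(X)
  new_similarity(S, variant = "COEF",
                 support = matrix(nrow(X), p, p, dimnames = dimnames(S)))
}

#' Jaccard similarity of binary fingerprints
#'
#' s(i,j) = |bits_i AND bits_j| / |bits_i OR bits_j| for drugs in rows.
#' Two all-zero fingerprints get 0 by convention.
#'
#' @param F Drugs x bits matrix with entries in \{0, 1\}.
#' @return Symmetric `ncfger_similarity` (variant `"COEF"`).
#' @export
jaccard_similarity <- function(F) {
  stopifnot(is.matrix(F))
  if (!all(F %in% c(0, 1))) {
    stop("fingerprint matrix must be binary (0/1)", call. = FALSE)
  }
  inter <- tcrossprod(F)
  n_on <- rowSums(F)
  uni <- outer(n_on, n_on, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  dimnames(S) <- list(rownames(F), rownames(F))
  p <- nrow(F)
  new_similarity(S, variant = "COEF",
                 support = matrix(ncol(F), p, p, dimnames = dimnames(S)))
}

#' Response-profile Pearson similarity with overlap support
#'
#' Pairwise Pearson correlation between the response profiles of two
#' entities, computed over the entries both have observed.  The overlap
#' count is recorded as the pair's support; pairs with overlap below
#' `min_overlap`, or with zero variance on the overlap, get similarity 0
#' (support is recorded regardless).
#'
#' @param R Cell-line x drug matrix (typically residuals after
#'   global-effect removal), `NA` = unobserved.
#' @param axis `"cell_lines"` correlates rows; `"drugs"` correlates
#'   columns.
#' @param min_overlap Minimum common observations for a nonzero value.
#' @return Symmetric `ncfger_similarity` (variant `"RPCC"`).
#' @export
response_pcc <- function(R, axis = c("cell_lines", "drugs"),
                         min_overlap = 3L) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(R), min_overlap >= 0)
  X <- if (axis == "cell_lines") t(R) else R   # entities in columns
  M <- is.finite(X)
  S <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  support <- crossprod(M * 1)
  S[support < max(min_overlap, 2L)] <- 0
  storage.mode(support) <- "integer"
  new_similarity(S, variant = "RPCC", support = support)
}

#' Fuse molecular-feature and response similarities
#'
#' Elementwise product of a COEF similarity (expression PCC or fingerprint
#' Jaccard) with the response-profile RPCC similarity; the support counts
#' are carried from the RPCC side.
#'
#' @param coef,rpcc `ncfger_similarity` objects over the same entities.
#' @return Symmetric `ncfger_similarity` (variant `"MRPCC"`).
#' @export
combine_mrpcc <- function(coef, rpcc) {
  stopifnot(inherits(coef, "ncfger_similarity"),
            inherits(rpcc, "ncfger_similarity"))
  if (!identical(dim(coef$values), dim(rpcc$values)) ||
      !identical(rownames(coef$values), rownames(rpcc$values))) {
    stop("similarity matrices have mismatched entity labels", call. = FALSE)
  }
  new_similarity(coef$values * rpcc$values, variant = "MRPCC",
                 support = rpcc$support)
}

#' Shrink similarities by overlap support
#'
#' Multiplies every off-diagonal similarity by |U|/(|U| + alpha2), where
#' |U| is the number of entries the pair has in common, down-weighting
#' pairs whose similarity rests on little shared data.  The diagonal is
#' left untouched.
#'
#' @param S An `ncfger_similarity` with support counts.
#' @param alpha2 Shrinkage constant, >= 0 (0 is the identity transform).
#' @return The shrunk similarity, with its `shrunk` flag set.
#' @export
shrink_similarity <- function(S, alpha2 = 1) {
  stopifnot(inherits(S, "ncfger_similarity"))
  if (alpha2 < 0) stop("alpha2 must be >= 0", call. = FALSE)
  vals <- S$values * S$support / (S$support + alpha2)
  vals[S$support == 0L] <- 0
  diag(vals) <- diag(S$values)
  out <- S
  out$values <- vals
  out$shrunk <- TRUE
  out
}

new_similarity <- function(values, variant, support) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            identical(dim(values), dim(support)))
  structure(list(values = values, variant = variant, support = support,
                 shrunk = FALSE),
            class = "ncfger_similarity")
}

#' @export
print.ncfger_similarity <- function(x, ...) {
  cat(sprintf("%s similarity over %d entities%s\n", x$variant,
              nrow(x$values), if (x$shrunk) " (support-shrunk)" else ""))
  invisible(x)
}

# Build the (cell-line, drug) shrunk similarity pair for one variant.
# COEF sides come from expression / fingerprints; RPCC from the supplied
# (residual or raw) response matrix.
build_similarities <- function(R_for_rpcc, expression, fingerprints,
                               variant = c("MRPCC", "RPCC", "COEF"),
                               alpha2 = 1, min_overlap = 3L) {
  variant <- match.arg(variant)
  need_feat <- variant %in% c("COEF", "MRPCC")
  if (need_feat && (is.null(expression) || is.null(fingerprints))) {
    stop(sprintf("similarity variant %s needs expression and fingerprint matrices",
                 variant), call. = FALSE)
  }
  coef_c <- if (need_feat) pearson_similarity(expression)
  coef_d <- if (need_feat) jaccard_similarity(fingerprints)
  if (variant != "COEF") {
    rpcc_c <- response_pcc(R_for_rpcc, "cell_lines", min_overlap)
    rpcc_d <- response_pcc(R_for_rpcc, "drugs", min_overlap)
  }
  S_c <- switch(variant, COEF = coef_c, RPCC = rpcc_c,
                MRPCC = combine_mrpcc(coef_c, rpcc_c))
  S_d <- switch(variant, COEF = coef_d, RPCC = rpcc_d,
                MRPCC = combine_mrpcc(coef_d, rpcc_d))
  if (variant == "COEF") {
    # feature-based similarities rest on complete profiles, but ranking
    # support is still the response overlap, as for the other variants
    sup_c <- response_pcc(R_for_rpcc, "cell_lines", 0L)$support
    sup_d <- response_pcc(R_for_rpcc, "drugs", 0L)$support
    S_c$support <- sup_c
    S_d$support <- sup_d
  }
  list(cell = shrink_similarity(S_c, alpha2),
       drug = shrink_similarity(S_d, alpha2))
}
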