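#' Shrunk per-entity effect estimate
#'
#' For one entity (a cell line or a drug) with observed responses `r` and
#' explanatory values `x`, the unshrunk estimate is the least-squares slope
#' sum(r*x)/sum(x^2); it is then pulled toward zero by the Bayesian factor
#' n/(n + alpha), where n is the number of observed responses for the
#' entity.  Entities with no data, or with sum(x^2) == 0, get 0.
#'
#' @param r Observed values (residuals from earlier steps) for one entity.
#' @param x Explanatory values, same length as `r` (identically 1 for the
#'   plain main effects).
#' @param alpha Shrinkage constant, >= 0; larger means stronger shrinkage.
#' @return The shrunk scalar estimate.
#' @export
estimate_effect <- function(r, x = rep(1, length(r)), alpha = 0) {
  stopifnot(length(r) == length(x), is.finite(alpha), alpha >= 0)
  if (length(r) && any(!is.finite(r))) {
    stop("non-finite residual in effect estimation", call. = FALSE)
  }
  n <- length(r)
  sx2 <- sum(x^2)
  if (n == 0L || sx2 == 0) return(0)
  (sum(r * x) / sx2) * (n / (n + alpha))
}

#' Fit a sequential global-effects model
#'
#' Estimates effects one at a time in the order given, each step taking
#' the residuals of the previous one as its response.  `specs` is an
#' ordered list of `list(name, axis, alpha)` with `axis` one of
#' `"scalar"`, `"row"`, `"column"`; the default chain (overall mean,
#' cell-line main effect, drug main effect) comes from
#' [default_effect_specs()].  Unobserved (`NA`) entries are ignored
#' throughout.
#'
#' @param R Cell-line x drug matrix with `NA` for unobserved entries.
#' @param specs Ordered effect specification list; an empty list gives
#'   the identity model.
#' @return An object of class `"ncfger_effects"` holding the fitted
#'   effect vectors in removal order.
#' @seealso [remove_effects()], [restore_effects()]
#' @export
fit_global_effects <- function(R, specs = default_effect_specs()) {
  stopifnot(is.matrix(R))
  obs <- is.finite(R)
  if (!any(obs)) stop("no observed entries to fit", call. = FALSE)
  resid <- R
  fitted <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    theta <- switch(spec$axis,
      scalar = estimate_effect(resid[obs], alpha = spec$alpha),
      row = vapply(seq_len(nrow(R)), function(u) {
        v <- resid[u, ]
        estimate_effect(v[is.finite(v)], alpha = spec$alpha)
      }, numeric(1L)),
      column = vapply(seq_len(ncol(R)), function(i) {
        v <- resid[, i]
        estimate_effect(v[is.finite(v)], alpha = spec$alpha)
      }, numeric(1L)),
      stop("unknown effect axis: ", spec$axis)
    )
    resid <- resid - effect_field(spec$axis, theta, nrow(R), ncol(R))
    resid[!obs] <- NA_real_
    fitted[[s]] <- list(spec = spec, theta = theta)
  }
  structure(list(effects = fitted, dim = dim(R), dimnames = dimnames(R)),
            class = "ncfger_effects")
}

#' Default global-effect chain
#'
#' Overall mean (unshrunk: a single scalar estimated from every observed
#' entry needs no stabilizing), then cell-line and drug main effects with
#' explanatory values identically 1 and shrinkage constants `alpha1`.
#'
#' @param alpha1_cell,alpha1_drug Shrinkage constants for the two main
#'   effects (default 3).
#' @return Ordered list of effect specifications for
#'   [fit_global_effects()].
#' @export
default_effect_specs <- function(alpha1_cell = 3, alpha1_drug = alpha1_cell) {
  list(list(name = "overall_mean",   axis = "scalar", alpha = 0),
       list(name = "cell_line_main", axis = "row",    alpha = alpha1_cell),
       list(name = "drug_main",      axis = "column", alpha = alpha1_drug))
}

# Expand a fitted effect into a full m x n contribution matrix.
effect_field <- function(axis, theta, m, n) {
  switch(axis,
         scalar = matrix(theta, m, n),
         row    = matrix(theta, m, n, byrow = FALSE),
         column = matrix(theta, m, n, byrow = TRUE))
}

# Total fitted effect (the global-effects-only prediction) for entries;
# u, i are index vectors recycled against each other.
effect_total <- function(model, u, i) {
  stopifnot(inherits(model, "ncfger_effects"))
  m <- model$dim[1L]; n <- model$dim[2L]
  if (any(u < 1L | u > m) || any(i < 1L | i > n)) {
    stop("entry index out of range", call. = FALSE)
  }
  tot <- numeric(max(length(u), length(i)))
  u <- rep_len(u, length(tot)); i <- rep_len(i, length(tot))
  for (eff in model$effects) {
    tot <- tot + switch(eff$spec$axis,
                        scalar = eff$theta,
                        row    = eff$theta[u],
                        column = eff$theta[i])
  }
  tot
}

#' Restore removed global effects onto residual-scale predictions
#'
#' The inverse of effect removal, applied entry-wise: adds back the
#' fitted effect contributions for entry (u, i).
#'
#' @param model Fitted `"ncfger_effects"` model.
#' @param u,i Cell-line and drug index vectors (recycled).
#' @param residual_prediction Residual-scale value(s).
#' @return Values on the original response scale.
#' @export
restore_effects <- function(model, u, i, residual_prediction) {
  residual_prediction + effect_total(model, u, i)
}

#' Remove fitted global effects from a matrix
#'
#' Residualizes a matrix with an already-fitted effects model; on the
#' data the model was fitted to, `remove_effects` followed by
#' [restore_effects()] reproduces the observed values exactly.
#'
#' @param model Fitted `"ncfger_effects"` model.
#' @param R Matrix with the model's dimensions.
#' @return Residual matrix (`NA` pattern preserved).
#' @export
remove_effects <- function(model, R) {
  stopifnot(inherits(model, "ncfger_effects"),
            all(dim(R) == model$dim))
  out <- R
  for (eff in model$effects) {
    out <- out - effect_field(eff$spec$axis, eff$theta, nrow(R), ncol(R))
  }
  out
}
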