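#' Fit a neighborhood collaborative-filtering drug-response model
#'
#' Fits the full predictor on the observed entries of a cell-line x drug
#' response matrix: (1) global effects (overall mean, per-cell-line and
#' per-drug offsets) are estimated sequentially with Bayesian shrinkage
#' n/(n + alpha1) and removed; (2) cell-line and drug similarity matrices
#' are built under the requested variant (COEF from molecular features,
#' RPCC from response residuals, MRPCC their product) and shrunk by
#' overlap support |U|/(|U| + alpha2).  The fitted object predicts unseen
#' entries by non-negative interpolation over the K most similar
#' neighbors, solved from beta-shrunk normal equations, with global
#' effects restored afterwards.
#'
#' @param response Cell-line x drug numeric matrix, `NA` = unobserved
#'   (log IC50 or activity area).
#' @param expression Genes x cell-lines matrix (needed for COEF/MRPCC
#'   similarity on the cell-line side).
#' @param fingerprints Drugs x bits binary matrix (needed for COEF/MRPCC
#'   on the drug side).
#' @param similarity Similarity variant: `"MRPCC"` (default), `"RPCC"`,
#'   or `"COEF"`.
#' @param orientation Which neighbor sets drive prediction: `"hybrid"`
#'   (default; average of both), `"cell_line"`, or `"drug"`.
#' @param K Neighbor count (default 10).
#' @param beta Normal-equation shrinkage constant (default 500).
#' @param alpha1 Effect-estimate shrinkage constant (default 3); a length-2
#'   vector gives (cell-line, drug) values separately.
#' @param alpha2 Similarity shrinkage constant (default 1).
#' @param min_overlap Minimum response overlap for a nonzero response-PCC
#'   (default 3).
#' @param rpcc_on Compute response-PCC on `"residuals"` (default) or on
#'   the `"raw"` response values.
#' @param effects `"default"` for the three-effect chain, `"none"` to
#'   skip global-effect removal, or an explicit spec list as accepted by
#'   the internal fitter.
#' @param align Align inputs by shared labels first (default `TRUE`).
#' @param quiet Suppress alignment messages.
#' @return An object of class `"ncfger"`; see [predict.ncfger()].
#' @examples
#' sim <- simulate_response_data(m = 40, n = 12, seed = 1)
#' fit <- ncfger(sim$response, sim$expression, sim$fingerprints)
#' fit
#' head(predict(fit))
#' @export
ncfger <- function(response, expression = NULL, fingerprints = NULL,
                   similarity = c("MRPCC", "RPCC", "COEF"),
                   orientation = c("hybrid", "cell_line", "drug"),
                   K = 10L, beta = 500, alpha1 = 3, alpha2 = 1,
                   min_overlap = 3L,
                   rpcc_on = c("residuals", "raw"),
                   effects = "default",
                   align = TRUE, quiet = FALSE) {
  similarity <- match.arg(similarity)
  orientation <- match.arg(orientation)
  rpcc_on <- match.arg(rpcc_on)
  stopifnot(is.matrix(response), K >= 1L, beta >= 0, all(alpha1 >= 0),
            alpha2 >= 0)
  if (is.null(rownames(response))) {
    rownames(response) <- sprintf("C%03d", seq_len(nrow(response)))
  }
  if (is.null(colnames(response))) {
    colnames(response) <- sprintf("D%03d", seq_len(ncol(response)))
  }
  if (align && (!is.null(expression) || !is.null(fingerprints))) {
    al <- align_inputs(response, expression, fingerprints, quiet = quiet)
    response <- al$response; expression <- al$expression
    fingerprints <- al$fingerprints
  }
  if (!any(is.finite(response))) {
    stop("response matrix has no observed entries", call. = FALSE)
  }

  specs <- if (identical(effects, "default")) {
    a1 <- rep_len(alpha1, 2L)
    default_effect_specs(a1[1L], a1[2L])
  } else if (identical(effects, "none")) {
    list()
  } else effects
  ge <- if (length(specs)) fit_global_effects(response, specs) else
    structure(list(effects = list(), dim = dim(response),
                   dimnames = dimnames(response)),
              class = "ncfger_effects")
  resid <- remove_effects(ge, response)

  sim_input <- if (rpcc_on == "residuals") resid else response
  S <- build_similarities(sim_input, expression, fingerprints,
                          variant = similarity, alpha2 = alpha2,
                          min_overlap = min_overlap)

  structure(list(
    response = response,
    residuals = resid,
    effects = ge,
    S_cell = S$cell, S_drug = S$drug,
    config = list(similarity = similarity, orientation = orientation,
                  K = as.integer(K), beta = beta,
                  alpha1 = rep_len(alpha1, 2L), alpha2 = alpha2,
                  min_overlap = as.integer(min_overlap),
                  rpcc_on = rpcc_on, effects = effects)),
    class = "ncfger")
}

#' Predict drug responses from a fitted model
#'
#' By default predicts every unobserved entry of the training response
#' matrix; alternatively, an explicit two-column (cell, drug) index or
#' label matrix selects the entries.
#'
#' @param object Fitted `"ncfger"` model.
#' @param entries Optional two-column matrix or data.frame of (cell line,
#'   drug) pairs — integer indices or labels.
#' @param orientation Override the fitted orientation.
#' @param ... Unused.
#' @return A data.frame: `cell_line`, `drug`, `predicted_value`,
#'   `residual_value`, `n_neighbors_cell`, `n_neighbors_drug`,
#'   `fallback_flag`.
#' @export
predict.ncfger <- function(object, entries = NULL, orientation = NULL, ...) {
  R <- object$response
  if (is.null(entries)) {
    idx <- which(!is.finite(R), arr.ind = TRUE)
  } else {
    idx <- .resolve_entries(entries, R)
  }
  cfg <- object$config
  if (!is.null(orientation)) {
    cfg$orientation <- match.arg(orientation, c("hybrid", "cell_line", "drug"))
  }
  n <- nrow(idx)
  out <- data.frame(cell_line = rownames(R)[idx[, 1L]],
                    drug = colnames(R)[idx[, 2L]],
                    predicted_value = numeric(n),
                    residual_value = numeric(n),
                    n_neighbors_cell = integer(n),
                    n_neighbors_drug = integer(n),
                    fallback_flag = logical(n),
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    p <- predict_entry(idx[r, 1L], idx[r, 2L], object$residuals,
                       object$effects, object$S_cell, object$S_drug, cfg)
    out$predicted_value[r] <- p$final_value
    out$residual_value[r] <- p$residual_value
    out$n_neighbors_cell[r] <- p$n_neighbors_cell
    out$n_neighbors_drug[r] <- p$n_neighbors_drug
    out$fallback_flag[r] <- p$fallback
  }
  out
}

.resolve_entries <- function(entries, R) {
  entries <- as.matrix(entries)
  if (ncol(entries) != 2L) stop("entries must have two columns", call. = FALSE)
  if (is.character(entries)) {
    u <- match(entries[, 1L], rownames(R))
    i <- match(entries[, 2L], colnames(R))
    if (anyNA(u) || anyNA(i)) stop("unknown cell-line or drug label",
                                   call. = FALSE)
    cbind(u, i)
  } else {
    storage.mode(entries) <- "integer"
    if (any(entries[, 1L] < 1L | entries[, 1L] > nrow(R)) ||
        any(entries[, 2L] < 1L | entries[, 2L] > ncol(R))) {
      stop("entry index out of range", call. = FALSE)
    }
    entries
  }
}

#' @export
print.ncfger <- function(x, ...) {
  R <- x$response
  cat("Neighborhood collaborative-filtering drug-response model\n")
  cat(sprintf("  %d cell lines x %d drugs, %d observed (%.1f%%)\n",
              nrow(R), ncol(R), sum(is.finite(R)),
              100 * mean(is.finite(R))))
  cfg <- x$config
  cat(sprintf("  similarity %s, orientation %s, K = %d, beta = %g, alpha1 = %g/%g, alpha2 = %g\n",
              cfg$similarity, cfg$orientation, cfg$K, cfg$beta,
              cfg$alpha1[1L], cfg$alpha1[2L], cfg$alpha2))
  cat(sprintf("  global effects: %s\n",
              if (length(x$effects$effects))
                paste(vapply(x$effects$effects, function(e) e$spec$name,
                             character(1L)), collapse = " -> ")
              else "none"))
  invisible(x)
}

#' @export
summary.ncfger <- function(object, ...) {
  co <- coef(object)
  res <- residuals(object)
  out <- list(dim = dim(object$response),
              n_observed = sum(is.finite(object$response)),
              config = object$config,
              overall_mean = co$overall_mean,
              cell_effect_range = if (!is.null(co$cell_line_main))
                range(co$cell_line_main),
              drug_effect_range = if (!is.null(co$drug_main))
                range(co$drug_main),
              residual_sd = stats::sd(res[is.finite(res)]))
  class(out) <- "summary.ncfger"
  out
}

#' @export
print.summary.ncfger <- function(x, ...) {
  cat(sprintf("ncfger fit: %d x %d, %d observed\n", x$dim[1L], x$dim[2L],
              x$n_observed))
  if (!is.null(x$overall_mean)) {
    cat(sprintf("  overall mean %.4g\n", x$overall_mean))
  }
  if (!is.null(x$cell_effect_range)) {
    cat(sprintf("  cell-line effects in [%.4g, %.4g]\n",
                x$cell_effect_range[1L], x$cell_effect_range[2L]))
  }
  if (!is.null(x$drug_effect_range)) {
    cat(sprintf("  drug effects in [%.4g, %.4g]\n",
                x$drug_effect_range[1L], x$drug_effect_range[2L]))
  }
  cat(sprintf("  residual s.d. %.4g\n", x$residual_sd))
  invisible(x)
}

#' Extract fitted global effects
#'
#' @param object Fitted `"ncfger"` model.
#' @param ... Unused.
#' @return Named list of effect estimates (scalar overall mean, named
#'   per-cell-line and per-drug vectors), in removal order.
#' @export
coef.ncfger <- function(object, ...) {
  out <- list()
  for (eff in object$effects$effects) {
    th <- eff$theta
    if (eff$spec$axis == "row") names(th) <- rownames(object$response)
    if (eff$spec$axis == "column") names(th) <- colnames(object$response)
    out[[eff$spec$name]] <- th
  }
  out
}

#' @export
residuals.ncfger <- function(object, ...) object$residuals

#' @export
fitted.ncfger <- function(object, ...) {
  # global-effects-only fit for the observed entries
  m <- nrow(object$response); n <- ncol(object$response)
  f <- matrix(effect_total(object$effects,
                           rep(seq_len(m), n), rep(seq_len(n), each = m)),
              m, n, dimnames = dimnames(object$response))
  f[!is.finite(object$response)] <- NA_real_
  f
}

#' Diagnostic plots for a fitted model
#'
#' Left: observed values against the global-effects-only fit (how much of
#' the signal the additive effects capture).  Right: histogram of the
#' residuals the neighborhood stage works on.
#'
#' @param x Fitted `"ncfger"` model.
#' @param ... Passed to [plot()].
#' @export
plot.ncfger <- function(x, ...) {
  obs <- is.finite(x$response)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(fitted(x)[obs], x$response[obs],
       xlab = "global-effects fit", ylab = "observed response", ...)
  graphics::abline(0, 1, col = "grey50")
  graphics::hist(x$residuals[obs], main = "", xlab = "residual")
  invisible(x)
}
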