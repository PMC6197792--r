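#' Select the K nearest neighbors for one target entry
#'
#' For a drug-oriented prediction of entry (u, i) the candidates are the
#' drugs j != i whose response r_uj is observed in the training matrix;
#' for a cell-line-oriented prediction they are the cell lines v != u with
#' r_vi observed.  The K candidates with the largest shrunk similarity to
#' the target entity are returned in descending similarity order, ties
#' broken by ascending index; fewer than K candidates are all returned.
#'
#' @param u,i Target cell-line and drug indices.
#' @param R_train Residual training matrix (`NA` = unobserved).
#' @param S Shrunk similarity values (plain matrix or `ncfger_similarity`)
#'   over the neighbor-supplying entities.
#' @param K Number of neighbors.
#' @param orientation `"drug"` (drug neighbors) or `"cell_line"`.
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
select_neighbors <- function(u, i, R_train, S, K = 10L,
                             orientation = c("drug", "cell_line")) {
  orientation <- match.arg(orientation)
  stopifnot(K >= 1L)
  sv <- if (inherits(S, "ncfger_similarity")) S$values else S
  if (orientation == "drug") {
    cand <- which(is.finite(R_train[u, ]))
    cand <- cand[cand != i]
    sims <- sv[i, cand]
  } else {
    cand <- which(is.finite(R_train[, i]))
    cand <- cand[cand != u]
    sims <- sv[u, cand]
  }
  if (!length(cand)) return(integer(0))
  ord <- order(-sims, cand)
  cand[ord][seq_len(min(K, length(cand)))]
}

#' Build the shrunk normal-equation system for interpolation weights
#'
#' Drug orientation (the cell-line orientation is the exact transpose):
#' for neighbor drugs j, k of target (u, i), the raw mean co-products are
#' A_bar_jk = sum over cell lines v in U(j,k) of r_vj * r_vk / |U(j,k)|
#' and b_bar_j analogously against the target drug i, where U(.,.) is the
#' set of cell lines observing both drugs; the target cell line u is
#' excluded from every sum to prevent leakage.  Because supports |U|
#' differ wildly across pairs, each entry is shrunk toward avg (the mean
#' of the positively-supported A_bar entries over the neighbor pairs,
#' diagonal included): A_hat = (|U| A_bar + beta avg) / (|U| + beta), and
#' likewise b_hat.  Zero-support pairs shrink fully to avg.
#'
#' @inheritParams select_neighbors
#' @param neighbors Neighbor index vector from [select_neighbors()].
#' @param beta Shrinkage constant, >= 0.
#' @return List with `A_bar`, `b_bar`, `A_hat`, `b_hat`, `avg`,
#'   `support_A`, `support_b`.
#' @export
build_weight_system <- function(u, i, neighbors, R_train, beta = 500,
                                orientation = c("drug", "cell_line")) {
  orientation <- match.arg(orientation)
  if (!length(neighbors)) stop("empty neighbor list", call. = FALSE)
  stopifnot(beta >= 0)
  X <- if (orientation == "drug") R_train else t(R_train)
  tu <- if (orientation == "drug") u else i   # entity whose rows are summed out
  ti <- if (orientation == "drug") i else u   # target column
  X <- X[-tu, c(neighbors, ti), drop = FALSE]
  M <- is.finite(X)
  X0 <- ifelse(M, X, 0)
  K <- length(neighbors)
  cp <- crossprod(X0)
  n <- crossprod(M * 1)
  A_n <- n[seq_len(K), seq_len(K), drop = FALSE]
  A_bar <- ifelse(A_n > 0, cp[seq_len(K), seq_len(K), drop = FALSE] / pmax(A_n, 1), 0)
  b_n <- n[seq_len(K), K + 1L]
  b_bar <- ifelse(b_n > 0, cp[seq_len(K), K + 1L] / pmax(b_n, 1), 0)
  avg <- if (any(A_n > 0)) mean(A_bar[A_n > 0]) else 0
  A_hat <- (A_n * A_bar + beta * avg) / (A_n + beta)
  b_hat <- (b_n * b_bar + beta * avg) / (b_n + beta)
  if (beta == 0) {                      # 0/0 guards at zero support
    A_hat[A_n == 0] <- 0
    b_hat[b_n == 0] <- 0
  }
  list(A_bar = A_bar, b_bar = b_bar, A_hat = A_hat, b_hat = b_hat,
       avg = avg, support_A = A_n, support_b = b_n)
}

#' Non-negative interpolation weights from a shrunk normal system
#'
#' Solves min over w >= 0 of w' A w - 2 b' w (equivalently the
#' non-negative solution of A w = b) by an active-set method of
#' Lawson-Hanson type operating directly on the normal-equations form.
#' Convergence is declared at KKT residual below `tol`; if the system is
#' singular on an active set, a small ridge (1e-8 * trace/K) is added and
#' a message emitted.
#'
#' @param sys List with `A_hat` and `b_hat` (as from
#'   [build_weight_system()]), or a matrix `A` with `b` given separately.
#' @param b Right-hand side when `sys` is a plain matrix.
#' @param tol KKT tolerance.
#' @return Non-negative weight vector.
#' @export
solve_nonnegative_weights <- function(sys, b = NULL, tol = 1e-8) {
  if (is.list(sys)) {
    A <- sys$A_hat; b <- sys$b_hat
  } else {
    A <- sys
  }
  K <- length(b)
  stopifnot(is.matrix(A), nrow(A) == K, ncol(A) == K)
  if (!all(is.finite(A)) || !all(is.finite(b))) {
    stop("non-finite weight system", call. = FALSE)
  }
  A <- (A + t(A)) / 2
  scale <- max(abs(b), abs(A), 1)
  w <- numeric(K)
  P <- logical(K)                      # active (free) set
  ridge_warned <- FALSE

  solve_free <- function(P) {
    Ap <- A[P, P, drop = FALSE]
    z <- tryCatch(solve(Ap, b[P]), error = function(e) NULL)
    if (is.null(z) || !all(is.finite(z))) {
      if (!ridge_warned) {
        message("singular active-set system; adding ridge")
        ridge_warned <<- TRUE
      }
      r <- 1e-8 * max(sum(diag(A)) / K, 1)
      z <- solve(Ap + diag(r, sum(P)), b[P])
    }
    z
  }

  for (outer in seq_len(10L * K + 10L)) {
    lambda <- b - drop(A %*% w)        # -(1/2) gradient
    lambda[P] <- -Inf
    j <- which.max(lambda)
    if (!length(j) || lambda[j] <= tol * scale) break
    P[j] <- TRUE
    repeat {
      z <- numeric(K)
      z[P] <- solve_free(P)
      if (all(z[P] > 0)) { w <- z; break }
      bad <- P & (z <= 0)
      alpha <- min(w[bad] / (w[bad] - z[bad]))
      w <- w + alpha * (z - w)
      P[P & (w <= tol)] <- FALSE
      w[!P] <- 0
      if (!any(P)) { w <- numeric(K); break }
    }
  }
  pmax(w, 0)
}

# Predict the residual-scale value of one entry for one orientation.
# Returns list(value, n_neighbors); value NA when no neighbors exist.
predict_orientation <- function(u, i, R_train, S, cfg, orientation) {
  nb <- select_neighbors(u, i, R_train, S, cfg$K, orientation)
  if (!length(nb)) return(list(value = NA_real_, n = 0L))
  sys <- build_weight_system(u, i, nb, R_train, cfg$beta, orientation)
  w <- solve_nonnegative_weights(sys)
  r_nb <- if (orientation == "drug") R_train[u, nb] else R_train[nb, i]
  list(value = sum(w * r_nb), n = length(nb))
}

#' Predict one held-out entry
#'
#' Runs the configured orientation(s) on the residual training matrix and
#' restores the removed global effects.  `"hybrid"` averages the
#' drug-oriented and cell-line-oriented residual predictions; if one
#' orientation has no candidates the other is used alone, and if neither
#' has candidates the prediction falls back to the global-effects-only
#' value (flagged).
#'
#' @param u,i Target indices.
#' @param R_train Residual training matrix (`NA` = unobserved).
#' @param model Fitted global-effects model.
#' @param S_cell,S_drug Shrunk similarity matrices.
#' @param cfg List with `K`, `beta`, `orientation`.
#' @return List: `final_value`, `residual_value`, `n_neighbors_cell`,
#'   `n_neighbors_drug`, `fallback`.
#' @export
predict_entry <- function(u, i, R_train, model, S_cell, S_drug, cfg) {
  pd <- if (cfg$orientation %in% c("drug", "hybrid")) {
    predict_orientation(u, i, R_train, S_drug, cfg, "drug")
  } else list(value = NA_real_, n = 0L)
  pc <- if (cfg$orientation %in% c("cell_line", "hybrid")) {
    predict_orientation(u, i, R_train, S_cell, cfg, "cell_line")
  } else list(value = NA_real_, n = 0L)
  both <- c(pd$value, pc$value)
  resid <- if (all(is.na(both))) 0 else mean(both, na.rm = TRUE)
  fallback <- all(is.na(both))
  list(final_value = restore_effects(model, u, i, resid),
       residual_value = resid,
       n_neighbors_cell = pc$n, n_neighbors_drug = pd$n,
       fallback = fallback)
}
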