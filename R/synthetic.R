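#' Simulate a drug-response dataset with known structure
#'
#' Generates the data-generating process the neighborhood model assumes:
#' responses are an overall mean plus additive cell-line and drug offsets
#' plus a low-rank cell-line x drug interaction plus i.i.d. Gaussian
#' noise,
#'
#'   R[u, i] = mu + a_u + b_i + s_int / sqrt(rank) * sum_f p_uf q_if + eps,
#'
#' with a ~ N(0, sigma_row^2), b ~ N(0, sigma_col^2), p, q ~ N(0, 1) and
#' eps ~ N(0, sigma_noise^2).  Expression profiles are generated from the
#' cell-line factors p through random gene loadings plus gene-level noise,
#' so expression correlation tracks latent cell-line similarity;
#' fingerprint bits are Bernoulli with log-odds driven by the drug
#' factors q, so drugs sharing factors share bits above chance.  Entries
#' are masked missing-at-random at `missing_rate`; rows or columns left
#' with no observation are re-masked (guard logged via `message`).
#'
#' @param m,n Cell-line and drug counts.
#' @param rank Latent dimension of the interaction (0 = additive only).
#' @param mu Overall mean.
#' @param sigma_row,sigma_col S.d. of cell-line and drug offsets.
#' @param sigma_int Scale of the (rank-normalized) interaction term.
#' @param sigma_noise Noise s.d.
#' @param missing_rate Fraction masked, in [0, 1).
#' @param n_genes,n_bits Expression and fingerprint dimensions.
#' @param sigma_expr Gene-level noise s.d. in the expression matrix.
#' @param sigma_gene S.d. of per-gene baseline expression shared by all
#'   cell lines.  Real expression profiles differ far more between genes
#'   than between samples, which makes sample-sample Pearson correlation
#'   positive for essentially every pair; this term reproduces that
#'   property, with the latent factors modulating the ranking on top.
#' @param seed Integer seed; output is fully deterministic given it.
#' @return List of class `"ncfger_sim"`: `response` (with `NA` at masked
#'   entries), `expression`, `fingerprints`, and `truth` (list with
#'   `mu`, `a`, `b`, `P`, `Q`, `full` — the complete noisy matrix).
#' @export
simulate_response_data <- function(m = 60L, n = 20L, rank = 3L, mu = 3,
                                   sigma_row = 1, sigma_col = 1,
                                   sigma_int = 1, sigma_noise = 0.3,
                                   missing_rate = 0.3,
                                   n_genes = 500L, n_bits = 128L,
                                   sigma_expr = 5, sigma_gene = 2,
                                   seed = 1L) {
  stopifnot(m >= 2L, n >= 2L, rank >= 0L, rank <= min(m, n),
            sigma_row >= 0, sigma_col >= 0, sigma_noise >= 0,
            missing_rate >= 0, missing_rate < 1)
  rs <- .save_rng()
  on.exit(.restore_rng(rs))
  set.seed(seed)

  a <- stats::rnorm(m, 0, sigma_row)
  b <- stats::rnorm(n, 0, sigma_col)
  P <- matrix(stats::rnorm(m * rank), m, rank)
  Q <- matrix(stats::rnorm(n * rank), n, rank)
  inter <- if (rank > 0L) sigma_int / sqrt(rank) * tcrossprod(P, Q) else
    matrix(0, m, n)
  full <- mu + outer(a, rep(1, n)) + outer(rep(1, m), b) + inter +
    matrix(stats::rnorm(m * n, 0, sigma_noise), m, n)
  cells <- sprintf("CL%03d", seq_len(m))
  drugs <- sprintf("DR%03d", seq_len(n))
  dimnames(full) <- list(cells, drugs)

  mask <- matrix(stats::runif(m * n) < missing_rate, m, n)
  if (missing_rate > 0) {
    for (guard in seq_len(100L)) {
      bad_r <- which(rowSums(!mask) == 0L)
      bad_c <- which(colSums(!mask) == 0L)
      if (!length(bad_r) && !length(bad_c)) break
      message("re-masking to avoid all-missing rows/columns")
      for (u in bad_r) mask[u, ] <- stats::runif(n) < missing_rate
      for (i in bad_c) mask[, i] <- stats::runif(m) < missing_rate
    }
  }
  response <- full
  response[mask] <- NA_real_

  L <- matrix(stats::rnorm(n_genes * max(rank, 1L)), n_genes)
  g0 <- stats::rnorm(n_genes, 0, sigma_gene)   # per-gene baseline level
  expression <- g0 +
    (if (rank > 0L) L[, seq_len(rank), drop = FALSE] %*% t(P)
     else matrix(0, n_genes, m)) +
    matrix(stats::rnorm(n_genes * m, 0, sigma_expr), n_genes, m)
  dimnames(expression) <- list(sprintf("G%04d", seq_len(n_genes)), cells)

  W <- matrix(stats::rnorm(n_bits * max(rank, 1L)), n_bits)
  logit <- if (rank > 0L) W[, seq_len(rank), drop = FALSE] %*% t(Q) else
    matrix(0, n_bits, n)
  pbit <- 1 / (1 + exp(-logit))
  fingerprints <- t(matrix(stats::runif(n_bits * n) < pbit, n_bits, n)) * 1
  dimnames(fingerprints) <- list(drugs, sprintf("B%03d", seq_len(n_bits)))

  structure(list(response = response, expression = expression,
                 fingerprints = fingerprints,
                 truth = list(mu = mu, a = a, b = b, P = P, Q = Q,
                              full = full)),
            class = "ncfger_sim")
}

#' @export
print.ncfger_sim <- function(x, ...) {
  cat(sprintf("simulated drug-response dataset: %d cell lines x %d drugs, %.1f%% observed\n",
              nrow(x$response), ncol(x$response),
              100 * mean(is.finite(x$response))))
  invisible(x)
}
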