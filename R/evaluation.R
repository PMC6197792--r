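#' Random entry-wise folds of near-equal size
#'
#' Partitions the observed entries (linear indices into the response
#' matrix) into `n_folds` disjoint random folds whose sizes differ by at
#' most one.  Deterministic given `seed`; the global RNG state is
#' restored on exit.
#'
#' @param entries Integer vector of entry indices.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `n_folds` disjoint integer vectors covering `entries`.
#' @export
make_folds <- function(entries, n_folds = 10L, seed = 1L) {
  stopifnot(n_folds >= 2L)
  if (length(entries) < n_folds) {
    stop("fewer entries than folds", call. = FALSE)
  }
  rs <- .save_rng()
  on.exit(.restore_rng(rs))
  set.seed(seed)
  perm <- sample(entries)
  unname(split(perm, rep_len(seq_len(n_folds), length(perm))))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", rs, envir = globalenv())
  }
}

#' Sensitive/resistant quartile labels for one drug
#'
#' Splits a drug's observed responses into quartiles: values at or below
#' the first quartile are `"sensitive"`, values at or above the third
#' quartile `"resistant"`, the rest `"neither"` (lower response = more
#' sensitive for log IC50).  Quartiles use linear interpolation of the
#' empirical distribution; boundary ties fall in the extreme group.
#' Drugs with fewer than 4 observed responses, or whose values are all
#' equal (the two boundaries coincide), are labeled all-`"neither"` and
#' thereby excluded from the S/R metrics.
#'
#' @param values Observed response values for one drug.
#' @return Character vector of labels, same length as `values`.
#' @export
sr_labels <- function(values) {
  lab <- rep("neither", length(values))
  ok <- is.finite(values)
  if (sum(ok) < 4L) return(lab)
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1L] >= q[2L]) return(lab)       # degenerate: quartiles collapse
  lab[ok & values <= q[1L]] <- "sensitive"
  lab[ok & values >= q[2L]] <- "resistant"
  lab
}

#' Per-drug prediction metrics
#'
#' Computes, for each drug, PCC and RMSE between predictions and truths
#' pooled across folds, and the same restricted to that drug's
#' sensitive/resistant cell lines (quartile labels from the observed
#' response distribution).  Drug-averaged values are unweighted means
#' over eligible drugs: a drug needs >= 2 pooled entries for PCC/RMSE and
#' >= 2 sensitive-or-resistant entries for the S/R versions.  A drug with
#' a zero-variance prediction or truth vector gets PCC 0 with a warning.
#'
#' @param drug Drug label per prediction.
#' @param truth,pred Observed and predicted values.
#' @param sr Label per prediction from [sr_labels()] (computed per drug
#'   on the observed responses).
#' @return List: `per_drug` data.frame, `drug_averaged` named vector
#'   (means and across-drug s.d.), `excluded` drug labels.
#' @export
score_predictions <- function(drug, truth, pred, sr) {
  stopifnot(length(drug) == length(truth), length(truth) == length(pred),
            length(sr) == length(truth))
  drugs <- unique(drug)
  per <- data.frame(drug = drugs, pcc = NA_real_, rmse = NA_real_,
                    pcc_sr = NA_real_, rmse_sr = NA_real_,
                    n_test = 0L, n_sr = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(drugs)) {
    sel <- drug == drugs[k]
    per$n_test[k] <- sum(sel)
    if (sum(sel) >= 2L) {
      per$pcc[k] <- .safe_pcc(pred[sel], truth[sel], drugs[k])
      per$rmse[k] <- sqrt(mean((pred[sel] - truth[sel])^2))
    }
    ssel <- sel & sr != "neither"
    per$n_sr[k] <- sum(ssel)
    if (sum(ssel) >= 2L) {
      per$pcc_sr[k] <- .safe_pcc(pred[ssel], truth[ssel], drugs[k])
      per$rmse_sr[k] <- sqrt(mean((pred[ssel] - truth[ssel])^2))
    }
  }
  avg <- c(pcc = mean(per$pcc, na.rm = TRUE),
           rmse = mean(per$rmse, na.rm = TRUE),
           pcc_sr = mean(per$pcc_sr, na.rm = TRUE),
           rmse_sr = mean(per$rmse_sr, na.rm = TRUE),
           sd_pcc = stats::sd(per$pcc, na.rm = TRUE),
           sd_rmse = stats::sd(per$rmse, na.rm = TRUE),
           sd_pcc_sr = stats::sd(per$pcc_sr, na.rm = TRUE),
           sd_rmse_sr = stats::sd(per$rmse_sr, na.rm = TRUE))
  list(per_drug = per, drug_averaged = avg,
       excluded = per$drug[is.na(per$pcc)])
}

.safe_pcc <- function(pred, truth, label) {
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warning(sprintf("zero-variance vector for drug '%s'; PCC recorded as 0",
                    label), call. = FALSE)
    return(0)
  }
  stats::cor(pred, truth)
}

#' Repeated entry-wise 10-fold cross-validation
#'
#' The observed entries are split into random folds of near-equal size;
#' each fold in turn is masked, the full model (global effects,
#' similarities, neighbor weights) is refitted on the remaining entries
#' only, and the masked entries are predicted.  Every observed entry is
#' therefore tested exactly once per repetition.  Both neighbor
#' orientations, their hybrid average, and the global-effects-only
#' baseline are recorded for every test entry, so one CV run supports all
#' orientation comparisons.
#'
#' @inheritParams ncfger
#' @param folds Number of folds (default 10).
#' @param repeats Number of full CV repetitions (default 5).
#' @param seed Integer seed; repetition r uses `seed + r - 1` for its
#'   fold assignment.  The predictor itself is deterministic.
#' @param keep_predictions Keep the per-entry prediction table (default
#'   `TRUE`; needed by [cv_rmse_by_fold()]).
#' @param ... Passed to [ncfger()] (similarity, K, beta, alpha1, ...).
#' @return An object of class `"ncfger_cv"`: `per_drug` (long table over
#'   repetitions), `drug_averaged` (means of the four metrics with s.d.
#'   across drugs and across repetitions), `predictions`, `config`.
#' @examples
#' sim <- simulate_response_data(m = 30, n = 10, missing_rate = 0.2, seed = 7)
#' cv <- cv_ncfger(sim$response, sim$expression, sim$fingerprints,
#'                 repeats = 2, seed = 7)
#' cv
#' @export
cv_ncfger <- function(response, expression = NULL, fingerprints = NULL,
                      folds = 10L, repeats = 5L, seed = 1L,
                      orientation = c("hybrid", "cell_line", "drug"),
                      keep_predictions = TRUE, quiet = TRUE, ...) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(response))
  if (is.null(rownames(response))) {
    rownames(response) <- sprintf("C%03d", seq_len(nrow(response)))
  }
  if (is.null(colnames(response))) {
    colnames(response) <- sprintf("D%03d", seq_len(ncol(response)))
  }
  if (!is.null(expression) || !is.null(fingerprints)) {
    al <- align_inputs(response, expression, fingerprints, quiet = quiet)
    response <- al$response; expression <- al$expression
    fingerprints <- al$fingerprints
  }
  obs <- which(is.finite(response))
  m <- nrow(response)

  # quartile labels per drug from the full observed response distribution
  sr_by_drug <- lapply(seq_len(ncol(response)), function(i) {
    v <- response[, i]
    lab <- rep("neither", m)
    lab[is.finite(v)] <- sr_labels(v[is.finite(v)])
    lab
  })

  all_pred <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_sets <- make_folds(obs, folds, seed + r - 1L)
    preds <- vector("list", folds)
    for (f in seq_len(folds)) {
      test <- fold_sets[[f]]
      train <- response
      train[test] <- NA_real_
      fit <- ncfger(train, expression, fingerprints,
                    orientation = "hybrid", align = FALSE, quiet = TRUE,
                    ...)
      ui <- arrayInd(test, dim(response))
      pd <- pc <- numeric(nrow(ui))
      nbd <- nbc <- integer(nrow(ui))
      for (k in seq_len(nrow(ui))) {
        o1 <- predict_orientation(ui[k, 1L], ui[k, 2L], fit$residuals,
                                  fit$S_drug, fit$config, "drug")
        o2 <- predict_orientation(ui[k, 1L], ui[k, 2L], fit$residuals,
                                  fit$S_cell, fit$config, "cell_line")
        pd[k] <- o1$value; pc[k] <- o2$value
        nbd[k] <- o1$n; nbc[k] <- o2$n
      }
      base <- effect_total(fit$effects, ui[, 1L], ui[, 2L])
      hyb <- rowMeans(cbind(pd, pc), na.rm = TRUE)
      hyb[is.nan(hyb)] <- 0
      preds[[f]] <- data.frame(
        repetition = r, fold = f, u = ui[, 1L], i = ui[, 2L],
        truth = response[test],
        pred_hybrid = base + hyb,
        pred_cell = base + ifelse(is.na(pc), 0, pc),
        pred_drug = base + ifelse(is.na(pd), 0, pd),
        pred_baseline = base,
        n_neighbors_cell = nbc, n_neighbors_drug = nbd,
        fallback = is.na(pd) & is.na(pc))
    }
    all_pred[[r]] <- do.call(rbind, preds)
  }
  pred_tab <- do.call(rbind, all_pred)
  pred_col <- paste0("pred_", sub("cell_line", "cell", orientation))
  sr_vec <- vapply(seq_len(nrow(pred_tab)), function(k) {
    sr_by_drug[[pred_tab$i[k]]][pred_tab$u[k]]
  }, character(1L))
  pred_tab$sr <- sr_vec
  pred_tab$drug <- colnames(response)[pred_tab$i]
  pred_tab$cell_line <- rownames(response)[pred_tab$u]

  per_rep <- lapply(seq_len(repeats), function(r) {
    sub <- pred_tab[pred_tab$repetition == r, ]
    sc <- score_predictions(sub$drug, sub$truth, sub[[pred_col]], sub$sr)
    sc$per_drug$repetition <- r
    sc
  })
  per_drug <- do.call(rbind, lapply(per_rep, `[[`, "per_drug"))
  rep_avg <- do.call(rbind, lapply(per_rep, `[[`, "drug_averaged"))
  drug_averaged <- list(
    pcc = mean(rep_avg[, "pcc"]), rmse = mean(rep_avg[, "rmse"]),
    pcc_sr = mean(rep_avg[, "pcc_sr"]), rmse_sr = mean(rep_avg[, "rmse_sr"]),
    sd_across_drugs = colMeans(rep_avg[, c("sd_pcc", "sd_rmse",
                                           "sd_pcc_sr", "sd_rmse_sr"),
                                       drop = FALSE]),
    sd_across_repeats = apply(rep_avg[, c("pcc", "rmse", "pcc_sr",
                                          "rmse_sr"), drop = FALSE],
                              2L, stats::sd))
  excluded <- unique(unlist(lapply(per_rep, `[[`, "excluded")))

  structure(list(
    per_drug = per_drug,
    drug_averaged = drug_averaged,
    excluded_drugs = excluded,
    predictions = if (keep_predictions) pred_tab,
    config = c(list(folds = as.integer(folds),
                    repeats = as.integer(repeats),
                    seed = as.integer(seed), orientation = orientation),
               list(...))),
    class = "ncfger_cv")
}

#' Per-fold overall RMSE for each predictor variant
#'
#' Summarizes a CV run into one RMSE per (repetition, fold) for the
#' hybrid, cell-line-oriented, drug-oriented, and global-effects-only
#' predictors — the unit used for paired predictor comparisons.
#'
#' @param cv An `"ncfger_cv"` object with predictions kept.
#' @return data.frame: `repetition`, `fold`, `rmse_hybrid`, `rmse_cell`,
#'   `rmse_drug`, `rmse_baseline`.
#' @export
cv_rmse_by_fold <- function(cv) {
  stopifnot(inherits(cv, "ncfger_cv"))
  p <- cv$predictions
  if (is.null(p)) stop("CV run did not keep predictions", call. = FALSE)
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  do.call(rbind, lapply(split(p, list(p$repetition, p$fold)), function(s) {
    data.frame(repetition = s$repetition[1L], fold = s$fold[1L],
               rmse_hybrid = rmse(s$pred_hybrid, s$truth),
               rmse_cell = rmse(s$pred_cell, s$truth),
               rmse_drug = rmse(s$pred_drug, s$truth),
               rmse_baseline = rmse(s$pred_baseline, s$truth))
  }))
}

#' @export
print.ncfger_cv <- function(x, ...) {
  da <- x$drug_averaged
  cat(sprintf("Cross-validation: %d folds x %d repetitions (seed %d, %s)\n",
              x$config$folds, x$config$repeats, x$config$seed,
              x$config$orientation))
  cat(sprintf("  drug-averaged PCC     %.3f (+/- %.3f across drugs)\n",
              da$pcc, da$sd_across_drugs[["sd_pcc"]]))
  cat(sprintf("  drug-averaged RMSE    %.3f (+/- %.3f)\n",
              da$rmse, da$sd_across_drugs[["sd_rmse"]]))
  cat(sprintf("  drug-averaged PCC_S/R %.3f (+/- %.3f)\n",
              da$pcc_sr, da$sd_across_drugs[["sd_pcc_sr"]]))
  cat(sprintf("  drug-averaged RMSE_S/R %.3f (+/- %.3f)\n",
              da$rmse_sr, da$sd_across_drugs[["sd_rmse_sr"]]))
  if (length(x$excluded_drugs)) {
    cat("  excluded drugs:", paste(x$excluded_drugs, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ncfger_cv <- function(object, ...) {
  print(object)
  fr <- tryCatch(cv_rmse_by_fold(object), error = function(e) NULL)
  if (!is.null(fr)) {
    cat("\nper-fold overall RMSE (mean):\n")
    print(colMeans(fr[, -(1:2)]))
  }
  invisible(object)
}

#' Per-drug PCC/RMSE boxplots for a CV run
#'
#' @param x An `"ncfger_cv"` object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.ncfger_cv <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(pcc ~ drug, data = x$per_drug, las = 2,
                    ylab = "per-drug PCC", xlab = "", ...)
  graphics::boxplot(rmse ~ drug, data = x$per_drug, las = 2,
                    ylab = "per-drug RMSE", xlab = "", ...)
  invisible(x)
}

#' Write a CV report as JSON
#'
#' Serializes the per-drug table, drug-averaged metrics, excluded drugs
#' and the full configuration (for provenance) to a JSON file, written
#' atomically (temp file then rename).
#'
#' @param cv An `"ncfger_cv"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  stopifnot(inherits(cv, "ncfger_cv"))
  payload <- list(config = cv$config,
                  drug_averaged = cv$drug_averaged,
                  per_drug = cv$per_drug,
                  excluded_drugs = cv$excluded_drugs)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
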