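#' Fit a multivariate negative-binomial community GLM
#'
#' Fits an independent negative-binomial GLM (log link) to every taxon of a
#' samples x taxa count table, sharing one design matrix and a per-sample
#' offset (log total reads by default), in the manner of multivariate
#' community abundance models. Dispersion is estimated per taxon by maximum
#' likelihood with a method-of-moments fallback when the ML update fails;
#' all-zero taxa are skipped with a warning. Total log-likelihood and AIC
#' are reported across taxa.
#'
#' @param trt a `taxon_read_table`, or a samples x taxa count matrix.
#' @param metadata data.frame of per-sample predictors, with `sample_id`
#'   matching the table rows.
#' @param formula model formula over metadata columns (e.g.
#'   `~ month + year`).
#' @param offset per-sample offset on the log scale; defaults to
#'   `log(rowSums(counts))`. Must be finite.
#' @param exclude_samples optional sample ids dropped before fitting (e.g. a
#'   month sampled in one year only, to keep years comparable).
#' @return a `community_model`: list with `beta`, `se` (coef x taxa),
#'   `theta`, `dispersion` (=1/theta), `loglik` per taxon, `logLik`, `AIC`,
#'   `formula`, `X`, `offset`, `counts`, `skipped`.
#' @export
fit_nb_glm <- function(trt, metadata, formula, offset = NULL,
                       exclude_samples = NULL) {
  counts <- if (inherits(trt, "taxon_read_table")) trt$counts else trt
  if (!is_count_matrix(counts))
    stop_hf("counts must be a non-negative integer matrix")
  if (!is.null(exclude_samples))
    counts <- counts[!rownames(counts) %in% exclude_samples, , drop = FALSE]
  md <- metadata[match(rownames(counts), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop_hf("metadata missing some samples")
  offset <- offset %||% log(rowSums(counts))
  if (!is.null(names(offset))) offset <- offset[rownames(counts)]
  if (any(!is.finite(offset))) stop_hf("offset must be finite (zero-read sample?)")
  X <- model.matrix(formula, data = md)
  if (qr(X)$rank < ncol(X)) stop_hf("design matrix is not full rank")
  zero <- colSums(counts) == 0
  if (any(zero))
    warning("skipping all-zero taxa: ",
            paste(colnames(counts)[zero], collapse = ", "))
  Y <- counts[, !zero, drop = FALSE]
  fit <- nb_glm_fit_cpp(Y, X, offset)
  dimnames(fit$beta) <- dimnames(fit$se) <- list(colnames(X), colnames(Y))
  names(fit$theta) <- names(fit$loglik) <- colnames(Y)
  k_par <- ncol(X) + 1L  # coefficients + dispersion, per taxon
  structure(list(beta = fit$beta, se = fit$se, theta = fit$theta,
                 dispersion = 1 / fit$theta, loglik = fit$loglik,
                 logLik = sum(fit$loglik),
                 AIC = -2 * sum(fit$loglik) + 2 * k_par * ncol(Y),
                 fallback = setNames(fit$fallback, colnames(Y)),
                 converged = setNames(fit$converged, colnames(Y)),
                 formula = formula, X = X, offset = offset, counts = Y,
                 skipped = colnames(counts)[zero]),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("community_model: %d taxa, %d samples, terms %s\n",
              ncol(x$counts), nrow(x$counts), deparse(x$formula)))
  cat(sprintf("  logLik %.2f, AIC %.2f\n", x$logLik, x$AIC))
  invisible(x)
}

#' Resampled likelihood-ratio test between nested community models
#'
#' The observed statistic is `2 * (logLik(full) - logLik(reduced))` summed
#' over taxa (per-taxon contributions clamped at zero). Its null
#' distribution is obtained by parametric bootstrap from the fitted reduced
#' model: counts are redrawn from each taxon's reduced-model NB fit, both
#' models refitted, and the multivariate LR recomputed. The p-value uses the
#' add-one estimator `(1 + #{LR* >= LR}) / (1 + n_resamples)`, so the floor
#' at 999 resamples is 0.001.
#'
#' @param full,reduced `community_model` objects on the same data; `reduced`
#'   must be nested in `full`.
#' @param n_resamples number of bootstrap resamples (default 999).
#' @param seed optional integer seed for reproducibility.
#' @return list of class `lr_test`: `lr_stat`, `p_value`, `n_resamples`,
#'   `per_taxon` (named LR contributions), `lr_resampled`.
#' @export
lr_test <- function(full, reduced, n_resamples = 999L, seed = NULL) {
  if (!identical(rownames(full$counts), rownames(reduced$counts)) ||
      !identical(colnames(full$counts), colnames(reduced$counts)))
    stop_hf("models were fitted to different data")
  # nesting check: every reduced column must lie in the span of the full design
  Xf <- full$X; Xr <- reduced$X
  fitres <- qr.resid(qr(Xf), Xr)
  if (max(abs(fitres)) > 1e-8)
    stop_hf("reduced model is not nested in the full model")
  if (!is.null(seed)) set.seed(seed)
  bt <- nb_lrt_boot_cpp(full$counts, Xf, Xr, full$offset,
                        as.integer(n_resamples))
  per_taxon <- setNames(as.numeric(bt$lr_obs), colnames(full$counts))
  lr <- sum(per_taxon)
  p <- (1 + sum(bt$lr_boot >= lr)) / (1 + n_resamples)
  structure(list(lr_stat = lr, p_value = p,
                 n_resamples = as.integer(n_resamples),
                 per_taxon = per_taxon,
                 lr_resampled = as.numeric(bt$lr_boot)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("multivariate LR = %.2f, P = %.4g (%d resamples)\n",
              x$lr_stat, x$p_value, x$n_resamples))
  invisible(x)
}

#' Bray-Curtis dissimilarities between samples
#'
#' Computed on per-sample proportions of reads:
#' `d(i,j) = sum |p_i - p_j| / sum (p_i + p_j)` over taxa. Symmetric, zero
#' diagonal, values in [0, 1].
#'
#' @param trt a `taxon_read_table` or samples x taxa count matrix with
#'   positive row sums.
#' @return sample x sample dissimilarity matrix.
#' @export
bray_curtis <- function(trt) {
  counts <- if (inherits(trt, "taxon_read_table")) trt$counts else trt
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop_hf("every sample needs at least one read")
  p <- counts / tot
  as.matrix(vegan::vegdist(p, method = "bray"))
}
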