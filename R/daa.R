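# Two-group negative-binomial Wald test with size-factor offsets.
#
# Per feature the model is log mu_i = eta_g + log s_i with NB2 variance
# mu + phi * mu^2 and a feature-specific dispersion phi. Group means are
# fitted by Fisher scoring, dispersion by profile maximum likelihood
# (method-of-moments start, golden-section refinement on log phi, floored
# at 1e-8), and the group contrast is tested with a two-sided Wald test.

# Fisher scoring for eta = log(mean per unit size factor) in one group.
.nb_fit_group <- function(y, s, phi, eta0) {
  eta <- eta0
  for (it in 1:50) {
    mu <- s * exp(eta)
    U <- sum((y - mu) / (1 + phi * mu))
    I <- sum(mu / (1 + phi * mu))
    if (!is.finite(U) || !is.finite(I) || I <= 0) return(list(eta = eta, ok = FALSE))
    step <- U / I
    step <- max(min(step, 5), -5)
    eta <- eta + step
    if (abs(step) < 1e-10) break
  }
  list(eta = eta, ok = is.finite(eta) && it < 50)
}

.nb_loglik_phi <- function(log_phi, y, mu) {
  r <- exp(-log_phi)  # size = 1/phi
  sum(lgamma(y + r) - lgamma(r) + r * log(r / (r + mu)) +
        y * log(mu / (r + mu) + (mu == 0)))
}

.nb_ml_phi <- function(y, mu, floor = 1e-8) {
  num <- sum((y - mu)^2 - mu)
  den <- sum(mu^2)
  mom <- if (den > 0) num / den else 0
  mom <- min(max(mom, floor), 1e6)
  opt <- stats::optimize(.nb_loglik_phi, interval = log(c(floor, 1e6)),
                         y = y, mu = mu, maximum = TRUE, tol = 1e-3)
  cand <- c(opt$maximum, log(mom))
  ll <- vapply(cand, .nb_loglik_phi, numeric(1), y = y, mu = mu)
  exp(cand[which.max(ll)])
}

.fit_nb_feature <- function(y, s, g2) {
  n1 <- sum(!g2); n2 <- sum(g2)
  y1 <- y[!g2]; s1 <- s[!g2]
  y2 <- y[g2]; s2 <- s[g2]
  zero1 <- sum(y1) == 0; zero2 <- sum(y2) == 0
  eta1 <- log((sum(y1) + 0.5 * zero1) / sum(s1))
  eta2 <- log((sum(y2) + 0.5 * zero2) / sum(s2))
  phi <- 0.5
  ok <- TRUE
  for (outer in 1:3) {
    if (!zero1) {
      f1 <- .nb_fit_group(y1, s1, phi, eta1); eta1 <- f1$eta
      ok <- ok && f1$ok
    }
    if (!zero2) {
      f2 <- .nb_fit_group(y2, s2, phi, eta2); eta2 <- f2$eta
      ok <- ok && f2$ok
    }
    mu <- c(s1 * exp(eta1), s2 * exp(eta2))
    phi <- .nb_ml_phi(c(y1, y2), mu)
  }
  mu1 <- s1 * exp(eta1); mu2 <- s2 * exp(eta2)
  info1 <- sum(mu1 / (1 + phi * mu1))
  info2 <- sum(mu2 / (1 + phi * mu2))
  beta <- eta2 - eta1
  se <- sqrt(1 / info1 + 1 / info2)
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))
  if (!is.finite(p)) { p <- 1; ok <- FALSE }
  c(log2fc = beta / log(2), se = se / log(2), stat = stat, pvalue = p,
    converged = as.numeric(ok && is.finite(se)), phi = phi)
}

#' Negative-binomial Wald test for differential abundance
#'
#' Tests every feature for an abundance difference between two sample
#' groups using a per-feature NB regression of counts on group with the
#' log size factor as offset. This is a plain, fully specified test kept
#' fixed across normalizations so that the benchmark isolates the effect
#' of the size factors themselves. Dispersion is estimated per feature by
#' profile maximum likelihood (method-of-moments start, floored at 1e-8);
#' the group contrast is a two-sided Wald test; no empirical-Bayes
#' shrinkage, independent filtering or outlier handling is applied.
#'
#' Features observed in fewer than two samples get `pvalue = 1` and a
#' `converged = FALSE` flag; a group with all-zero counts gets a
#' continuity-corrected mean (0.5 pseudo-reads spread over its size
#' factors), which yields a finite fold estimate with an honestly large
#' standard error. Non-convergence is flagged, never thrown.
#'
#' @param table A `count_table`.
#' @param labels Data.frame with columns `sample_id`, `group` (exactly two
#'   levels, each with at least two samples).
#' @param sf A [size_factors] object aligned to the table's samples.
#' @return A data.frame (one row per feature): `feature_id`, `log2fc`
#'   (second group level vs first), `se`, `stat`, `pvalue`, `qvalue`
#'   (Benjamini-Hochberg), `converged`.
#' @export
fit_nb_wald <- function(table, labels, sf) {
  table <- validate_count_table(table)
  if (!all(c("sample_id", "group") %in% names(labels)))
    stop("labels must have columns sample_id and group")
  labels <- labels[match(colnames(table), labels$sample_id), , drop = FALSE]
  if (anyNA(labels$sample_id)) stop("labels do not cover all samples")
  gl <- factor(labels$group)
  if (nlevels(gl) != 2L) stop("exactly two groups are required")
  if (any(table(gl) < 2L)) stop("each group needs at least two samples")
  v <- as.numeric(sf)[match(colnames(table), names(sf))]
  if (anyNA(v) || any(v <= 0))
    stop("size factors must be positive and aligned to the table")
  g2 <- gl == levels(gl)[2L]
  x <- unclass(table)
  q <- nrow(x)
  res <- matrix(NA_real_, q, 6L,
                dimnames = list(NULL, c("log2fc", "se", "stat", "pvalue",
                                        "converged", "phi")))
  for (k in seq_len(q)) {
    y <- x[k, ]
    if (sum(y > 0) < 2L) {
      res[k, ] <- c(NA, NA, NA, 1, 0, NA)
      next
    }
    res[k, ] <- .fit_nb_feature(y, v, g2)
  }
  out <- data.frame(feature_id = rownames(x),
                    log2fc = res[, "log2fc"], se = res[, "se"],
                    stat = res[, "stat"], pvalue = res[, "pvalue"],
                    qvalue = bh_adjust(res[, "pvalue"]),
                    converged = res[, "converged"] > 0)
  attr(out, "dispersion") <- res[, "phi"]
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in \[0, 1\], same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Observed false discovery rate at a q-value cutoff
#'
#' Features with `qvalue <= q_cutoff` are called; the observed FDR is
#' `FP / max(1, FP + TP)` (the denominator clamp makes an empty call set
#' score 0).
#'
#' @param result A [fit_nb_wald()] result (needs a `qvalue` column).
#' @param truth Logical vector, TRUE for truly differential features,
#'   aligned to the result rows.
#' @param q_cutoff Decision threshold on q-values (default 0.05).
#' @return The observed FDR in \[0, 1\].
#' @export
observed_fdr <- function(result, truth, q_cutoff = 0.05) {
  if (length(truth) != nrow(result))
    stop("truth is not aligned to the result")
  called <- result$qvalue <= q_cutoff
  fp <- sum(called & !truth)
  tp <- sum(called & truth)
  fp / max(1, fp + tp)
}

#' Confusion counts at a q-value cutoff
#'
#' @inheritParams observed_fdr
#' @return A list with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(result, truth, q_cutoff = 0.05) {
  if (length(truth) != nrow(result))
    stop("truth is not aligned to the result")
  called <- result$qvalue <= q_cutoff
  list(TP = sum(called & truth), FP = sum(called & !truth),
       TN = sum(!called & !truth), FN = sum(!called & truth))
}

#' ROC curve over p-value cutoffs
#'
#' Sweeps the p-value threshold over all observed values and returns the
#' (FPR, TPR) step curve, anchored at (0, 0) and (1, 1), with the
#' trapezoidal area under the curve.
#'
#' @inheritParams observed_fdr
#' @return A list: `curve` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(result, truth) {
  if (length(truth) != nrow(result))
    stop("truth is not aligned to the result")
  truth <- as.logical(truth)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L)
    stop("truth must contain at least one positive and one negative")
  p <- result$pvalue
  o <- order(p)
  ps <- p[o]; ts <- truth[o]
  idx <- cumsum(tabulate(match(ps, unique(ps)), length(unique(ps))))
  tpr <- c(0, cumsum(ts)[idx] / npos, 1)
  fpr <- c(0, cumsum(!ts)[idx] / nneg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
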