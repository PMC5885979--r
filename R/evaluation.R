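# Scoring of normalization methods: correlation with true library sizes
# on perturbed simulations, inter-sample variance ranking, paired
# signed-rank comparison of ranks, and ICC reproducibility.

# Registry used by the benchmark and the CLI; each entry maps a method
# label to a function(table) -> size_factors (or an error).
.norm_methods <- function() {
  list(
    GMPR   = function(tab) gmpr_size_factors(tab),
    TSS    = function(tab) tss_size_factors(tab),
    RLE    = function(tab) rle_size_factors(tab),
    "RLE+" = function(tab) rle_size_factors(tab, pseudo_count = 1),
    TMM    = function(tab) tmm_size_factors(tab),
    "TMM+" = function(tab) tmm_size_factors(tab, pseudo_count = 1),
    CSS    = function(tab) css_size_factors(tab)
  )
}

#' Names of the available normalization methods
#' @return Character vector of method labels.
#' @export
norm_method_names <- function() names(.norm_methods())

#' Compute size factors by method name
#'
#' Dispatch helper used by the benchmark and the command-line interface.
#'
#' @param table A `count_table`.
#' @param method One of [norm_method_names()] (case-insensitive).
#' @param rescale Apply [rescale_by_median()] to the result.
#' @param ... Passed to the underlying method function.
#' @return A [size_factors] object.
#' @export
compute_size_factors <- function(table, method, rescale = FALSE, ...) {
  reg <- .norm_methods()
  hit <- match(toupper(method), toupper(names(reg)))
  if (is.na(hit))
    stop("unknown method '", method, "'; valid methods: ",
         paste(names(reg), collapse = ", "))
  fn <- switch(names(reg)[hit],
               GMPR = function(tab) gmpr_size_factors(tab, ...),
               TSS = function(tab) tss_size_factors(tab),
               RLE = function(tab) rle_size_factors(tab, ...),
               "RLE+" = function(tab) rle_size_factors(tab, pseudo_count = 1),
               TMM = function(tab) tmm_size_factors(tab, ...),
               "TMM+" = function(tab) tmm_size_factors(tab, pseudo_count = 1),
               CSS = function(tab) css_size_factors(tab, ...))
  sf <- fn(table)
  if (rescale) sf <- rescale_by_median(sf)
  sf
}

#' Correlation between estimated size factors and true library sizes
#'
#' @param sf A [size_factors] object (or numeric vector).
#' @param true_sizes Numeric vector of the true library sizes, aligned by
#'   position (or by name when both are named).
#' @param method `"spearman"` (default, rank-based) or `"pearson"`.
#' @return The correlation coefficient, or `NA` when either vector is
#'   constant.
#' @export
sizefactor_correlation <- function(sf, true_sizes,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- as.numeric(sf)
  if (!is.null(names(sf)) && !is.null(names(true_sizes)))
    true_sizes <- true_sizes[match(names(sf), names(true_sizes))]
  t <- as.numeric(true_sizes)
  if (length(v) != length(t)) stop("vectors differ in length")
  if (length(v) < 3L) stop("need at least three samples")
  if (stats::sd(v) == 0 || stats::sd(t) == 0) return(NA_real_)
  stats::cor(v, t, method = method)
}

#' Perturbation benchmark of normalization methods
#'
#' The robustness benchmark: Dirichlet-multinomial tables are simulated
#' at a calibrated sparsity, corrupted by fixed- or random-mode
#' perturbations of increasing extent, normalized by every requested
#' method, and each method's size factors are correlated against the
#' pre-perturbation ("true") library sizes. Each grid cell is replicated
#' and summarized by the mean correlation with a normal-approximation 95%
#' confidence interval. RLE failures on sparse tables are recorded as
#' `NA`, not raised.
#'
#' @param zero_targets Named or unnamed vector of target zero fractions;
#'   dispersion is calibrated once per target.
#' @param modes,strengths,fractions Perturbation grid (see
#'   [perturbation_spec()]).
#' @param methods Character vector of method labels
#'   (see [norm_method_names()]).
#' @param reps Replicates per cell (default 25).
#' @param q,n Table dimensions (defaults 625 features, 98 samples).
#' @param seed Master seed; the full report is a pure function of it.
#' @param cor_method Correlation type (default Spearman).
#' @param params Base `dm_params` (default [default_dm_params()] at `q`).
#' @return A data.frame with one row per (zero_target, mode, strength,
#'   fraction, method): mean correlation, `ci_lo`, `ci_hi`, `reps`,
#'   and `n_ok` (replicates where the method returned).
#' @export
run_perturbation_benchmark <- function(zero_targets = 0.7,
                                       modes = "fixed",
                                       strengths = "strong",
                                       fractions = c(0, 0.16, 0.32),
                                       methods = c("GMPR", "TSS", "RLE+"),
                                       reps = 25L, q = 625L, n = 98L,
                                       seed = 1L,
                                       cor_method = c("spearman", "pearson"),
                                       params = NULL) {
  cor_method <- match.arg(cor_method)
  bad <- setdiff(methods, norm_method_names())
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  base <- params %||% default_dm_params(q = q)
  rows <- list()
  cell <- 0L
  for (zt in zero_targets) {
    calib <- calibrate_dispersion(base, zt, n = n,
                                  seed = derive_seed(seed, 9000L + round(100 * zt)))
    for (mode in modes) for (strength in strengths) {
      # one table per (preset, rep); all fractions perturb the same draw
      tabs <- lapply(seq_len(reps), function(r) {
        srep <- derive_seed(seed, cell * 1000L + r)
        ls <- sample_library_sizes(n, calib, seed = srep)
        list(tab = simulate_dm_counts(calib, ls,
                                      seed = derive_seed(srep, 1L)),
             ls = ls)
      })
      for (frac in fractions) {
        cors <- matrix(NA_real_, reps, length(methods),
                       dimnames = list(NULL, methods))
        for (r in seq_len(reps)) {
          srep <- derive_seed(seed, cell * 1000L + r)
          pt <- if (frac == 0) tabs[[r]]$tab else
            perturb_counts(tabs[[r]]$tab,
                           perturbation_spec(mode, frac, strength,
                                             seed = derive_seed(srep, 2L)))$table
          for (m in methods) {
            sf <- tryCatch(compute_size_factors(pt, m), error = function(e) NULL)
            if (!is.null(sf))
              cors[r, m] <- sizefactor_correlation(sf, tabs[[r]]$ls,
                                                   method = cor_method)
          }
        }
        for (m in methods) {
          v <- cors[, m]
          ok <- sum(!is.na(v))
          mu <- if (ok) mean(v, na.rm = TRUE) else NA_real_
          se <- if (ok > 1) stats::sd(v, na.rm = TRUE) / sqrt(ok) else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            zero_target = zt, mode = mode, strength = strength,
            fraction = frac, method = m, mean_cor = mu,
            ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
            reps = reps, n_ok = ok)
        }
      }
      cell <- cell + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-sample variance ranking of normalization methods
#'
#' For every dataset and method, size factors are computed,
#' median-rescaled, and used to normalize the counts; the across-sample
#' variance of each feature's normalized abundance is computed and its
#' median over features is the dataset-level score. Methods are ranked
#' per dataset (rank 1 = smallest median variance, average ranks on
#' ties); per-feature ranks among methods are returned as well. A `RAW`
#' pseudo-method (no normalization) is included when requested. A method
#' that fails on a dataset (e.g. RLE on a table with no common feature)
#' gets `NA` everywhere for that dataset.
#'
#' @param tables A list of `count_table`s (the datasets).
#' @param methods Character vector of method labels; `"RAW"` is allowed.
#' @return A list: `median_variance` (datasets x methods),
#'   `dataset_ranks` (same shape), `per_otu_ranks` (list, one
#'   features x methods matrix per dataset).
#' @export
variance_rank_analysis <- function(tables,
                                   methods = c("RAW", "GMPR", "TSS")) {
  if (length(methods) < 2L) stop("need at least two methods to rank")
  if (!is.list(tables)) tables <- list(tables)
  nd <- length(tables)
  med <- matrix(NA_real_, nd, length(methods),
                dimnames = list(names(tables) %||% paste0("D", seq_len(nd)),
                                methods))
  per_otu <- vector("list", nd)
  for (d in seq_len(nd)) {
    tab <- validate_count_table(tables[[d]], allow_real = TRUE)
    vars <- matrix(NA_real_, nrow(tab), length(methods),
                   dimnames = list(rownames(tab), methods))
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      norm <- if (toupper(m) == "RAW") {
        unclass(tab)
      } else {
        sf <- tryCatch(rescale_by_median(compute_size_factors(tab, m)),
                       error = function(e) NULL)
        if (is.null(sf)) next
        normalize_counts(tab, sf)
      }
      vars[, mi] <- apply(norm, 1L, stats::var)
      med[d, mi] <- stats::median(vars[, mi])
    }
    per_otu[[d]] <- t(apply(vars, 1L, function(v)
      if (all(is.na(v))) v else rank(v, na.last = "keep")))
  }
  ranks <- t(apply(med, 1L, function(v) rank(v, na.last = "keep")))
  dimnames(ranks) <- dimnames(med)
  list(median_variance = med, dataset_ranks = ranks,
       per_otu_ranks = per_otu)
}

#' Stratify features by prevalence terciles
#'
#' Prevalence is the fraction of samples in which a feature is observed
#' (nonzero). Features are split into `top`, `middle` and `bottom`
#' prevalence terciles of near-equal size; ties are broken by feature
#' order. When all prevalences are equal the split is meaningless and all
#' features are labeled `top` (degenerate case).
#'
#' @param table A `count_table` with at least three features.
#' @return Factor of length `q` with levels `top`, `middle`, `bottom`.
#' @export
prevalence_stratify <- function(table) {
  table <- validate_count_table(table, allow_real = TRUE)
  q <- nrow(table)
  if (q < 3L) stop("need at least three features")
  prev <- rowMeans(unclass(table) > 0)
  lv <- c("top", "middle", "bottom")
  if (length(unique(prev)) == 1L)
    return(stats::setNames(factor(rep("top", q), levels = lv),
                           rownames(table)))
  r <- rank(-prev, ties.method = "first")
  b1 <- ceiling(q / 3); b2 <- ceiling(2 * q / 3)
  lab <- ifelse(r <= b1, "top", ifelse(r <= b2, "middle", "bottom"))
  stats::setNames(factor(lab, levels = lv), rownames(table))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences, used to compare per-dataset
#' method ranks. Zero differences and incomplete pairs are dropped. For
#' up to 25 informative pairs the p-value is exact, computed by a dynamic
#' program over the (possibly tied, hence half-integer) ranks; beyond
#' that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param ranks_a,ranks_b Equal-length paired numeric vectors.
#' @return Two-sided p-value (1 when all differences are zero).
#' @export
paired_signed_rank <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) stop("unequal lengths")
  d <- ranks_a - ranks_b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= 25L) {
    # exact: distribution of the positive-rank sum over all 2^m sign
    # assignments, via convolution on doubled ranks (integers even
    # under average-rank ties)
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)  # counts[s + 1] = #assignments with sum s
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(length(counts) - rr)])
      counts <- counts + shifted
    }
    tot <- 2^m
    w2 <- round(2 * w)
    p_ge <- sum(counts[(w2 + 1L):length(counts)]) / tot
    p_le <- sum(counts[seq_len(w2 + 1L)]) / tot
    return(min(1, 2 * min(p_ge, p_le)))
  }
  e <- m * (m + 1) / 4
  v <- sum(r^2) / 4  # tie correction enters through the actual ranks
  z <- (w - e - sign(w - e) * 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Intraclass correlation by one-way random-effects ANOVA
#'
#' Reproducibility of a normalized abundance across technical replicates:
#' `rho = sigma_b^2 / (sigma_b^2 + sigma_e^2)`, where `sigma_b^2` is the
#' between-subject (biological) variance and `sigma_e^2` the
#' replicate-to-replicate variance. Estimated by the ANOVA method:
#' `sigma_e^2 = MSW`, `sigma_b^2 = max(0, (MSB - MSW) / k0)` with `k0`
#' the average group size adjusted for unbalanced designs; `rho` is
#' clamped to \[0, 1\]. An `rho` near one indicates excellent
#' reproducibility.
#'
#' @param values Numeric vector (e.g. one feature's normalized abundance
#'   across all replicate samples).
#' @param subjects Subject identifier per value (>= 2 subjects, and at
#'   least one subject with >= 2 replicates).
#' @return A list: `sigma_b_sq`, `sigma_e_sq`, `rho` (`NA` when the
#'   total variance is zero).
#' @export
icc <- function(values, subjects) {
  if (length(values) != length(subjects)) stop("unequal lengths")
  g <- factor(subjects)
  if (nlevels(g) < 2L) stop("need at least two subjects")
  nj <- as.numeric(table(g))
  if (all(nj < 2L)) stop("need at least one subject with two replicates")
  N <- length(values); J <- nlevels(g)
  gm <- mean(values)
  mj <- tapply(values, g, mean)
  msb <- sum(nj * (mj - gm)^2) / (J - 1)
  msw <- sum((values - mj[g])^2) / (N - J)
  k0 <- (N - sum(nj^2) / N) / (J - 1)
  sigma_e <- msw
  sigma_b <- max(0, (msb - msw) / k0)
  rho <- if (sigma_b + sigma_e > 0) sigma_b / (sigma_b + sigma_e)
  else NA_real_
  list(sigma_b_sq = sigma_b, sigma_e_sq = sigma_e,
       rho = if (is.na(rho)) rho else min(max(rho, 0), 1))
}
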