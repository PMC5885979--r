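#' Total-sum scaling size factors
#'
#' The size factor of a sample is its total read count. Simple but not
#' robust: outlier counts inflate it and truly differential abundant
#' features induce compositional effects in everything else.
#'
#' @param table A `count_table`.
#' @return A [size_factors] object (method `"TSS"`).
#' @export
tss_size_factors <- function(table) {
  table <- validate_count_table(table, allow_real = TRUE)
  s <- colSums(table)
  if (any(s <= 0))
    stop("zero-total sample(s): ", paste(colnames(table)[s <= 0], collapse = ", "))
  size_factors(s, colnames(table), method = "TSS")
}

#' Relative log expression (median-of-ratios) size factors
#'
#' Step 1 computes a reference profile: the per-feature geometric mean
#' `mu_k = (c_k1 ... c_kn)^(1/n)`, defined only for features with no zero
#' count (all features, after pseudo-count addition). Step 2 takes, per
#' sample, the median over those features of `c_ki / mu_k`.
#'
#' With `pseudo_count = 0` the method needs at least one feature observed
#' in every sample; on sparse tables none may exist, in which case RLE
#' fails with an error (this is a defined failure mode, not a bug). The
#' `RLE+` variant (`pseudo_count = 1`) adds the constant to every cell
#' before all computations and never fails.
#'
#' @param table A `count_table`.
#' @param pseudo_count Non-negative constant added to every entry before
#'   computation; `1` gives the `RLE+` variant.
#' @return A [size_factors] object (method `"RLE"` or `"RLE+"`).
#' @export
rle_size_factors <- function(table, pseudo_count = 0) {
  table <- validate_count_table(table, allow_real = TRUE)
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  x <- unclass(table) + pseudo_count
  ok <- rowSums(x == 0) == 0L
  if (!any(ok))
    defined_failure("RLE fails: no feature is nonzero in every sample ",
                    "(consider pseudo_count = 1 for RLE+)")
  xz <- x[ok, , drop = FALSE]
  mu <- exp(rowMeans(log(xz)))
  s <- apply(xz / mu, 2L, stats::median)
  size_factors(s, colnames(table),
               method = if (pseudo_count > 0) "RLE+" else "RLE")
}

#' Configuration for TMM size factors
#'
#' The canonical published defaults: 30% two-sided trim on the log ratios
#' (M), 5% two-sided trim on absolute log expression (A), reference sample
#' chosen by the 75th-percentile rule.
#'
#' @param log_ratio_trim Fraction trimmed from each tail of M.
#' @param abs_expr_trim Fraction trimmed from each tail of A.
#' @param reference_sample Optional sample id overriding the automatic
#'   reference selection.
#' @return A `tmm_config` list.
#' @export
tmm_config <- function(log_ratio_trim = 0.30, abs_expr_trim = 0.05,
                       reference_sample = NULL) {
  stopifnot(log_ratio_trim >= 0, log_ratio_trim < 0.5,
            abs_expr_trim >= 0, abs_expr_trim < 0.5)
  structure(list(log_ratio_trim = log_ratio_trim,
                 abs_expr_trim = abs_expr_trim,
                 reference_sample = reference_sample),
            class = "tmm_config")
}

#' Trimmed mean of M-values size factors
#'
#' Each sample is compared to a reference sample: over the features
#' nonzero in both, the log ratio of library-size-scaled counts (M) and
#' the average log abundance (A) are computed, both tails of M and A are
#' trimmed, and the TMM factor is `2^` the precision-weighted mean of the
#' surviving M values (weights are inverse asymptotic binomial variances).
#' The reference is the sample whose 75th percentile of scaled counts is
#' closest to the mean of those percentiles. The library-size-relative
#' TMM factor is multiplied by the sample's total count so the result is
#' on the same scale as the other methods here.
#'
#' @param table A `count_table`.
#' @param cfg A [tmm_config].
#' @param pseudo_count Non-negative constant added to every entry before
#'   all computations; `1` gives the `TMM+` variant.
#' @return A [size_factors] object (method `"TMM"` or `"TMM+"`).
#' @export
tmm_size_factors <- function(table, cfg = tmm_config(), pseudo_count = 0) {
  table <- validate_count_table(table, allow_real = TRUE)
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  x <- unclass(table) + pseudo_count
  N <- colSums(x)
  if (any(N <= 0))
    stop("zero-total sample(s): ", paste(colnames(x)[N <= 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(x)),
                function(i) unname(stats::quantile(x[, i] / N[i], 0.75)),
                numeric(1))
  ref <- if (!is.null(cfg$reference_sample)) {
    match(cfg$reference_sample, colnames(x))
  } else {
    which.min(abs(f75 - mean(f75)))
  }
  if (is.na(ref)) stop("reference sample not found")
  r <- x[, ref]; Nr <- N[ref]
  fac <- vapply(seq_len(ncol(x)), function(i) {
    if (i == ref) return(1)
    keep0 <- x[, i] > 0 & r > 0
    xi <- x[keep0, i]; ri <- r[keep0]
    if (!length(xi)) {
      warning("no shared features with reference for sample ",
              colnames(x)[i], "; TMM factor set to 1")
      return(1)
    }
    M <- log2((xi / N[i]) / (ri / Nr))
    A <- 0.5 * log2((xi / N[i]) * (ri / Nr))
    w <- (N[i] - xi) / (N[i] * xi) + (Nr - ri) / (Nr * ri)
    nM <- length(M)
    loM <- floor(nM * cfg$log_ratio_trim) + 1
    hiM <- nM + 1 - loM
    loA <- floor(nM * cfg$abs_expr_trim) + 1
    hiA <- nM + 1 - loA
    keep <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA &
      is.finite(M) & w > 0
    if (!any(keep)) {
      warning("no features survive TMM trimming for sample ",
              colnames(x)[i], "; factor set to 1")
      return(1)
    }
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  size_factors(fac * N, colnames(x),
               method = if (pseudo_count > 0) "TMM+" else "TMM")
}

#' Cumulative sum scaling size factors
#'
#' A data-driven percentile is chosen from the stability of the count
#' quantiles across samples, and each sample's size factor is the sum of
#' its counts up to that percentile of its nonzero counts. The percentile
#' search: (1) each sample's nonzero-count quantile function is evaluated
#' on a common probability grid; (2) the reference curve is the
#' per-probability mean of the sorted full count columns; (3) the
#' instability profile is the across-sample median absolute deviation from
#' the reference; (4) the chosen percentile is the smallest grid point at
#' which the relative increment of the profile exceeds `rel_threshold`,
#' floored at `floor_quantile`. When the criterion never triggers, the
#' floor is used (with a warning if the profile is entirely flat). This is
#' a CSS-compatible reimplementation of the published data-driven
#' percentile selection, not guaranteed bit-identical to the original.
#'
#' @param table A `count_table`; every sample needs a nonzero count.
#' @param rel_threshold Relative-increment trigger for the percentile
#'   search (default 0.1).
#' @param floor_quantile Lower bound on the chosen percentile
#'   (default 0.5).
#' @return A [size_factors] object (method `"CSS"`) with the chosen
#'   percentile in attribute `css_quantile`.
#' @export
css_size_factors <- function(table, rel_threshold = 0.1,
                             floor_quantile = 0.5) {
  table <- validate_count_table(table, allow_real = TRUE)
  x <- unclass(table)
  if (any(colSums(x > 0) == 0L))
    stop("all-zero sample(s): ",
         paste(colnames(x)[colSums(x > 0) == 0L], collapse = ", "))
  q <- nrow(x); n <- ncol(x)
  probs <- if (q > 1L) seq(0, 1, length.out = q) else 1
  Qs <- vapply(seq_len(n),
               function(i) unname(stats::quantile(x[x[, i] > 0, i], probs,
                                                  names = FALSE)),
               numeric(length(probs)))
  ref <- rowMeans(apply(x, 2L, sort))
  d <- apply(abs(Qs - ref), 1L, stats::median)
  l <- floor_quantile
  if (length(d) > 1L) {
    inc <- diff(d)
    base <- utils::head(d, -1L)
    rel <- ifelse(base > 0, inc / base, ifelse(inc > 0, Inf, 0))
    hit <- which(rel > rel_threshold)
    if (length(hit)) {
      l <- max(probs[min(hit) + 1L], floor_quantile)
    } else if (all(inc == 0)) {
      warning("degenerate instability profile; using floor_quantile = ",
              floor_quantile)
    }
  }
  s <- vapply(seq_len(n), function(i) {
    xi <- x[, i]
    cut <- stats::quantile(xi[xi > 0], l, names = FALSE)
    sum(xi[xi <= cut])
  }, numeric(1))
  if (any(s <= 0)) s[s <= 0] <- 1  # all counts above the cut; degenerate
  out <- size_factors(s, colnames(x), method = "CSS")
  attr(out, "css_quantile") <- l
  out
}
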