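#' Per-sample size factors
#'
#' Light S3 wrapper around a named positive numeric vector recording which
#' normalization produced it and whether it has been rescaled to unit
#' median. Size factors estimate relative sequencing depth: raw counts
#' divided by them give normalized abundances, and their log enters count
#' regressions as an offset.
#'
#' @param values Positive finite numeric vector.
#' @param sample_ids Character vector of sample identifiers.
#' @param method Label of the producing method
#'   (`"GMPR"`, `"TSS"`, `"RLE"`, `"RLE+"`, `"TMM"`, `"TMM+"`, `"CSS"`).
#' @param median_rescaled Has [rescale_by_median()] been applied?
#' @return A `size_factors` object.
#' @export
size_factors <- function(values, sample_ids = names(values), method,
                         median_rescaled = FALSE) {
  if (is.null(sample_ids)) stop("size factors require sample ids")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("size factors must be positive and finite")
  structure(as.numeric(values), names = as.character(sample_ids),
            method = method, median_rescaled = median_rescaled,
            class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("%s size factors for %d samples%s\n", attr(x, "method"),
              length(x),
              if (isTRUE(attr(x, "median_rescaled"))) " (median-rescaled)"
              else ""))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Median count ratio between two samples over their shared features
#'
#' The elementary comparison of GMPR: restricted to the features with a
#' nonzero count in both samples, the median of the per-feature count
#' ratios `c_ki / c_kj`. With fewer than `min_shared` shared features the
#' ratio is considered undefined and `NA` is returned.
#'
#' @param sample_i,sample_j Count vectors of equal length.
#' @param min_shared Minimum number of shared nonzero features required
#'   for the ratio to be defined (default 2).
#' @return A positive number, or `NA_real_` when undefined.
#' @examples
#' pairwise_ratio(c(2, 4, 0, 6), c(1, 2, 3, 0), min_shared = 1)  # 2
#' @export
pairwise_ratio <- function(sample_i, sample_j, min_shared = 2L) {
  if (length(sample_i) != length(sample_j))
    stop("count vectors differ in length")
  if (min_shared < 1L) stop("min_shared must be >= 1")
  sh <- sample_i > 0 & sample_j > 0
  if (sum(sh) < min_shared) return(NA_real_)
  stats::median(sample_i[sh] / sample_j[sh])
}

#' All pairwise median count ratios of a count table
#'
#' The intermediate object of GMPR: an `n x n` matrix of pairwise ratios
#' `r_ij` together with the matrix of shared-feature counts. Entries with
#' fewer than `min_shared` shared features are `NA`. The diagonal holds the
#' self-ratio 1 and the per-sample number of nonzero features.
#'
#' Because the median of an even-sized set is the midpoint of the two
#' central order statistics, `r_ij == 1 / r_ji` holds exactly only for odd
#' shared-set sizes; both orientations are computed from the same shared
#' ratio vector.
#'
#' @param table A `count_table`.
#' @inheritParams pairwise_ratio
#' @return A list with components `ratios` (`n x n` numeric) and
#'   `shared_counts` (`n x n` integer), sample ids as dimnames.
#' @export
pairwise_ratios <- function(table, min_shared = 2L) {
  table <- validate_count_table(table, allow_real = TRUE)
  n <- ncol(table)
  if (n < 2L) stop("need at least two samples (n >= 2)")
  x <- unclass(table)
  nz <- x > 0
  R <- matrix(NA_real_, n, n, dimnames = list(colnames(x), colnames(x)))
  S <- matrix(0L, n, n, dimnames = dimnames(R))
  for (i in seq_len(n - 1L)) {
    xi <- x[, i]; nzi <- nz[, i]
    for (j in (i + 1L):n) {
      sh <- nzi & nz[, j]
      m <- sum(sh)
      S[i, j] <- S[j, i] <- m
      if (m >= min_shared) {
        v <- xi[sh] / x[sh, j]
        R[i, j] <- stats::median(v)
        R[j, i] <- stats::median(1 / v)
      }
    }
  }
  diag(S) <- colSums(nz)
  diag(R) <- ifelse(diag(S) >= min_shared, 1, NA_real_)
  list(ratios = R, shared_counts = S)
}

#' GMPR size factors
#'
#' Geometric mean of pairwise ratios: for sample `i`, the size factor is
#' the geometric mean over partner samples `j` of the median count ratio
#' `r_ij` computed on the features nonzero in both samples (including the
#' self-ratio `r_ii = 1`). Pairs sharing fewer than `min_shared` features
#' contribute nothing: the geometric mean runs over the defined ratios
#' only. The method is designed for zero-inflated tables where no feature
#' is common to all samples, so reference-profile methods (RLE, TMM)
#' discard most of the data; every pair of samples still shares many
#' features, and GMPR pools all those pairwise comparisons.
#'
#' The geometric mean is computed in log space. Complexity is `O(n^2 q)`.
#'
#' @param table A `count_table`; every sample must have at least one
#'   nonzero count and at least one defined partner ratio.
#' @inheritParams pairwise_ratio
#' @return A [size_factors] object (method `"GMPR"`, not median-rescaled).
#' @examples
#' tab <- count_table(matrix(c(10, 20, 0, 40,
#'                              5, 10, 15, 0,
#'                             20, 40, 0, 80), ncol = 3),
#'                    sample_ids = c("S1", "S2", "S3"))
#' gmpr_size_factors(tab)  # (1, 0.5, 2)
#' @export
gmpr_size_factors <- function(table, min_shared = 2L) {
  table <- validate_count_table(table, allow_real = TRUE)
  if (any(colSums(table > 0) == 0L))
    stop("all-zero sample(s): ",
         paste(colnames(table)[colSums(table > 0) == 0L], collapse = ", "))
  pr <- pairwise_ratios(table, min_shared = min_shared)
  L <- log(pr$ratios)
  off_defined <- rowSums(!is.na(pr$ratios)) - as.integer(!is.na(diag(pr$ratios)))
  if (any(off_defined == 0L))
    stop("no defined pairwise ratio (beyond self) for sample(s): ",
         paste(colnames(table)[off_defined == 0L], collapse = ", "),
         "; too few shared nonzero features (min_shared = ", min_shared, ")")
  s <- exp(rowMeans(L, na.rm = TRUE))
  size_factors(s, colnames(table), method = "GMPR")
}

#' Rescale size factors to unit median
#'
#' Divides the factors by their median so that estimates from different
#' methods are on the same scale. The method label is preserved.
#'
#' @param sf A [size_factors] object.
#' @return A [size_factors] object with `median_rescaled = TRUE`.
#' @export
rescale_by_median <- function(sf) {
  v <- as.numeric(sf)
  size_factors(v / stats::median(v), names(sf), method = attr(sf, "method"),
               median_rescaled = TRUE)
}
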