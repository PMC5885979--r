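#' Default zero-inflated negative-binomial parameters
#'
#' A stool-like preset for the two-group differential-abundance benchmark.
#' Each feature `k` has a prevalence parameter `p_k` (probability of a
#' structural zero), an abundance `mu_k` and a dispersion `phi_k` under
#' the NB parameterization with variance `mu + phi * mu^2`. The two most
#' abundant features are fixed at relative abundances 0.168 and 0.083 —
#' dominant taxa whose perturbation in one group creates the strong
#' compositional effects probed by the unbalanced scene — and the
#' remaining mass decays as a power law over the ranked tail. Structural-
#' zero probability rises and dispersion grows with rarity rank.
#' Sample-to-sample sequencing-depth heterogeneity is modeled by a
#' log-normal multiplier on `mu` (the "true" size factor the benchmark
#' scores against).
#'
#' @param q Number of features.
#' @param profile Community preset; only `"stool-like"` is provided.
#' @param mean_depth Expected total reads per sample at multiplier 1.
#' @param power_exponent Decay of the ranked tail abundances.
#' @param prevalence_range Structural-zero probability at the most/least
#'   abundant rank (linear interpolation in between).
#' @param dispersion_range NB dispersion `phi` at the most/least abundant
#'   rank.
#' @param depth_sdlog Log-sd of the log-normal depth multiplier.
#' @return A `zinb_params` list with vectors `prevalence`, `abundance`,
#'   `dispersion` and scalar `depth_sdlog`.
#' @export
default_zinb_params <- function(q = 625L, profile = "stool-like",
                                mean_depth = 10000,
                                power_exponent = 1.0,
                                prevalence_range = c(0.05, 0.75),
                                dispersion_range = c(0.5, 2),
                                depth_sdlog = 0.7) {
  profile <- match.arg(profile)
  stopifnot(q >= 3L, mean_depth > 0, power_exponent > 0,
            all(prevalence_range >= 0), all(prevalence_range <= 1),
            all(dispersion_range > 0), depth_sdlog >= 0)
  tail_rel <- seq_len(q - 2L)^(-power_exponent)
  rel <- c(0.168, 0.083, (1 - 0.168 - 0.083) * tail_rel / sum(tail_rel))
  rank01 <- (seq_len(q) - 1) / (q - 1)
  zinb_params(prevalence = prevalence_range[1] +
                diff(prevalence_range) * rank01,
              abundance = rel * mean_depth,
              dispersion = dispersion_range[1] +
                diff(dispersion_range) * rank01,
              depth_sdlog = depth_sdlog)
}

#' @rdname default_zinb_params
#' @param prevalence,abundance,dispersion Per-feature ZINB parameters
#'   (`p_k` in \[0, 1\], `mu_k > 0`, `phi_k > 0`).
#' @export
zinb_params <- function(prevalence, abundance, dispersion,
                        depth_sdlog = 0.7) {
  q <- length(prevalence)
  if (length(abundance) != q || length(dispersion) != q)
    stop("prevalence, abundance and dispersion must have equal length")
  if (any(prevalence < 0 | prevalence > 1)) stop("prevalence outside [0, 1]")
  if (any(abundance <= 0) || any(dispersion <= 0))
    stop("abundance and dispersion must be positive")
  structure(list(prevalence = prevalence, abundance = abundance,
                 dispersion = dispersion, depth_sdlog = depth_sdlog),
            class = "zinb_params")
}

#' Design of a two-group differential-abundance simulation
#'
#' Selects the truly differential features. In the balanced scene a
#' random 5% of features are differential with fold change 4, each in a
#' uniformly chosen group, so the up/down changes roughly cancel. The
#' unbalanced scene additionally forces the two most abundant features
#' (relative abundances 0.168 and 0.083 under the default parameters) to
#' be differential in one fixed group, creating strong compositional
#' effects: under total-sum normalization every other feature's relative
#' abundance shifts in the opposite direction.
#'
#' @param q Number of features.
#' @param n_per_group Samples per group (default 49).
#' @param diff_fraction Fraction of randomly differential features
#'   (default 0.05; the count is rounded half-up).
#' @param fold Fold change applied to differential features (default 4).
#' @param scene `"balanced"` or `"unbalanced"`.
#' @param seed Optional integer seed.
#' @return A `daa_design` list: `diff_set` (feature indices),
#'   `diff_group` (1 or 2, aligned to `diff_set`), `unbalanced_features`,
#'   `truth` (logical per feature), plus the design constants.
#' @export
make_daa_design <- function(q, n_per_group = 49L, diff_fraction = 0.05,
                            fold = 4, scene = c("balanced", "unbalanced"),
                            seed = NULL) {
  scene <- match.arg(scene)
  m <- round_half_up(diff_fraction * q)
  stopifnot(q >= 3L, m >= 1L, n_per_group >= 2L, fold > 0)
  with_seed(seed, {
    diff_set <- sort(sample.int(q, m))
    diff_group <- sample(1:2, m, replace = TRUE)
    unbalanced <- integer(0)
    if (scene == "unbalanced") {
      unbalanced <- c(1L, 2L)  # the two most abundant ranks
      for (u in unbalanced) {
        at <- match(u, diff_set)
        if (is.na(at)) {
          diff_set <- c(diff_set, u)
          diff_group <- c(diff_group, 2L)
        } else {
          diff_group[at] <- 2L
        }
      }
      o <- order(diff_set)
      diff_set <- diff_set[o]; diff_group <- diff_group[o]
    }
    truth <- logical(q)
    truth[diff_set] <- TRUE
    structure(list(q = q, n_per_group = n_per_group,
                   diff_fraction = diff_fraction, fold = fold,
                   scene = scene, diff_set = diff_set,
                   diff_group = diff_group,
                   unbalanced_features = unbalanced, truth = truth),
              class = "daa_design")
  })
}

#' Simulate a two-group zero-inflated negative-binomial count table
#'
#' Feature `k` in sample `i` of group `g` is zero with probability `p_k`
#' (structural zero) and otherwise negative-binomial with mean
#' `mu_k * t_i * fold^(k differential in g)` and variance
#' `mu + phi_k * mu^2`, where `t_i` is the sample's log-normal depth
#' multiplier. The multipliers are returned as the true size factors
#' against which estimated factors can be scored.
#'
#' @param params A `zinb_params` object.
#' @param design A `daa_design` object with matching `q`.
#' @param seed Optional integer seed.
#' @return A list: `table` (`count_table`), `labels` (data.frame
#'   `sample_id`, `group`), `truth` (logical per feature),
#'   `true_factors` (the depth multipliers `t_i`).
#' @export
simulate_zinb_counts <- function(params, design, seed = NULL) {
  stopifnot(inherits(params, "zinb_params"), inherits(design, "daa_design"))
  q <- length(params$prevalence)
  if (design$q != q) stop("design and params disagree on q")
  n <- 2L * design$n_per_group
  group <- rep(1:2, each = design$n_per_group)
  fold_mat <- matrix(1, q, n)
  for (a in seq_along(design$diff_set)) {
    k <- design$diff_set[a]
    fold_mat[k, group == design$diff_group[a]] <- design$fold
  }
  with_seed(seed, {
    t_i <- stats::rlnorm(n, meanlog = 0, sdlog = params$depth_sdlog)
    mu <- (params$abundance * fold_mat) *
      matrix(t_i, q, n, byrow = TRUE)
    counts <- matrix(stats::rnbinom(q * n, mu = mu,
                                    size = rep(1 / params$dispersion, n)),
                     q, n)
    zero <- matrix(stats::runif(q * n), q, n) <
      matrix(params$prevalence, q, n)
    counts[zero] <- 0
    tab <- count_table(counts,
                       sample_ids = paste0("S", seq_len(n)))
    list(table = tab,
         labels = data.frame(sample_id = colnames(tab),
                             group = paste0("G", group)),
         truth = design$truth,
         true_factors = stats::setNames(t_i, colnames(tab)))
  })
}
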