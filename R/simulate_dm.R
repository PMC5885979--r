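#' Default Dirichlet-multinomial parameters for a stool-like community
#'
#' A synthetic preset emulating a filtered human-gut OTU table: a ranked
#' power-law mean composition (a few dominant taxa, a long tail of rare
#' ones) and a truncated log-normal library-size model. The dispersion
#' defaults to a moderate value and is normally tuned afterwards with
#' [calibrate_dispersion()] to hit a target zero fraction (~60%, 70% or
#' 80% of cells), mimicking tables of increasing sparsity.
#'
#' @param q Number of features (default 625).
#' @param profile Community preset; only `"stool-like"` is provided.
#' @param power_exponent Decay exponent of the ranked proportions
#'   (`pi_k` proportional to `k^-a`).
#' @param theta Dirichlet-multinomial overdispersion in (0, 1).
#' @param lib_meanlog,lib_sdlog,lib_min,lib_max Log-normal library-size
#'   model (log mean, log sd, truncation bounds in reads).
#' @return A `dm_params` list with components `pi`, `theta`,
#'   `lib_meanlog`, `lib_sdlog`, `lib_min`, `lib_max`.
#' @export
default_dm_params <- function(q = 625L, profile = "stool-like",
                              power_exponent = 1.0, theta = 0.02,
                              lib_meanlog = log(10000), lib_sdlog = 0.7,
                              lib_min = 1000, lib_max = 100000) {
  profile <- match.arg(profile)
  stopifnot(q >= 2L, power_exponent > 0, theta > 0, theta < 1,
            lib_sdlog >= 0, lib_min >= 1, lib_max >= lib_min)
  p <- seq_len(q)^(-power_exponent)
  dm_params(pi = p / sum(p), theta = theta, lib_meanlog = lib_meanlog,
            lib_sdlog = lib_sdlog, lib_min = lib_min, lib_max = lib_max)
}

#' @rdname default_dm_params
#' @param pi Simplex vector of mean proportions.
#' @export
dm_params <- function(pi, theta, lib_meanlog = log(10000), lib_sdlog = 0.7,
                      lib_min = 1000, lib_max = 100000) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a simplex vector (non-negative, summing to 1)")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  structure(list(pi = pi / sum(pi), theta = theta,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                 lib_min = lib_min, lib_max = lib_max),
            class = "dm_params")
}

#' Draw library sizes from the truncated log-normal model
#'
#' These draws play the role of the "true" library sizes of the benchmark:
#' counts are simulated to sum to them exactly, and size factors are later
#' scored by their correlation with them.
#'
#' @param n Number of samples (>= 2).
#' @param params A `dm_params` object.
#' @param seed Optional integer seed (bit-reproducible draws).
#' @return Positive integer vector of length `n`.
#' @export
sample_library_sizes <- function(n, params, seed = NULL) {
  stopifnot(n >= 2L, inherits(params, "dm_params"))
  with_seed(seed, {
    if (params$lib_sdlog == 0) {
      sizes <- rep(round_half_up(exp(params$lib_meanlog)), n)
    } else {
      lo <- stats::plnorm(params$lib_min, params$lib_meanlog, params$lib_sdlog)
      hi <- stats::plnorm(params$lib_max, params$lib_meanlog, params$lib_sdlog)
      u <- stats::runif(n, lo, hi)
      sizes <- round_half_up(stats::qlnorm(u, params$lib_meanlog,
                                           params$lib_sdlog))
    }
    pmax(pmin(sizes, params$lib_max), params$lib_min)
  })
}

#' Simulate a Dirichlet-multinomial count table
#'
#' For each sample a composition is drawn from a Dirichlet with
#' concentration `pi * (1 - theta) / theta` and counts are then drawn
#' multinomially at the sample's library size, so column sums equal the
#' library sizes exactly. Larger `theta` means more between-sample
#' compositional variability and hence more zeros.
#'
#' @param params A `dm_params` object.
#' @param library_sizes Positive integer vector (one per sample).
#' @param seed Optional integer seed.
#' @return A `count_table` (`q x n`).
#' @export
simulate_dm_counts <- function(params, library_sizes, seed = NULL) {
  stopifnot(inherits(params, "dm_params"), all(library_sizes > 0))
  q <- length(params$pi)
  n <- length(library_sizes)
  alpha <- params$pi * (1 - params$theta) / params$theta
  with_seed(seed, {
    counts <- matrix(0, q, n)
    for (i in seq_len(n)) {
      g <- stats::rgamma(q, shape = alpha, rate = 1)
      if (sum(g) == 0) g[which.max(alpha)] <- 1  # numeric underflow guard
      counts[, i] <- stats::rmultinom(1L, size = library_sizes[i],
                                      prob = g / sum(g))
    }
    count_table(counts)
  })
}

#' Tune the Dirichlet-multinomial dispersion to a target zero fraction
#'
#' Monotone bisection on `theta`: the realized fraction of zero cells in
#' simulated tables (at `n` samples, library sizes drawn from the model)
#' is a nondecreasing function of the overdispersion, so the target
#' sparsity presets (~60%, 70%, 80% zeros) can each be hit by root
#' finding. Simulation noise is kept small by averaging several tables per
#' evaluation under a fixed internal seed (common random numbers).
#'
#' @param params A `dm_params` object.
#' @param target_zero_fraction Desired fraction of zero cells in (0, 1).
#' @param n Number of samples per evaluation table.
#' @param tol Acceptable deviation of the expected realized fraction.
#' @param reps Tables averaged per evaluation (default 5).
#' @param seed Internal seed for the calibration simulations.
#' @return `params` with `theta` replaced; the realized zero fraction at
#'   the returned `theta` is in attribute `realized_zero_fraction`.
#' @export
calibrate_dispersion <- function(params, target_zero_fraction, n = 98L,
                                 tol = 0.01, reps = 5L, seed = 20260101L) {
  stopifnot(inherits(params, "dm_params"),
            target_zero_fraction > 0, target_zero_fraction < 1)
  zero_at <- function(theta) {
    p <- params; p$theta <- theta
    mean(vapply(seq_len(reps), function(r) {
      ls <- sample_library_sizes(n, p, seed = derive_seed(seed, r))
      tab <- simulate_dm_counts(p, ls, seed = derive_seed(seed, 100L + r))
      mean(tab == 0)
    }, numeric(1)))
  }
  lo <- 1e-6; hi <- 0.999
  f_lo <- zero_at(lo); f_hi <- zero_at(hi)
  if (target_zero_fraction < f_lo - tol || target_zero_fraction > f_hi + tol)
    stop(sprintf(paste0("target zero fraction %.3f unattainable; attainable ",
                        "range for this mean vector is about [%.3f, %.3f]"),
                 target_zero_fraction, f_lo, f_hi))
  f_mid <- NA_real_
  for (it in seq_len(40L)) {
    mid <- sqrt(lo * hi)  # bisect on log scale; theta spans decades
    f_mid <- zero_at(mid)
    if (abs(f_mid - target_zero_fraction) <= tol / 2) {
      lo <- hi <- mid
      break
    }
    if (f_mid < target_zero_fraction) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-4) break
  }
  theta <- sqrt(lo * hi)
  out <- params
  out$theta <- theta
  attr(out, "realized_zero_fraction") <-
    if (lo == hi) f_mid else zero_at(theta)
  out
}

#' Specification of a count-perturbation scheme
#'
#' Describes how a simulated table is corrupted before normalization
#' methods are scored. `fixed` mode perturbs one global feature subset in
#' a per-feature direction shared by all samples (emulating differentially
#' abundant taxa); `random` mode draws an independent subset and direction
#' per sample (emulating sample-specific outliers). Strong perturbation
#' maps a count `c` to `sqrt(c)` (decrease) or `c^2` (increase); moderate
#' maps it to `0.25 c` or `4 c`.
#'
#' @param mode `"fixed"` or `"random"`.
#' @param fraction Fraction of features perturbed; the benchmark grid uses
#'   0, .01, .02, .04, .08, .16, .32, .64.
#' @param strength `"strong"` or `"moderate"`.
#' @param seed Optional integer seed.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(mode = c("fixed", "random"), fraction,
                              strength = c("strong", "moderate"),
                              seed = NULL) {
  mode <- match.arg(mode)
  strength <- match.arg(strength)
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(mode = mode, fraction = fraction, strength = strength,
                 seed = seed), class = "perturbation_spec")
}

#' Apply a perturbation scheme to a count table
#'
#' Perturbed values are rounded half-up to the nearest integer; zeros stay
#' zeros, so the zero structure is preserved. This is the only step of the
#' benchmark that breaks the equality between a column sum and the true
#' library size — that corruption is what the normalizations are then
#' scored against.
#'
#' @param table A `count_table` of raw counts.
#' @param spec A [perturbation_spec].
#' @return A list: `table` (perturbed `count_table`), `perturbed`
#'   (fixed mode: integer vector of feature indices plus a `directions`
#'   attribute of +1/-1; random mode: per-sample list of such vectors).
#' @export
perturb_counts <- function(table, spec) {
  table <- validate_count_table(table)
  stopifnot(inherits(spec, "perturbation_spec"))
  q <- nrow(table)
  m <- round_half_up(spec$fraction * q)
  if (spec$fraction > 0 && m == 0) {
    warning("fraction ", spec$fraction, " selects no feature at q = ", q,
            "; table returned unchanged")
    return(list(table = table, perturbed = integer(0)))
  }
  if (m == 0) return(list(table = table, perturbed = integer(0)))
  apply_dir <- function(v, dir) {
    out <- if (spec$strength == "strong") {
      ifelse(dir > 0, v^2, round_half_up(sqrt(v)))
    } else {
      ifelse(dir > 0, 4 * v, round_half_up(0.25 * v))
    }
    out[v == 0] <- 0
    out
  }
  x <- unclass(table)
  with_seed(spec$seed, {
    if (spec$mode == "fixed") {
      idx <- sort(sample.int(q, m))
      dir <- sample(c(-1L, 1L), m, replace = TRUE)
      x[idx, ] <- apply_dir(x[idx, , drop = FALSE],
                            matrix(dir, m, ncol(x)))
      perturbed <- structure(idx, directions = dir)
    } else {
      perturbed <- vector("list", ncol(x))
      names(perturbed) <- colnames(x)
      for (i in seq_len(ncol(x))) {
        idx <- sort(sample.int(q, m))
        dir <- sample(c(-1L, 1L), m, replace = TRUE)
        x[idx, i] <- apply_dir(x[idx, i], dir)
        perturbed[[i]] <- structure(idx, directions = dir)
      }
    }
    list(table = count_table(x), perturbed = perturbed)
  })
}
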