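# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, explicit sorting) and
# share no code with the implementations they check.

# The worked 3x4 example table used throughout: GMPR = RLE = (1, 0.5, 2),
# TSS = (70, 30, 140).
example_table <- function() {
  count_table(matrix(c(10, 20, 0, 40,
                        5, 10, 15, 0,
                       20, 40, 0, 80), ncol = 3),
              feature_ids = paste0("F", 1:4),
              sample_ids = c("S1", "S2", "S3"))
}

# Random sparse count table for oracle-equivalence sweeps.
random_table <- function(q, n, zero_prob = 0.3, max_count = 50) {
  m <- matrix(rpois(q * n, lambda = max_count / 4), q, n)
  m[matrix(runif(q * n) < zero_prob, q, n)] <- 0
  # ensure every sample keeps at least two nonzero features so pairwise
  # ratios are defined at min_shared = 1
  for (i in seq_len(n)) {
    if (sum(m[, i] > 0) < 2) m[sample.int(q, 2), i] <- 1 + rpois(2, 5)
  }
  count_table(m)
}

brute_gmpr <- function(mat, min_shared = 1) {
  mat <- unclass(mat)
  n <- ncol(mat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    logs <- c()
    for (j in seq_len(n)) {
      shared <- which(mat[, i] != 0 & mat[, j] != 0)
      if (length(shared) >= min_shared) {
        ratios <- mat[shared, i] / mat[shared, j]
        logs <- c(logs, log(median(ratios)))
      }
    }
    s[i] <- if (length(logs)) exp(mean(logs)) else NA_real_
  }
  s
}

brute_rle <- function(mat, pseudo = 0) {
  mat <- unclass(mat) + pseudo
  keep <- apply(mat, 1, function(r) all(r > 0))
  if (!any(keep)) return(NULL)
  mu <- apply(mat[keep, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(mat[keep, , drop = FALSE], 2, function(col) median(col / mu))
}

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  # step-up: q_(i) = min over j >= i of m * p_(j) / j
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) m * p[o[j]] / j)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Exact two-sided signed-rank p by full enumeration of sign assignments.
brute_signed_rank <- function(a, b) {
  d <- (a - b)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  stopifnot(m <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- signs %*% r
  p_ge <- mean(w_all >= w_obs - 1e-9)
  p_le <- mean(w_all <= w_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# One-way ANOVA variance components on a balanced design, from scratch.
brute_icc_balanced <- function(values, subjects) {
  g <- factor(subjects)
  k <- as.numeric(table(g))[1]
  stopifnot(all(table(g) == k))
  mj <- tapply(values, g, mean)
  J <- nlevels(g)
  msb <- k * sum((mj - mean(values))^2) / (J - 1)
  msw <- sum((values - mj[g])^2) / (length(values) - J)
  sb <- max(0, (msb - msw) / k)
  list(sigma_b_sq = sb, sigma_e_sq = msw, rho = sb / (sb + msw))
}

# Literal step-by-step TMM re-derivation with explicit sorting and trims.
brute_tmm <- function(mat, trim_m = 0.3, trim_a = 0.05, pseudo = 0) {
  x <- unclass(mat) + pseudo
  N <- colSums(x)
  f75 <- sapply(seq_len(ncol(x)), function(i) quantile(x[, i] / N[i], 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  sapply(seq_len(ncol(x)), function(i) {
    if (i == ref) return(1 * N[i])
    keep <- x[, i] > 0 & x[, ref] > 0
    xi <- x[keep, i]; xr <- x[keep, ref]
    M <- log2((xi / N[i]) / (xr / N[ref]))
    A <- 0.5 * log2((xi / N[i]) * (xr / N[ref]))
    w <- (N[i] - xi) / (N[i] * xi) + (N[ref] - xr) / (N[ref] * xr)
    nf <- length(M)
    cut_m <- floor(nf * trim_m)
    cut_a <- floor(nf * trim_a)
    ord_m <- order(M)
    ord_a <- order(A)
    keep_m <- logical(nf); keep_m[ord_m[(cut_m + 1):(nf - cut_m)]] <- TRUE
    keep_a <- logical(nf); keep_a[ord_a[(cut_a + 1):(nf - cut_a)]] <- TRUE
    sel <- keep_m & keep_a & is.finite(M)
    if (!any(sel)) return(N[i])
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel])) * N[i]
  })
}

# Literal CSS oracle following the five documented steps one by one.
brute_css <- function(mat, rel_threshold = 0.1, floor_q = 0.5) {
  x <- unclass(mat)
  q <- nrow(x); n <- ncol(x)
  probs <- seq(0, 1, length.out = q)
  Qs <- matrix(0, q, n)
  for (i in seq_len(n)) Qs[, i] <- quantile(x[x[, i] > 0, i], probs)
  sorted <- apply(x, 2, sort)
  ref <- rowMeans(sorted)
  d <- numeric(q)
  for (l in seq_len(q)) d[l] <- median(abs(Qs[l, ] - ref[l]))
  l_star <- floor_q
  for (l in 2:q) {
    base <- d[l - 1]
    inc <- d[l] - base
    rel <- if (base > 0) inc / base else if (inc > 0) Inf else 0
    if (rel > rel_threshold) {
      l_star <- max(probs[l], floor_q)
      break
    }
  }
  sapply(seq_len(n), function(i) {
    xi <- x[, i]
    cut <- quantile(xi[xi > 0], l_star)
    sum(xi[xi <= cut])
  })
}

cli_script <- function() {
  system.file("cli", "gmprnorm.R", package = "gmprnorm")
}

run_cli <- function(args) {
  out <- suppressWarnings(
    system2("Rscript", c(cli_script(), args), stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
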