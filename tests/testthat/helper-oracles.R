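# Independent oracles used by the recovery tests. These deliberately share
# no code with the package implementations they check.

dice_coef <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Scalar breadth-first flood fill for 3D binary volumes; returns the number
# of connected components.
flood_fill_count_3d <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  visited <- array(FALSE, dims)
  count <- 0L
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    v <- fg[i, ]
    if (visited[v[1], v[2], v[3]]) next
    count <- count + 1L
    queue <- list(v)
    visited[v[1], v[2], v[3]] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > dims)) next
        if (mask[q[1], q[2], q[3]] && !visited[q[1], q[2], q[3]]) {
          visited[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
  }
  count
}

# Independent exhaustive Renyi-entropy threshold search over all 256
# candidate levels (0-based threshold; background = levels <= t).
renyi_threshold_oracle <- function(counts256, alpha) {
  p <- counts256 / sum(counts256)
  best_t <- NA_integer_
  best_val <- -Inf
  for (t in 0:254) {
    pb <- sum(p[1:(t + 1)])
    pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    hb <- 0; hf <- 0
    if (abs(alpha - 1) < 1e-12) {
      for (l in 1:(t + 1)) if (p[l] > 0) {
        q <- p[l] / pb; hb <- hb - q * log(q)
      }
      for (l in (t + 2):256) if (p[l] > 0) {
        q <- p[l] / pf; hf <- hf - q * log(q)
      }
    } else {
      sb <- 0; sf <- 0
      for (l in 1:(t + 1)) if (p[l] > 0) sb <- sb + (p[l] / pb)^alpha
      for (l in (t + 2):256) if (p[l] > 0) sf <- sf + (p[l] / pf)^alpha
      hb <- log(sb) / (1 - alpha); hf <- log(sf) / (1 - alpha)
    }
    if (hb + hf > best_val) {
      best_val <- hb + hf
      best_t <- t
    }
  }
  best_t
}

# Independent Kapur maximum-Shannon-entropy threshold.
shannon_threshold_oracle <- function(counts256) {
  p <- counts256 / sum(counts256)
  best_t <- NA_integer_; best_val <- -Inf
  for (t in 0:254) {
    pb <- sum(p[1:(t + 1)]); pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    qb <- p[1:(t + 1)]; qb <- qb[qb > 0] / pb
    qf <- p[(t + 2):256]; qf <- qf[qf > 0] / pf
    val <- -sum(qb * log(qb)) - sum(qf * log(qf))
    if (val > best_val) { best_val <- val; best_t <- t }
  }
  best_t
}

# Fine-grid numerical contact extent for a pointwise gap profile.
numeric_extent_oracle <- function(gap_fun, span, cutoff, step = 0.01) {
  s <- seq(0, span, by = step)
  sum(gap_fun(s) <= cutoff) * step
}

# Random 256-bin histograms with two noisy intensity modes.
random_bimodal_hist <- function(seed) {
  withr::with_seed(seed, {
    m1 <- sample(30:90, 1); m2 <- sample(140:220, 1)
    s1 <- runif(1, 5, 20); s2 <- runif(1, 5, 25)
    x <- c(round(rnorm(3000, m1, s1)), round(rnorm(runif(1, 200, 2000), m2, s2)))
    tabulate(pmin(pmax(x, 0), 255) + 1L, 256L)
  })
}

# Independent one-component Poisson-MLE decay fit (Nelder-Mead, linear
# parameters) used as the monoexponential oracle.
mono_fit_oracle <- function(hist) {
  t <- ermechquant::bin_centers(hist)
  cts <- hist$counts
  nll <- function(par) {
    mu <- pmax(par[2] * exp(-t / par[1]) + par[3], 1e-12)
    sum(mu) - sum(cts * log(mu))
  }
  init <- c(5, max(cts), 1)
  stats::optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))$par[1]
}
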