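# Independent reference implementations used as oracles. These deliberately
# use direct summation / exhaustive enumeration rather than the package's
# algorithms.

pair_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  table(factor(g1[ok], 0:2), factor(g2[ok], 0:2))
}

# log-likelihood of the 3x3 genotype table for each candidate p11
# (allele frequencies fixed); vectorized over p11
oracle_loglik <- function(counts, p11, pA, pB) {
  p10 <- pA - p11
  p01 <- pB - p11
  p00 <- 1 - pA - pB + p11
  clamp <- function(x) pmax(x, 0)
  p00 <- clamp(p00); p01 <- clamp(p01); p10 <- clamp(p10)
  p11 <- clamp(p11)
  P <- cbind(p00^2, 2 * p00 * p01, p01^2,
             2 * p00 * p10, 2 * (p00 * p11 + p01 * p10), 2 * p01 * p11,
             p10^2, 2 * p10 * p11, p11^2)
  nvec <- as.vector(t(counts))  # row-major: (0,0),(0,1),...,(2,2)
  P[, nvec == 0] <- 1           # unobserved cells contribute 0
  lp <- suppressWarnings(log(P))
  lp[!is.finite(lp)] <- -1e10
  as.numeric(lp %*% nvec)
}

# fine-grid maximum-likelihood haplotype frequencies (margins are fixed by
# the data, so the likelihood has a single free parameter p11)
oracle_em <- function(g1, g2, step = 1e-5) {
  counts <- pair_counts(g1, g2)
  ok <- !is.na(g1) & !is.na(g2)
  pA <- sum(g1[ok]) / (2 * sum(ok))
  pB <- sum(g2[ok]) / (2 * sum(ok))
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  ll <- oracle_loglik(counts, grid, pA, pB)
  p11 <- grid[which.max(ll)]
  c(p00 = 1 - pA - pB + p11, p01 = pB - p11, p10 = pA - p11, p11 = p11)
}

# direct normalization of the |D'| likelihood on the same grid definition
oracle_ci <- function(g1, g2, grid_n = 101) {
  counts <- pair_counts(g1, g2)
  ok <- !is.na(g1) & !is.na(g2)
  pA <- sum(g1[ok]) / (2 * sum(ok))
  pB <- sum(g2[ok]) / (2 * sum(ok))
  em <- oracle_em(g1, g2)
  s <- if (em[["p11"]] - pA * pB >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d <- seq(0, 1, length.out = grid_n)
  ll <- oracle_loglik(counts, pA * pB + s * d * dmax, pA, pB)
  w <- exp(ll - max(ll))
  cum <- cumsum(w / sum(w))
  list(ci_low = d[min(which(cum >= 0.05))],
       ci_high = d[min(which(cum >= 0.95))],
       density = w / sum(w))
}

# exhaustive block enumeration: same pair classification as the package
# (via dprime_ci), but spans enumerated and resolved by brute force
oracle_blocks <- function(geno, pos, cfg = ld_config()) {
  m <- ncol(geno)
  cls <- matrix(0L, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (pos[j] - pos[i] > cfg$window) next
      st <- dprime_ci(geno[, i], geno[, j], cfg)
      if (!isTRUE(st$defined) || st$n_informative < cfg$min_informative) next
      if (st$ci_low >= cfg$strong_ci_low &&
          st$ci_high >= cfg$strong_ci_high) {
        cls[i, j] <- 1L
      } else if (st$ci_high < cfg$recomb_ci_high) {
        cls[i, j] <- 2L
      }
    }
  }
  spans <- list()
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (pos[j] - pos[i] > cfg$window) next
      sub <- cls[i:j, i:j]
      ninf <- sum(sub %in% 1:2)
      nstrong <- sum(sub == 1L)
      if (ninf > 0 && nstrong + 1e-9 >= cfg$strong_fraction * ninf) {
        spans[[length(spans) + 1]] <-
          data.frame(i = i, j = j, span = pos[j] - pos[i])
      }
    }
  }
  if (length(spans) == 0) return(data.frame(i = integer(), j = integer()))
  spans <- do.call(rbind, spans)
  spans <- spans[order(-spans$span, spans$i, -spans$j), , drop = FALSE]
  taken <- rep(FALSE, m)
  keep <- logical(nrow(spans))
  for (k in seq_len(nrow(spans))) {
    idx <- spans$i[k]:spans$j[k]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      keep[k] <- TRUE
    }
  }
  out <- spans[keep, c("i", "j"), drop = FALSE]
  out[order(out$i), , drop = FALSE]
}

# brute-force allele tally
oracle_aaf <- function(geno) {
  apply(geno, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    sum(g) / (2 * length(g))
  })
}
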