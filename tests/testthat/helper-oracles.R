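# Independent brute-force oracles: deliberately written as plain nested
# loops over explicit windows, sharing no code with the package's
# vectorized implementations.

clampi <- function(i, n) pmin(pmax(i, 1L), n)

oracle_local_stats <- function(g, radius) {
  m <- nrow(g); n <- ncol(g)
  mu <- v <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius) {
      vals <- c(vals, g[clampi(i + di, m), clampi(j + dj, n)])
    }
    mu[i, j] <- mean(vals)
    v[i, j] <- mean((vals - mean(vals))^2)
  }
  list(mean_map = mu, var_map = v)
}

oracle_wiener <- function(g, radius, lam) {
  st <- oracle_local_stats(g, radius)
  out <- matrix(0, nrow(g), ncol(g))
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    k <- st$var_map[i, j] / (st$var_map[i, j] + lam)
    if (!is.finite(k)) k <- 0
    out[i, j] <- st$mean_map[i, j] + k * (g[i, j] - st$mean_map[i, j])
  }
  out
}

oracle_mean_filter <- function(D, window) {
  r <- (window - 1L) %/% 2L
  m <- nrow(D); n <- ncol(D)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + D[clampi(i + di, m), clampi(j + dj, n)]
    }
    out[i, j] <- acc / window^2
  }
  out
}

oracle_nc_line <- function(signal, ct, r) {
  n <- length(signal)
  out <- numeric(n)
  for (p in seq_len(n)) {
    inside <- abs(ct[p] - ct) <= r
    out[p] <- sum(signal[inside]) / sum(inside)
  }
  out
}

oracle_sd <- function(f) {
  m <- nrow(f); n <- ncol(f)
  fb <- sum(f) / (m * n)
  acc <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) acc <- acc + (f[i, j] - fb)^2
  sqrt(acc / (m * n))
}

oracle_ag <- function(f) {
  m <- nrow(f); n <- ncol(f)
  acc <- 0
  for (i in seq_len(m - 1L)) for (j in seq_len(n - 1L)) {
    acc <- acc + sqrt((f[i, j] - f[i + 1L, j])^2 + (f[i, j] - f[i, j + 1L])^2)
  }
  acc / ((m - 1L) * (n - 1L))
}

oracle_entropy <- function(f) {
  lev <- floor(f + 0.5)
  h <- 0
  for (k in 0:255) {
    p <- sum(lev == k) / length(lev)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(a, b) {
  la <- floor(a + 0.5); lb <- floor(b + 0.5)
  N <- length(la)
  mi <- 0
  for (k in sort(unique(as.vector(la)))) for (l in sort(unique(as.vector(lb)))) {
    pj <- sum(la == k & lb == l) / N
    if (pj > 0) {
      pa <- sum(la == k) / N; pb <- sum(lb == l) / N
      mi <- mi + pj * log2(pj / (pa * pb))
    }
  }
  mi
}

oracle_sf <- function(f) {
  m <- nrow(f); n <- ncol(f)
  rf <- 0; cf <- 0
  for (i in seq_len(m)) for (j in 2:n) rf <- rf + (f[i, j] - f[i, j - 1L])^2
  for (i in 2:m) for (j in seq_len(n)) cf <- cf + (f[i, j] - f[i - 1L, j])^2
  sqrt(rf / (m * n) + cf / (m * n))
}

oracle_sobel <- function(x) {
  m <- nrow(x); n <- ncol(x)
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # column kernel
  gy <- t(gx)
  g <- al <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    sx <- 0; sy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- x[clampi(i + di, m), clampi(j + dj, n)]
      sx <- sx + gx[di + 2L, dj + 2L] * v
      sy <- sy + gy[di + 2L, dj + 2L] * v
    }
    g[i, j] <- sqrt(sx^2 + sy^2)
    al[i, j] <- if (sx != 0) atan(sy / sx) else if (sy != 0) pi / 2 else 0
  }
  list(g = g, alpha = al)
}

# full independent evaluation of the gradient-preservation family
oracle_qlnm <- function(a, b, f, const = ncfuse::qabf_constants()) {
  ea <- oracle_sobel(a); eb <- oracle_sobel(b); ef <- oracle_sobel(f)
  m <- nrow(a); n <- ncol(a)
  sQ <- sN <- sNm <- sL <- sW <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    qr <- function(gs, als) {
      G <- if (gs > ef$g[i, j]) ef$g[i, j] / gs
           else if (ef$g[i, j] > 0) gs / ef$g[i, j] else 1
      A <- 1 - abs(als - ef$alpha[i, j]) / (pi / 2)
      qg <- const$gamma_g / (1 + exp(const$kappa_g * (G - const$sigma_g)))
      qa <- const$gamma_a / (1 + exp(const$kappa_a * (A - const$sigma_a)))
      qg * qa
    }
    qaf <- qr(ea$g[i, j], ea$alpha[i, j])
    qbf <- qr(eb$g[i, j], eb$alpha[i, j])
    wa <- ea$g[i, j]^const$L; wb <- eb$g[i, j]^const$L
    am <- ef$g[i, j] > ea$g[i, j] && ef$g[i, j] > eb$g[i, j]
    sQ <- sQ + qaf * wa + qbf * wb
    if (am) {
      sN <- sN + wa + wb
      sNm <- sNm + (1 - qaf) * wa + (1 - qbf) * wb
    } else {
      sL <- sL + (1 - qaf) * wa + (1 - qbf) * wb
    }
    sW <- sW + wa + wb
  }
  list(Q = sQ / sW, N = sN / sW, Nm = sNm / sW, L = sL / sW)
}

rand_raw8 <- function(m, n, seed) {
  set.seed(seed)
  matrix(sample(0:255, m * n, replace = TRUE) + 0.0, m, n)
}

rand_unit <- function(m, n, seed) {
  set.seed(seed)
  matrix(stats::runif(m * n), m, n)
}
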