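# Shared fixtures and independent brute-force oracles.

# reflective (mirror) index into 1..n
reflect_idx <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

# direct nested-sum 2-D convolution with reflective boundary
brute_convolve <- function(img, k) {
  hw <- (nrow(k) - 1L) %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (cc in seq_len(ncol(img))) {
      s <- 0
      for (a in -hw:hw) {
        for (b in -hw:hw) {
          s <- s + k[a + hw + 1L, b + hw + 1L] *
            img[reflect_idx(r - a, nrow(img)), reflect_idx(cc - b, ncol(img))]
        }
      }
      out[r, cc] <- s
    }
  }
  out
}

# dense matrix of the linear operator kernel -> Lf (*) k on the padded
# periodic domain (the kernel solver's computational domain), built column
# by column from unit kernels with R's own fft; used to cross-check the CG
# solution against a dense least-squares solve
dense_kernel_operator <- function(Lf, ksize, P) {
  hw <- (ksize - 1L) %/% 2L
  FLf <- fft(reflect_pad_r(Lf, hw, P))
  N <- prod(P)
  A <- matrix(0, N, ksize * ksize)
  for (j in seq_len(ksize * ksize)) {
    e <- matrix(0, ksize, ksize)
    e[j] <- 1
    col <- Re(fft(FLf * fft(embed_kernel_r(e, P)), inverse = TRUE)) / N
    A[, j] <- as.vector(col)
  }
  A
}

# windowed SSIM recomputed with explicit per-pixel loops (independent of the
# vectorized implementation)
naive_ssim <- function(test, ref) {
  w <- kernelWeights(gaussianPSF(11L, 1.5))
  hw <- 5L
  n1 <- nrow(test); n2 <- ncol(test)
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- matrix(0, n1, n2)
  for (r in seq_len(n1)) {
    for (cc in seq_len(n2)) {
      m1 <- 0; m2 <- 0; q11 <- 0; q22 <- 0; q12 <- 0
      for (a in -hw:hw) {
        for (b in -hw:hw) {
          wv <- w[a + hw + 1L, b + hw + 1L]
          x <- test[reflect_idx(r + a, n1), reflect_idx(cc + b, n2)]
          y <- ref[reflect_idx(r + a, n1), reflect_idx(cc + b, n2)]
          m1 <- m1 + wv * x; m2 <- m2 + wv * y
          q11 <- q11 + wv * x * x; q22 <- q22 + wv * y * y
          q12 <- q12 + wv * x * y
        }
      }
      s11 <- q11 - m1^2; s22 <- q22 - m2^2; s12 <- q12 - m1 * m2
      vals[r, cc] <- ((2 * m1 * m2 + C1) * (2 * s12 + C2)) /
        ((m1^2 + m2^2 + C1) * (s11 + s22 + C2))
    }
  }
  mean(vals)
}

random_image <- function(n1, n2 = n1, seed = 1) {
  set.seed(seed)
  matrix(runif(n1 * n2), n1, n2)
}

small_star <- function(n = 96L) {
  generateStarPhantom(starPhantomSpec(imageSize = n, supersampleFactor = 2L))
}

# --- padded periodic-domain objective oracles -------------------------------
# These replicate the solver's computational domain (reflective pre-pad of
# the kernel half-width, embedded top-left in a P x P periodic grid) so that
# objectives reported in solver traces can be recomputed independently.

reflect_pad_r <- function(img, hw, P) {
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, P[1], P[2])
  ext <- img[vapply((1 - hw):(n1 + hw), reflect_idx, numeric(1), n = n1),
             vapply((1 - hw):(n2 + hw), reflect_idx, numeric(1), n = n2)]
  out[seq_len(n1 + 2 * hw), seq_len(n2 + 2 * hw)] <- ext
  out
}

embed_kernel_r <- function(k, P) {
  hw <- (nrow(k) - 1L) %/% 2L
  out <- matrix(0, P[1], P[2])
  for (a in -hw:hw) for (b in -hw:hw)
    out[(a %% P[1]) + 1L, (b %% P[2]) + 1L] <- k[a + hw + 1L, b + hw + 1L]
  out
}

grad_periodic_r <- function(f) {
  P1 <- nrow(f); P2 <- ncol(f)
  list(gx = f[, c(2:P2, 1)] - f, gy = f[c(2:P1, 1), ] - f)
}

huber_val <- function(z, eps) {
  a <- abs(z)
  ifelse(a < eps, z^2 / (2 * eps), a - eps / 2)
}

# l1-mode objective on the padded periodic domain (fidelity-normalized)
padded_objective_l1 <- function(fpad, gpad, OTF, w1, eps) {
  P <- length(fpad)
  data <- 0.5 * sum(Mod(OTF * fft(fpad) - fft(gpad))^2) / P
  gr <- grad_periodic_r(fpad)
  data + w1 * (sum(huber_val(gr$gx, eps)) + sum(huber_val(gr$gy, eps)))
}

# long-run projected gradient on the same objective (reference solver)
pg_solve_l1 <- function(start, gpad, OTF, w1, eps, lo, hi, iters = 1e4) {
  G <- fft(gpad)
  P <- length(gpad)
  L <- max(Mod(OTF)^2) + (w1 / eps) * 8
  s <- 1 / L
  f <- start
  for (i in seq_len(iters)) {
    Fh <- fft(f)
    gd <- Re(fft(Conj(OTF) * (OTF * Fh - G), inverse = TRUE)) / P
    gr <- grad_periodic_r(f)
    hx <- pmin(pmax(gr$gx / eps, -1), 1)
    hy <- pmin(pmax(gr$gy / eps, -1), 1)
    P1 <- nrow(f); P2 <- ncol(f)
    gradT <- (hx[, c(P2, 1:(P2 - 1))] - hx) + (hy[c(P1, 1:(P1 - 1)), ] - hy)
    f <- pmin(pmax(f - s * (gd + w1 * gradT), lo), hi)
  }
  f
}
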