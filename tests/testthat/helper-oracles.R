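# Independent brute-force oracles used to verify the package's fast paths.

# Log-likelihood of the ordered 3-state HMM by explicit enumeration of all
# monotone state paths (valid only for small T).
enum_hmm_loglik <- function(y, beta, sigma, q1, q2) {
  T <- length(y)
  tot <- -Inf
  for (a in 1:T) {
    for (b in 0:(T - a)) {
      cc <- T - a - b
      if (cc > 0 && b == 0) next  # 1 -> 3 is not allowed
      lp <- (a - 1) * log(1 - q1)
      if (b > 0) lp <- lp + log(q1) + (b - 1) * log(1 - q2)
      if (cc > 0) lp <- lp + log(q2)
      st <- rep(1:3, c(a, b, cc))
      ok <- !is.na(y)
      lp <- lp + sum(dnorm(y[ok], beta[st[ok]], sigma[st[ok]], log = TRUE))
      m <- max(tot, lp)
      tot <- m + log(exp(tot - m) + exp(lp - m))
    }
  }
  tot
}

# Dense Gaussian-process log-likelihood of integrated-OU positions,
# conditioned on the first observation, from the closed-form covariance.
gp_iou_loglik <- function(y, times, beta, sigv) {
  s <- times[-1] - times[1]
  K <- outer(s, s, function(a, b) {
    sigv^2 / beta^2 * (2 * beta * pmin(a, b) + exp(-beta * a) +
                         exp(-beta * b) - 1 - exp(-beta * abs(a - b)))
  })
  yc <- y[-1] - y[1]
  -0.5 * (length(yc) * log(2 * pi) +
            as.numeric(determinant(K)$modulus) +
            drop(yc %*% solve(K, yc)))
}

# Convex hull area by gift wrapping (Jarvis march) + shoelace.
giftwrap_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
        (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2))) {
        q <- r
      }
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) break
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  if (length(hull) < 3) return(0)
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Brute-force percent-MCP: explicit distance sort then gift-wrap hull.
brute_mcp <- function(x, y, percent) {
  n <- length(x)
  m <- ceiling((1 - percent / 100) * n)
  if (m > 0) {
    d2 <- (x - mean(x))^2 + (y - mean(y))^2
    ord <- order(-d2, seq_len(n))
    keep <- setdiff(seq_len(n), ord[seq_len(m)])
    x <- x[keep]; y <- y[keep]
  }
  giftwrap_area(x, y)
}

# Direct vector-sum VRM oracle over the full window at one interior cell.
brute_vrm_cell <- function(xn, yn, zn, i, j, half) {
  ri <- (i - half):(i + half)
  rj <- (j - half):(j + half)
  n <- length(ri) * length(rj)
  1 - sqrt(sum(xn[ri, rj])^2 + sum(yn[ri, rj])^2 + sum(zn[ri, rj])^2) / n
}
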