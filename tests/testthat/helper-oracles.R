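# Independent brute-force oracles. Deliberately written with explicit loops
# and scalar arithmetic, sharing no code with the package internals.

# Full ComBat pipeline (parametric priors, both effects), looped per
# batch/feature, EB fixed point iterated to `eps`.
bf_combat <- function(X, batches, eps = 1e-12, iter = 10000L) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  lev <- unique(batches)
  B <- length(lev)

  bmean <- matrix(0, B, D)
  nb <- integer(B)
  for (i in seq_len(B)) {
    rows <- which(batches == lev[i])
    nb[i] <- length(rows)
    for (g in seq_len(D)) bmean[i, g] <- mean(X[rows, g])
  }
  alpha <- numeric(D)
  for (g in seq_len(D))
    for (i in seq_len(B)) alpha[g] <- alpha[g] + nb[i] / n * bmean[i, g]
  sigma2 <- numeric(D)
  for (j in seq_len(n)) {
    i <- match(batches[j], lev)
    for (g in seq_len(D))
      sigma2[g] <- sigma2[g] + (X[j, g] - bmean[i, g])^2 / n
  }
  Z <- matrix(0, n, D)
  for (j in seq_len(n))
    for (g in seq_len(D)) Z[j, g] <- (X[j, g] - alpha[g]) / sqrt(sigma2[g])

  Xs <- matrix(0, n, D)
  for (i in seq_len(B)) {
    rows <- which(batches == lev[i])
    ni <- length(rows)
    gh <- numeric(D); d2h <- numeric(D)
    for (g in seq_len(D)) {
      gh[g] <- mean(Z[rows, g])
      d2h[g] <- sum((Z[rows, g] - gh[g])^2) / (ni - 1)
    }
    gbar <- mean(gh)
    t2 <- sum((gh - gbar)^2) / (D - 1)
    vbar <- mean(d2h)
    s2 <- sum((d2h - vbar)^2) / (D - 1)
    lam <- (vbar^2 + 2 * s2) / s2
    th <- (vbar^3 + vbar * s2) / s2
    gs <- gh; ds <- d2h
    for (it in seq_len(iter)) {
      gs_new <- numeric(D); ds_new <- numeric(D)
      for (g in seq_len(D)) {
        gs_new[g] <- (ni * t2 * gh[g] + ds[g] * gbar) / (ni * t2 + ds[g])
        ss <- 0
        for (j in rows) ss <- ss + (Z[j, g] - gs_new[g])^2
        ds_new[g] <- (th + 0.5 * ss) / (ni / 2 + lam - 1)
      }
      delta <- max(abs(gs_new - gs), abs(ds_new - ds))
      gs <- gs_new; ds <- ds_new
      if (delta < eps) break
    }
    for (j in rows)
      for (g in seq_len(D))
        Xs[j, g] <- sqrt(sigma2[g]) * (Z[j, g] - gs[g]) / sqrt(ds[g]) +
          alpha[g]
  }
  Xs
}

# parametric EB fixed point for one batch, scalar loops, iterated to 1e-12
bf_eb_parametric <- function(Z, gh, d2h, gbar, t2, lam, th) {
  ni <- nrow(Z); D <- length(gh)
  gs <- gh; ds <- d2h
  repeat {
    gs_new <- numeric(D); ds_new <- numeric(D)
    for (g in seq_len(D)) {
      gs_new[g] <- (ni * t2 * gh[g] + ds[g] * gbar) / (ni * t2 + ds[g])
      ss <- 0
      for (j in seq_len(ni)) ss <- ss + (Z[j, g] - gs_new[g])^2
      ds_new[g] <- (th + 0.5 * ss) / (ni / 2 + lam - 1)
    }
    delta <- max(abs(gs_new - gs), abs(ds_new - ds))
    gs <- gs_new; ds <- ds_new
    if (delta < 1e-12) break
  }
  list(gamma_star = gs, delta_star2 = ds)
}

# non-parametric EB, brute-force double loop with log-space weights
bf_eb_nonparametric <- function(Z, gh, d2h) {
  D <- length(gh)
  gs <- numeric(D); ds <- numeric(D)
  for (g in seq_len(D)) {
    lw <- c(); cand_g <- c(); cand_d <- c()
    for (gp in seq_len(D)) {
      if (gp == g) next
      ll <- 0
      for (j in seq_len(nrow(Z)))
        ll <- ll + stats::dnorm(Z[j, g], gh[gp], sqrt(d2h[gp]), log = TRUE)
      lw <- c(lw, ll); cand_g <- c(cand_g, gh[gp]); cand_d <- c(cand_d, d2h[gp])
    }
    w <- exp(lw - max(lw)); w <- w / sum(w)
    gs[g] <- sum(w * cand_g)
    ds[g] <- sum(w * cand_d)
  }
  list(gamma_star = gs, delta_star2 = ds)
}

# AUROC by exhaustive pair enumeration with half-credit for ties
bf_auroc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# BH step-up, direct definition: q_(i) = min_{j >= i} m p_(j) / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- numeric(0)
    for (j in i:m) cands <- c(cands, m * ps[j] / j)
    q[i] <- min(1, min(cands))
  }
  out <- numeric(m)
  out[o] <- q
  out
}
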