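# Shared memoized fixtures: mean fields, GW runs and the four-start water
# experiment are expensive, so every test file pulls them from this cache.

.tcache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
  .tcache[[key]]
}

cachedMF <- function(fixture, ref = "HF") {
  memo(paste0("mf_", fixture, "_", ref), {
    fx <- makeFixture(fixture)
    runMeanField(fx$molecule, fx$basis, ref)
  })
}

cachedQsGW <- function(ref) {
  memo(paste0("qsgw_h2o_", ref), runQsGW(cachedMF("h2o", ref)))
}

cachedBSELowest <- function(ref) {
  memo(paste0("bse_h2o_", ref), {
    op <- buildBSEOperator(cachedQsGW(ref), mode = "BSE")
    davidsonSolve(op, nRoots = 1, tol = 1e-5)
  })
}

cachedTDHFOp <- function(name) {
  memo(paste0("op_tdhf_", name),
       buildBSEOperator(cachedMF(name, "HF"), mode = "TDHF"))
}

cachedTDHFDav <- function(name, nRoots = 4) {
  memo(paste0("tdhf_dav_", name),
       davidsonSolve(cachedTDHFOp(name), nRoots = nRoots, tol = 1e-10,
                     maxIter = 300))
}

cachedTDHFDense <- function(name) {
  memo(paste0("tdhf_dense_", name), denseTDHF(cachedMF(name, "HF"), "ri"))
}

cachedEvGW <- function(ref) {
  memo(paste0("evgw_h2o_", ref),
       runEvGW(cachedMF("h2o", ref),
               gwConfig(evgwConvHomo = 1e-3 / 27.211386)))
}

# independent restricted HF for s-function-only molecules, built from
# closed-form s-orbital integrals (Boys function via erf); second SCF
# implementation used as the oracle for the production engine
oracleSCFh2 <- function(bond = 0.74) {
  ang2bohr <- 0.529177210903
  R <- bond / ang2bohr
  ex <- c(3.425250914, 0.6239137298, 0.1688554040)
  cf <- c(0.1543289673, 0.5353281423, 0.4446345422)
  cf <- cf * (2 * ex / pi)^0.75
  centers <- list(c(0, 0, 0), c(0, 0, R))
  boys0 <- function(t) ifelse(t < 1e-12, 1 - t / 3,
                              0.5 * sqrt(pi / t) * pracma::erf(sqrt(t)))
  ss <- function(a, b, A, B) (pi / (a + b))^1.5 *
    exp(-a * b / (a + b) * sum((A - B)^2))
  tt <- function(a, b, A, B) {
    ab <- a * b / (a + b)
    ab * (3 - 2 * ab * sum((A - B)^2)) * ss(a, b, A, B)
  }
  vv <- function(a, b, A, B, C) {
    p <- a + b
    P <- (a * A + b * B) / p
    -2 * pi / p * exp(-a * b / p * sum((A - B)^2)) * boys0(p * sum((P - C)^2))
  }
  ee <- function(a, b, c, d, A, B, C, D) {
    p <- a + b; q <- c + d
    P <- (a * A + b * B) / p; Q <- (c * C + d * D) / q
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
      exp(-a * b / p * sum((A - B)^2) - c * d / q * sum((C - D)^2)) *
      boys0(p * q / (p + q) * sum((P - Q)^2))
  }
  S <- matrix(0, 2, 2); Tm <- matrix(0, 2, 2); V <- matrix(0, 2, 2)
  for (m in 1:2) for (n in 1:2) for (i in 1:3) for (j in 1:3) {
    cc <- cf[i] * cf[j]
    S[m, n] <- S[m, n] + cc * ss(ex[i], ex[j], centers[[m]], centers[[n]])
    Tm[m, n] <- Tm[m, n] + cc * tt(ex[i], ex[j], centers[[m]], centers[[n]])
    for (at in 1:2)
      V[m, n] <- V[m, n] + cc * vv(ex[i], ex[j], centers[[m]], centers[[n]],
                                   centers[[at]])
  }
  eri <- array(0, c(2, 2, 2, 2))
  for (m in 1:2) for (n in 1:2) for (l in 1:2) for (s in 1:2)
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (q in 1:3)
      eri[m, n, l, s] <- eri[m, n, l, s] + cf[i] * cf[j] * cf[k] * cf[q] *
        ee(ex[i], ex[j], ex[k], ex[q], centers[[m]], centers[[n]],
           centers[[l]], centers[[s]])
  h <- Tm + V
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  C <- X[, 1, drop = FALSE]  # start from symmetric combination
  E <- 0
  for (it in 1:60) {
    ev <- eigen(t(X) %*% h %*% X, symmetric = TRUE)
    # first iteration: core guess; afterwards Fock
    D <- NULL
    Fm <- h
    for (scf in 1:200) {
      Fp <- t(X) %*% Fm %*% X
      e2 <- eigen(Fp, symmetric = TRUE)
      ord <- order(e2$values)
      C <- X %*% e2$vectors[, ord[1], drop = FALSE]
      D <- 2 * tcrossprod(C)
      J <- matrix(0, 2, 2); K <- matrix(0, 2, 2)
      for (m in 1:2) for (n in 1:2) for (l in 1:2) for (s in 1:2) {
        J[m, n] <- J[m, n] + eri[m, n, l, s] * D[l, s]
        K[m, n] <- K[m, n] + eri[m, l, n, s] * D[l, s]
      }
      Fnew <- h + J - 0.5 * K
      Enew <- sum(D * h) + 0.5 * sum(D * J) - 0.25 * sum(D * K) + 1 / R
      if (abs(Enew - E) < 1e-13) { E <- Enew; break }
      E <- Enew
      Fm <- Fnew
    }
    break
  }
  E
}
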