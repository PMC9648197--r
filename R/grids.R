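# Imaginary-time / imaginary-frequency grids.
#
# Quadrature nodes and weights are least-squares-optimized exponential-sum
# rules: geometric initialization, derivative-free refinement of (offset,
# ratio), then an iteratively reweighted Levenberg-Marquardt polish that
# approaches the minimax (L-infinity) solution with strictly positive weights.
# Transform matrices (cosine/sine time->frequency, cosine frequency->time) are
# per-row reweighted least-squares fits on the analytic kernel pairs
#   exp(-d*tau)  <->  2d/(d^2+w^2)   and   exp(-d*tau) -> 2w/(d^2+w^2).
# Every rule and transform carries a certified max error measured on a dense
# independent verification mesh; downstream modules propagate these errors.

.pinvSolve <- function(A, b, tol = 1e-13) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep]))
}

# Lawson iteratively-reweighted LSQ: approximates the minimax solution of
# A x ~ b; returns coefficients
.lawson <- function(A, b, nit = 30L) {
  u <- rep(1, nrow(A))
  x <- NULL
  for (k in seq_len(nit)) {
    sw <- sqrt(u / sum(u))
    x <- .pinvSolve(A * sw, b * sw)
    r <- abs(drop(A %*% x) - b)
    u <- u * (r + 1e-300)
    u <- u / max(u)
  }
  x
}

# least-squares weights constrained to w >= floor (simple active-set loop);
# keeps quadrature weights strictly positive even when the node set
# over-resolves an easy energy range
.posSolve <- function(A, b, floor = 1e-12) {
  n <- ncol(A)
  free <- rep(TRUE, n)
  w <- rep(floor, n)
  for (it in seq_len(2L * n)) {
    rhs <- b - A[, !free, drop = FALSE] %*% rep(floor, sum(!free))
    wf <- .pinvSolve(A[, free, drop = FALSE], drop(rhs))
    if (all(wf > floor)) {
      w[free] <- wf
      return(w)
    }
    bad <- which(free)[which.min(wf)]
    free[bad] <- FALSE
    if (!any(free)) break
  }
  w
}

# optimize nodes/weights of  sum_k w_k K(d, x_k) ~ 1  for d in [dmin, dmax];
# K is the kernel already scaled so the target is identically 1
.expsumRule <- function(n, dmin, dmax, kern, refine = TRUE) {
  dg <- exp(seq(log(dmin), log(dmax), length.out = 150L * n))
  m <- length(dg)
  res <- function(x, w) drop(kern(dg, x) %*% w) - 1
  wsolve <- function(x) .pinvSolve(kern(dg, x), rep(1, m))
  geom <- function(p) exp(p[1]) * exp(p[2])^(0:(n - 1))
  obj <- function(p) {
    x <- geom(p)
    max(abs(res(x, wsolve(x))))
  }
  best <- NULL
  for (lb in log(seq(1.4, 3.2, by = 0.2)))
    for (lt in log(c(0.01, 0.1, 0.3) / dmax)) {
      v <- obj(c(lt, lb))
      if (is.null(best) || v < best$v) best <- list(v = v, p = c(lt, lb))
    }
  op <- stats::optim(best$p, obj, control = list(maxit = 300, reltol = 1e-12))
  x <- geom(op$par)
  w <- .posSolve(kern(dg, x), rep(1, m))
  if (refine) {
    # iteratively reweighted LM polish toward the minimax solution
    irls <- function(x0, w0, stages = c(2, 4, 8)) {
      par <- c(log(pmax(x0, 1e-300)), log(pmax(w0, 1e-300)))
      u <- rep(1, m)
      bp <- par
      be <- max(abs(res(x0, w0)))
      for (pnorm in stages) {
        # clamp in log space so trial steps cannot overflow to Inf/NaN
        fn <- function(p) {
          p <- pmax(pmin(p, 60), -700)
          sqrt(u) * res(exp(p[1:n]), exp(p[(n + 1):(2 * n)]))
        }
        fit <- minpack.lm::nls.lm(
          par, fn = fn,
          control = minpack.lm::nls.lm.control(maxiter = 350, ptol = 1e-15,
                                               ftol = 1e-15))
        par <- pmax(pmin(fit$par, 60), -700)
        r <- res(exp(par[1:n]), exp(par[(n + 1):(2 * n)]))
        if (is.finite(max(abs(r))) && max(abs(r)) < be) {
          be <- max(abs(r))
          bp <- par
        }
        u <- (abs(r) / max(abs(r)) + 1e-8)^(pnorm - 2)
        u <- u * m / sum(u)
      }
      list(x = exp(bp[1:n]), w = exp(bp[(n + 1):(2 * n)]), err = be)
    }
    cur <- irls(x, w)
    # nodes whose weight collapsed are respawned in the widest log-gap and
    # the polish repeated; keeps all n nodes effective
    for (round in 1:4) {
      dead <- cur$w < 1e-8 * max(cur$w)
      if (!any(dead)) break
      xs <- sort(cur$x[!dead])
      lx <- log(xs)
      need <- sum(dead)
      ord <- order(diff(lx), decreasing = TRUE)
      newx <- exp((lx[ord] + lx[ord + 1]) / 2)[seq_len(min(need,
                                                           length(xs) - 1))]
      extra <- need - length(newx)
      if (extra > 0)  # over-resolved range: spread the rest log-uniformly
        newx <- c(newx, exp(seq(log(dmin), log(dmax),
                                length.out = extra + 2))[2:(extra + 1)])
      xnew <- sort(unique(c(xs, newx)))
      while (length(xnew) < n)
        xnew <- sort(c(xnew, max(xnew) * 1.37))
      cur2 <- irls(xnew, .posSolve(kern(dg, xnew), rep(1, m)))
      if (cur2$err < cur$err) cur <- cur2 else break
    }
    x <- cur$x
    w <- cur$w
  }
  w <- pmax(w, 1e-14)
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

# fit rows of a transform matrix: sum_k M[j,k] basis_k(d) ~ target_j(d)
.fitRows <- function(basisMat, targets, relative = TRUE) {
  M <- matrix(0, ncol(targets), ncol(basisMat))
  for (j in seq_len(ncol(targets))) {
    y <- targets[, j]
    sc <- if (relative) 1 / y else rep(1, length(y))
    M[j, ] <- .lawson(basisMat * sc, y * sc)
  }
  M
}

#' Build imaginary-time and imaginary-frequency grids with transforms
#'
#' Constructs quadrature rules certified for all transition energies
#' \code{delta} inside \code{energyRange}: the time rule integrates
#' \code{exp(-delta*tau)} to \code{1/delta}, the frequency rule integrates the
#' Lorentzian to its closed form, and the transform matrices map between the
#' two kernel representations.  All certified errors are measured on a dense
#' verification mesh independent of the fit mesh and stored in the result.
#'
#' @param nPoints number of nodes for both grids (>= 4)
#' @param energyRange numeric(2): smallest/largest transition energy (Hartree)
#' @param refine run the minimax polishing stage (default TRUE)
#' @return an \linkS4class{ImaginaryGrid}
#' @export
buildGrids <- function(nPoints = 16L, energyRange, refine = TRUE) {
  if (nPoints < 4) stop("nPoints must be >= 4", call. = FALSE)
  dmin <- energyRange[1]; dmax <- energyRange[2]
  if (!(dmin > 0 && dmax > dmin))
    stop("energyRange must satisfy 0 < min < max", call. = FALSE)
  n <- as.integer(nPoints)
  tauRule <- .expsumRule(n, dmin, dmax,
                         function(d, x) exp(-outer(d, x)) * d, refine)
  omgRule <- .expsumRule(n, dmin, dmax,
                         function(d, x) (2 / pi) * d / outer(d^2, x^2, "+"),
                         refine)
  tau <- tauRule$x; wt <- tauRule$w
  omg <- omgRule$x; wo <- omgRule$w
  # transform fits on the fit mesh
  dg <- exp(seq(log(dmin), log(dmax), length.out = 80L * n))
  E <- exp(-outer(dg, tau))
  Lor <- 2 * dg / outer(dg^2, omg^2, "+")
  LorS <- 2 * rep(1, length(dg)) %o% omg / outer(dg^2, omg^2, "+")
  cosTW <- .fitRows(E, Lor, relative = TRUE)
  sinTW <- .fitRows(E, LorS, relative = TRUE)
  cosWT <- .fitRows(Lor, E, relative = FALSE)
  # certification on an independent, denser, offset mesh
  dv <- exp(seq(log(dmin) + 1e-4, log(dmax) - 1e-4, length.out = 137L * n))
  Ev <- exp(-outer(dv, tau))
  Lv <- 2 * dv / outer(dv^2, omg^2, "+")
  LvS <- 2 * rep(1, length(dv)) %o% omg / outer(dv^2, omg^2, "+")
  cert <- c(
    quad_tau = max(abs(drop(Ev %*% wt) * dv - 1)),
    quad_omega = max(abs(drop((2 / pi) * (dv / outer(dv^2, omg^2, "+")) %*%
                                wo) - 1)),
    cos_tw = max(abs(Ev %*% t(cosTW) - Lv) / Lv),
    sin_tw = max(abs(Ev %*% t(sinTW) - LvS) / LvS),
    cos_wt = max(abs(Lv %*% t(cosWT) - Ev)))
  new("ImaginaryGrid", tauPoints = tau, tauWeights = wt,
      omegaPoints = omg, omegaWeights = wo,
      cosTauToOmega = cosTW, sinTauToOmega = sinTW, cosOmegaToTau = cosWT,
      energyRange = c(dmin, dmax), certifiedError = cert)
}

# per-session memo so repeated GW runs on similar energy ranges share grids
.gridCache <- new.env(parent = emptyenv())

# padded + log-rounded range lookup
.cachedGrid <- function(nPoints, dmin, dmax) {
  lo <- floor(log10(dmin / 1.3) * 5) / 5
  hi <- ceiling(log10(dmax * 1.3) * 5) / 5
  key <- paste0("n", nPoints, "_", lo, "_", hi)
  g <- .gridCache[[key]]
  if (is.null(g)) {
    g <- buildGrids(nPoints, c(10^lo, 10^hi))
    .gridCache[[key]] <- g
  }
  g
}

#' Grid report: nodes, weights and certified errors
#'
#' @param grid an \linkS4class{ImaginaryGrid}
#' @param path optional JSON output file
#' @return (invisibly) the report list
#' @export
gridReport <- function(grid, path = NULL) {
  rep <- list(tau_points = grid@tauPoints, tau_weights = grid@tauWeights,
              omega_points = grid@omegaPoints,
              omega_weights = grid@omegaWeights,
              energy_range_Ha = grid@energyRange,
              certified_error = as.list(grid@certifiedError))
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}
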