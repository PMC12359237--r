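#' Dense primal-dual interior-point solver for convex QPs and LPs
#'
#' Minimises `0.5 * t(x) %*% Q %*% x + sum(cvec * x)` subject to
#' `A %*% x == b` and `lb <= x <= ub`. With `Q = NULL` the problem is a
#' linear program. This is the numerical engine behind [solve_fba()],
#' [solve_pfba()], [run_fva()] and [fit_to_solution_space()]; it is exported
#' because it is independently useful and independently testable.
#'
#' The algorithm is a Mehrotra-style predictor-corrector method on the KKT
#' system of the box-constrained QP. Equality constraints may be rank
#' deficient (stoichiometric matrices usually are: mass conservation makes
#' rows linearly dependent); the Schur complement is therefore solved with a
#' small primal-dual regularisation.
#'
#' @param cvec linear objective coefficients (length n).
#' @param Q optional n x n symmetric positive semidefinite matrix.
#' @param A optional equality-constraint matrix (m x n).
#' @param b equality right-hand side (length m).
#' @param lb,ub elementwise bounds; `-Inf`/`Inf` allowed.
#' @param maximize if `TRUE` the linear part is maximised (`Q` must be NULL).
#' @param tol convergence tolerance on scaled primal/dual residuals and on
#'   the complementarity gap.
#' @param maxit maximum interior-point iterations.
#' @return list with `x` (solution), `objective`, `status` (one of
#'   `"optimal"`, `"infeasible"`, `"unbounded"`, `"maxit"`), `iterations`,
#'   and `dual` (equality multipliers).
#' @examples
#' # max x3 over a 3-step chain: S v = 0, 0 <= v <= (2, 10, 10)
#' S <- rbind(c(1, -1, 0), c(0, 1, -1))
#' solve_qp(c(0, 0, 1), A = S, b = c(0, 0), lb = rep(0, 3),
#'          ub = c(2, 10, 10), maximize = TRUE)$objective
#' @export
solve_qp <- function(cvec, Q = NULL, A = NULL, b = NULL,
                     lb = rep(-Inf, length(cvec)), ub = rep(Inf, length(cvec)),
                     maximize = FALSE, tol = 1e-9, maxit = 200L) {
  n <- length(cvec)
  stopifnot(length(lb) == n, length(ub) == n)
  if (maximize) {
    if (!is.null(Q)) stop("maximize = TRUE is only supported for linear objectives")
    cvec <- -cvec
  }
  if (any(lb > ub + 1e-12)) stop("lower bound exceeds upper bound")
  if (is.null(A)) {
    A <- matrix(0, 0, n)
    b <- numeric(0)
  }
  A <- as.matrix(A)
  if (ncol(A) != n) stop("ncol(A) must equal length(cvec)")

  # eliminate (near-)fixed variables up front: a box with (near-)zero width
  # has no interior and wrecks the barrier iteration
  fixed <- which(is.finite(lb) & is.finite(ub) & (ub - lb) <= 1e-8)
  if (length(fixed)) {
    keep <- setdiff(seq_len(n), fixed)
    xf <- (lb[fixed] + ub[fixed]) / 2
    b2 <- b - as.numeric(A[, fixed, drop = FALSE] %*% xf)
    c2 <- cvec[keep]
    Q2 <- NULL
    const <- sum(cvec[fixed] * xf)
    if (!is.null(Q)) {
      Q <- as.matrix(Q)
      c2 <- c2 + as.numeric(Q[keep, fixed, drop = FALSE] %*% xf)
      const <- const + 0.5 * sum(xf * (Q[fixed, fixed, drop = FALSE] %*% xf))
      Q2 <- Q[keep, keep, drop = FALSE]
    }
    if (!length(keep)) {
      # everything is fixed; just check feasibility
      feas <- if (nrow(A)) max(abs(b2)) <= 1e-7 else TRUE
      x <- numeric(n)
      x[fixed] <- xf
      return(list(x = x, objective = (if (maximize) -1 else 1) * const,
                  status = if (feas) "optimal" else "infeasible",
                  iterations = 0L, dual = numeric(nrow(A))))
    }
    inner <- solve_qp(c2, Q = Q2, A = A[, keep, drop = FALSE], b = b2,
                      lb = lb[keep], ub = ub[keep], tol = tol, maxit = maxit)
    x <- numeric(n)
    x[fixed] <- xf
    x[keep] <- inner$x
    inner$x <- x
    inner$objective <- inner$objective + const
    if (maximize) inner$objective <- -inner$objective
    return(inner)
  }

  res <- .ip_core(cvec, Q, A, b, lb, ub, tol = tol, maxit = maxit)

  if (res$status != "optimal") {
    # classify: phase-1 feasibility LP min 1'(p+q) s.t. Ax + p - q = b
    m <- nrow(A)
    if (m > 0) {
      cf <- c(rep(0, n), rep(1, 2 * m))
      Af <- cbind(A, diag(m), -diag(m))
      lf <- c(lb, rep(0, 2 * m))
      uf <- c(ub, rep(Inf, 2 * m))
      ph1 <- .ip_core(cf, NULL, Af, b, lf, uf, tol = 1e-8, maxit = maxit)
      if (ph1$status == "optimal" && ph1$objective > 1e-6 * max(1, max(abs(b)))) {
        res$status <- "infeasible"
      }
    }
  }
  if (maximize) res$objective <- -res$objective
  res
}

# Mehrotra predictor-corrector core. Assumes lb < ub strictly (fixed
# variables already eliminated) and A possibly row-rank-deficient.
.ip_core <- function(cvec, Q, A, b, lb, ub, tol = 1e-9, maxit = 200L) {
  n <- length(cvec)
  # drop linearly dependent equality rows (stoichiometric matrices have them);
  # consistency of the dropped rows is verified on the final iterate
  A_full <- A
  b_full <- b
  if (nrow(A) > 1) {
    qa <- qr(t(A))
    if (qa$rank < nrow(A)) {
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      A <- A[keep, , drop = FALSE]
      b <- b[keep]
    }
  }
  m <- nrow(A)
  hasQ <- !is.null(Q)
  if (hasQ) Q <- as.matrix(Q)
  hasL <- is.finite(lb)
  hasU <- is.finite(ub)
  nL <- sum(hasL)
  nU <- sum(hasU)
  if (nL + nU == 0 && !hasQ) {
    # fully unconstrained linear directions exist unless cvec lies in row(A)
    # leave to the generic path with a box at +-1e12 for stability
    lb <- rep(-1e12, n); ub <- rep(1e12, n)
    hasL <- hasU <- rep(TRUE, n); nL <- nU <- n
  }

  # strictly interior start: 0 clamped into the box with a margin
  width <- ub - lb
  marg <- ifelse(hasL & hasU, pmin(1, 0.25 * width), 1)
  x <- pmin(pmax(numeric(n), ifelse(hasL, lb + marg, -Inf)),
            ifelse(hasU, ub - marg, Inf))
  y <- numeric(m)
  z <- ifelse(hasL, 1, 0)   # duals for x - lb >= 0
  w <- ifelse(hasU, 1, 0)   # duals for ub - x >= 0

  bigx <- 1e13 * max(1, max(abs(b), 0))
  objscale <- max(1, max(abs(cvec)))
  bscale <- max(1, if (m) max(abs(b)) else 0)
  status <- "maxit"
  iter <- 0L
  reg <- 1e-10
  best <- list(score = Inf, x = x, y = y, since = 0L)

  for (iter in seq_len(maxit)) {
    s <- ifelse(hasL, pmax(x - lb, 1e-14), 1)
    t <- ifelse(hasU, pmax(ub - x, 1e-14), 1)
    qx <- if (hasQ) as.numeric(Q %*% x) else numeric(n)
    rd <- qx + cvec - (if (m) as.numeric(crossprod(A, y)) else 0) - z + w
    rp <- if (m) b - as.numeric(A %*% x) else numeric(0)
    mu <- (sum(ifelse(hasL, s * z, 0)) + sum(ifelse(hasU, t * w, 0))) /
      max(1, nL + nU)

    pinf <- if (nrow(A_full)) max(abs(b_full - as.numeric(A_full %*% x))) / bscale else 0
    dinf <- max(abs(rd)) / objscale
    gapscale <- max(1, abs(sum(cvec * x)), max(abs(x)))
    if (isTRUE(getOption("minn.ip.verbose")))
      message(sprintf("ip it %3d pinf %.2e dinf %.2e mu %.2e", iter, pinf, dinf, mu))
    score <- max(pinf, dinf, mu / gapscale)
    if (score < best$score) {
      best <- list(score = score, x = x, y = y, since = 0L)
    } else {
      best$since <- best$since + 1L
    }
    if (score < tol * 10) {
      status <- "optimal"
      break
    }
    # degenerate problems oscillate near the solution; accept the best
    # iterate once it is well within practical LP tolerance and stalled
    if (best$score < 1e-8 && best$since >= 15L) {
      x <- best$x; y <- best$y
      status <- "optimal"
      break
    }
    if (max(abs(x)) > bigx) {
      status <- "unbounded"
      break
    }

    D <- pmin(ifelse(hasL, z / s, 0) + ifelse(hasU, w / t, 0), 1e16)
    M <- if (hasQ) Q else matrix(0, n, n)
    diag(M) <- diag(M) + D + reg

    ch <- tryCatch(chol(M), error = function(e) NULL)
    jit <- reg
    while (is.null(ch) && jit < 1e-2) {
      jit <- jit * 100
      M2 <- M; diag(M2) <- diag(M2) + jit
      ch <- tryCatch(chol(M2), error = function(e) NULL)
    }
    if (is.null(ch)) { status <- "numerical"; break }

    Minv <- function(v) backsolve(ch, forwardsolve(t(ch), v))

    newton <- function(rc3, rc4) {
      # (M) dx - A'dy = r1 ; A dx = rp
      r1 <- -rd + ifelse(hasL, rc3 / s, 0) - ifelse(hasU, rc4 / t, 0)
      if (m) {
        MiAt <- Minv(t(A))
        Schur <- A %*% MiAt
        dmax <- max(diag(Schur), 1e-30)
        rhs <- rp - as.numeric(A %*% Minv(r1))
        dy <- NULL
        sjit <- 1e-13
        while (is.null(dy) && sjit < 1e-2) {
          S2 <- Schur
          diag(S2) <- diag(S2) + sjit * dmax
          dy <- tryCatch(solve(S2, rhs), error = function(e) NULL)
          sjit <- sjit * 100
        }
        if (is.null(dy)) dy <- rep(0, m)
        dx <- as.numeric(Minv(r1 + as.numeric(crossprod(A, dy))))
      } else {
        dy <- numeric(0)
        dx <- as.numeric(Minv(r1))
      }
      dz <- ifelse(hasL, (rc3 - z * dx) / s, 0)
      dw <- ifelse(hasU, (rc4 + w * dx) / t, 0)
      list(dx = dx, dy = dy, dz = dz, dw = dw)
    }

    steplen <- function(v, dv, mask) {
      neg <- mask & (dv < 0)
      if (!any(neg)) return(1)
      min(1, min(-v[neg] / dv[neg]))
    }

    # predictor (affine) step
    aff <- newton(rc3 = ifelse(hasL, -s * z, 0), rc4 = ifelse(hasU, -t * w, 0))
    if (!all(is.finite(aff$dx))) { status <- "numerical"; break }
    ap <- min(steplen(s, aff$dx, hasL), steplen(t, -aff$dx, hasU))
    ad <- min(steplen(z, aff$dz, hasL), steplen(w, aff$dw, hasU))
    a_aff <- min(ap, ad)
    mu_aff <- (sum(ifelse(hasL, (s + a_aff * aff$dx) * (z + a_aff * aff$dz), 0)) +
               sum(ifelse(hasU, (t - a_aff * aff$dx) * (w + a_aff * aff$dw), 0))) /
      max(1, nL + nU)
    sigma <- if (mu > 0) min(1, (mu_aff / mu)^3) else 0

    # corrector
    rc3 <- ifelse(hasL, sigma * mu - s * z - aff$dx * aff$dz, 0)
    rc4 <- ifelse(hasU, sigma * mu - t * w + aff$dx * aff$dw, 0)
    cor <- newton(rc3 = rc3, rc4 = rc4)
    if (!all(is.finite(cor$dx))) { status <- "numerical"; break }

    ap <- min(steplen(s, cor$dx, hasL), steplen(t, -cor$dx, hasU))
    ad <- min(steplen(z, cor$dz, hasL), steplen(w, cor$dw, hasU))
    eta <- 0.99995
    ap <- eta * ap
    ad <- eta * ad

    x <- x + ap * cor$dx
    y <- y + ad * cor$dy
    z <- pmax(ifelse(hasL, z + ad * cor$dz, 0), 0)
    w <- pmax(ifelse(hasU, w + ad * cor$dw, 0), 0)
    z[hasL] <- pmax(z[hasL], 1e-14)
    w[hasU] <- pmax(w[hasU], 1e-14)
  }

  if (status %in% c("maxit", "numerical") && best$score < 1e-6) {
    x <- best$x; y <- best$y
    status <- "optimal"
  }
  # polish: alternate projection onto the equality manifold and the box.
  # Interior-point iterates carry O(tol) equality residuals that downstream
  # two-stage solves (e.g. fixing an optimum) would otherwise amplify.
  if (status == "optimal" && m > 0) {
    AAt <- tcrossprod(A)
    diag(AAt) <- diag(AAt) + 1e-12 * max(diag(AAt))
    ch2 <- tryCatch(chol(AAt), error = function(e) NULL)
    if (!is.null(ch2)) {
      pinf0 <- if (nrow(A_full)) max(abs(b_full - as.numeric(A_full %*% x))) else 0
      xp <- x
      for (k in 1:3) {
        r <- as.numeric(A %*% xp) - b
        xp <- xp - as.numeric(crossprod(A, backsolve(ch2, forwardsolve(t(ch2), r))))
        xp <- pmin(pmax(xp, lb), ub)
      }
      pinf1 <- if (nrow(A_full)) max(abs(b_full - as.numeric(A_full %*% xp))) else 0
      if (pinf1 < pinf0) x <- xp
    }
  }
  obj <- sum(cvec * x) + if (hasQ) 0.5 * sum(x * as.numeric(Q %*% x)) else 0
  list(x = x, objective = obj, status = status, iterations = iter, dual = y)
}
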