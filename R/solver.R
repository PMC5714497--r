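# Primal log-barrier interior-point solver for convex problems with a
# linear objective, one linear equality, non-negativity bounds and convex
# quadratic / linear inequality constraints:
#
#   maximize  obj'x
#   s.t.      aeq'x = beq
#             x_i >= 0              for i in nonneg
#             x'Q x + l'x + r <= 0  for each quad (Q PSD)
#             a'x + b <= 0          for each lin
#
# Standard path-following scheme (centering by equality-constrained Newton,
# barrier parameter multiplied by mu between centerings). Problem sizes here
# are a few hundred variables, so dense KKT solves are adequate.

quad_value <- function(q, x) {
  qx <- drop(q$Q %*% x)
  list(g = sum(x * qx) + sum(q$l * x) + q$r, grad = 2 * qx + q$l)
}

barrier_center <- function(x, t, obj, quads, lins, nonneg, aeq,
                           max_newton = 60) {
  n <- length(x)
  for (it in seq_len(max_newton)) {
    grad <- -t * obj
    H <- matrix(0, n, n)
    gq <- vector("list", length(quads))
    for (k in seq_along(quads)) {
      qv <- quad_value(quads[[k]], x)
      if (qv$g >= 0) stop("barrier: infeasible iterate")
      gq[[k]] <- qv
      grad <- grad + qv$grad / (-qv$g)
      H <- H + tcrossprod(qv$grad) / qv$g^2 + 2 * quads[[k]]$Q / (-qv$g)
    }
    for (k in seq_along(lins)) {
      g <- sum(lins[[k]]$a * x) + lins[[k]]$b
      if (g >= 0) stop("barrier: infeasible iterate")
      grad <- grad + lins[[k]]$a / (-g)
      H <- H + tcrossprod(lins[[k]]$a) / g^2
    }
    grad[nonneg] <- grad[nonneg] - 1 / x[nonneg]
    dH <- numeric(n)
    dH[nonneg] <- 1 / x[nonneg]^2
    diag(H) <- diag(H) + dH
    # equality-constrained Newton step via Cholesky + Schur complement
    # (H is SPD: PSD barrier curvature plus the positive bound diagonal)
    ridge <- 1e-13 * max(diag(H))
    R <- tryCatch(chol(H + diag(ridge, n)), error = function(e)
      chol(H + diag(1e-7 * max(diag(H)), n)))
    v1 <- backsolve(R, backsolve(R, grad, transpose = TRUE))
    v2 <- backsolve(R, backsolve(R, aeq, transpose = TRUE))
    nu <- sum(aeq * v1) / sum(aeq * v2)
    d <- -v1 + nu * v2
    lambda2 <- -sum(grad * d)
    if (!is.finite(lambda2) || lambda2 / 2 < 1e-11) break
    # backtracking: stay strictly feasible, then Armijo on the barrier
    psi <- function(y) {
      v <- -t * sum(obj * y)
      if (any(y[nonneg] <= 0)) return(Inf)
      v <- v - sum(log(y[nonneg]))
      for (q in quads) {
        g <- quad_value(q, y)$g
        if (g >= 0) return(Inf)
        v <- v - log(-g)
      }
      for (l in lins) {
        g <- sum(l$a * y) + l$b
        if (g >= 0) return(Inf)
        v <- v - log(-g)
      }
      v
    }
    f0 <- psi(x)
    alpha <- 1
    repeat {
      xn <- x + alpha * d
      fn <- psi(xn)
      if (is.finite(fn) && fn <= f0 - 0.25 * alpha * lambda2) break
      alpha <- alpha / 2
      if (alpha < 1e-14) { xn <- x; break }
    }
    if (identical(xn, x)) break
    x <- xn
  }
  x
}

barrier_qclp <- function(obj, quads = list(), lins = list(),
                         nonneg = seq_along(obj), aeq, beq, x0,
                         t0 = 1, mu = 50, gap_tol = 1e-9, t_max = 1e12,
                         stop_fn = NULL) {
  m_ineq <- length(nonneg) + length(quads) + length(lins)
  x <- x0
  t <- t0
  repeat {
    x <- barrier_center(x, t, obj, quads, lins, nonneg, aeq)
    if (!is.null(stop_fn) && stop_fn(x)) break
    if (m_ineq / t < gap_tol || t >= t_max) break
    t <- min(t * mu, t_max)
  }
  list(x = x, gap = m_ineq / t)
}

# Max constraint violation at x (0 when strictly feasible with margin).
constraint_violations <- function(x, quads, lins) {
  v <- numeric(0)
  for (q in quads) v <- c(v, quad_value(q, x)$g)
  for (l in lins) v <- c(v, sum(l$a * x) + l$b)
  v
}

# Phase I: minimize the common slack s with g_k(x) <= s. Returns a strictly
# feasible point or status "infeasible".
barrier_phase1 <- function(quads, lins, aeq, beq, x0, margin = 1e-9) {
  n <- length(x0)
  s0 <- max(c(constraint_violations(x0, quads, lins), 0)) + 1
  ext <- function(v, last = 0) c(v, last)
  quads_e <- lapply(quads, function(q) {
    Q <- matrix(0, n + 1, n + 1)
    Q[seq_len(n), seq_len(n)] <- q$Q
    list(Q = Q, l = ext(q$l, -1), r = q$r)
  })
  lins_e <- lapply(lins, function(l) list(a = ext(l$a, -1), b = l$b))
  # keep s bounded above so the feasible set of the phase-I problem is bounded
  lins_e <- c(lins_e, list(list(a = c(rep(0, n), 1), b = -(s0 + 1))))
  # stop as soon as a clearly interior point is found; only run to
  # optimality when deciding infeasibility
  res <- barrier_qclp(obj = c(rep(0, n), -1), quads = quads_e,
                      lins = lins_e, nonneg = seq_len(n),
                      aeq = c(aeq, 0), beq = beq,
                      x0 = c(x0, s0), gap_tol = 1e-10,
                      stop_fn = function(y) y[n + 1] < -1e-6)
  s <- res$x[n + 1]
  x <- res$x[seq_len(n)]
  if (s >= -margin)
    list(status = "infeasible", x = x,
         violations = constraint_violations(x, quads, lins))
  else list(status = "feasible", x = x)
}

# Full solve with automatic phase I when the start is infeasible. A larger
# t0 warm-starts path following from a good x0 (e.g. the previous iterate
# of the fixed-denominator loop).
solve_qclp <- function(obj, quads, lins, aeq, beq, x0,
                       gap_tol = 1e-9, t0 = 1) {
  strictly_ok <- function(x) {
    v <- constraint_violations(x, quads, lins)
    all(x > 0) && (length(v) == 0 || max(v) < -1e-9)
  }
  if (!strictly_ok(x0)) {
    # pull a near-feasible warm start toward the uniform point first
    unif <- rep(beq / length(x0), length(x0))
    fixed <- FALSE
    for (alpha in c(0.1, 0.3, 0.6, 1)) {
      xb <- (1 - alpha) * x0 + alpha * unif
      if (strictly_ok(xb)) { x0 <- xb; fixed <- TRUE; break }
    }
    if (!fixed) {
      p1 <- barrier_phase1(quads, lins, aeq, beq, unif)
      if (p1$status == "infeasible")
        return(list(status = "infeasible", x = p1$x,
                    violations = p1$violations))
      x0 <- p1$x
      t0 <- 1
    }
  }
  res <- barrier_qclp(obj, quads, lins, nonneg = seq_along(obj),
                      aeq = aeq, beq = beq, x0 = x0, gap_tol = gap_tol,
                      t0 = t0)
  list(status = "optimal", x = res$x, gap = res$gap)
}
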