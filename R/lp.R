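# Linear-programming core: bounded-variable revised simplex.
#
# Every LP this package solves has the steady-state form
#
#     min / max  c'v    s.t.   S v = 0,   lb <= v <= ub
#
# with finite bounds. Such problems are heavily degenerate (all-zero right-
# hand side), so the implementation uses Bland's anti-cycling rule on both
# the entering and the leaving choice; pivoting is deterministic given the
# column order. Phase 1 drives artificial variables (one per row, signed to
# cover the initial residual) to zero; phase 2 optimizes the true objective
# with artificials locked at zero. Dense algebra: model matrices here are
# tens of columns, not thousands.

lp_solve <- function(obj, S, lb, ub, maximize = FALSE, tol = 1e-9,
                     max_iter = 20000L) {
  S <- as.matrix(S)
  m <- nrow(S); n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort("lp_solve() requires finite bounds; encode large bounds as a big finite value.")
  }
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", fluxes = NULL, objective = NA_real_))
  }
  ub <- pmax(ub, lb)
  cc <- if (maximize) -obj else obj

  # ---- working arrays over n structural + m artificial variables ----------
  # status: 0 = nonbasic at lower, 1 = nonbasic at upper, 2 = basic
  nt <- n + m
  L <- c(lb, rep(0, m))
  U <- c(ub, rep(Inf, m))
  # structural start: the bound of smaller magnitude (0 whenever possible)
  start <- ifelse(abs(lb) <= abs(ub), lb, ub)
  x <- c(start, rep(0, m))
  resid <- as.numeric(-S %*% start)          # what artificials must cover
  art_sign <- ifelse(resid >= 0, 1, -1)
  A <- cbind(S, diag(art_sign, m))
  x[n + seq_len(m)] <- abs(resid)

  basis <- n + seq_len(m)
  status <- c(ifelse(abs(lb) <= abs(ub), 0L, 1L), rep(2L, m))

  run_phase <- function(costs, allow, x, basis, status, max_iter, tol) {
    for (iter in seq_len(max_iter)) {
      B <- A[, basis, drop = FALSE]
      Binv_ok <- TRUE
      y <- tryCatch(solve(t(B), costs[basis]),
                    error = function(e) { Binv_ok <<- FALSE; NULL })
      if (!Binv_ok) return(list(ok = FALSE, why = "singular"))

      # entering: Bland — smallest eligible index
      enter <- 0L; sigma <- 0
      for (j in seq_len(nt)) {
        if (status[j] == 2L || !allow[j] || U[j] - L[j] < tol) next
        d <- costs[j] - sum(y * A[, j])
        if (status[j] == 0L && d < -tol) { enter <- j; sigma <- 1; break }
        if (status[j] == 1L && d > tol)  { enter <- j; sigma <- -1; break }
      }
      if (enter == 0L) {
        return(list(ok = TRUE, x = x, basis = basis, status = status,
                    iters = iter))
      }

      w <- solve(B, A[, enter])
      # x_basis moves by -sigma * t * w as x_enter moves by sigma * t, t >= 0
      caps <- rep(Inf, length(basis))
      for (i in seq_along(basis)) {
        delta <- -sigma * w[i]
        if (abs(delta) < tol) next
        xi <- x[basis[i]]
        cap <- if (delta < 0) (xi - L[basis[i]]) / (-delta)
               else (U[basis[i]] - xi) / delta
        caps[i] <- max(cap, 0)
      }
      flip_cap <- U[enter] - L[enter]
      t_max <- min(flip_cap, caps)
      if (!is.finite(t_max)) return(list(ok = FALSE, why = "unbounded"))
      # leaving: Bland — smallest variable index among minimal-ratio blocks;
      # a bound-to-bound flip of the entering variable counts with its index
      cand <- which(caps <= t_max + tol)
      leave <- 0L                            # 0 = flip of entering variable
      best_idx <- if (flip_cap <= t_max + tol) enter else Inf
      for (i in cand) {
        if (basis[i] < best_idx) { best_idx <- basis[i]; leave <- i }
      }
      if (leave != 0L) t_max <- min(t_max, caps[leave])

      x[enter] <- x[enter] + sigma * t_max
      x[basis] <- x[basis] - sigma * t_max * w
      if (leave == 0L) {
        status[enter] <- if (status[enter] == 0L) 1L else 0L
      } else {
        out <- basis[leave]
        # leaving variable lands on whichever bound it hit
        status[out] <- if (-sigma * w[leave] < 0) 0L else 1L
        x[out] <- if (status[out] == 0L) L[out] else U[out]
        basis[leave] <- enter
        status[enter] <- 2L
      }
    }
    list(ok = FALSE, why = "maxiter")
  }

  # ---- phase 1 -------------------------------------------------------------
  costs1 <- c(rep(0, n), rep(1, m))
  allow1 <- c(rep(TRUE, n), rep(FALSE, m))
  ph1 <- run_phase(costs1, allow1, x, basis, status, max_iter, tol)
  if (!ph1$ok) {
    return(list(status = if (ph1$why == "maxiter") "maxiter" else "infeasible",
                fluxes = NULL, objective = NA_real_))
  }
  scale1 <- max(1, max(abs(lb)), max(abs(ub)))
  art_total <- sum(ph1$x[n + seq_len(m)])
  if (art_total > tol * scale1 * m) {
    return(list(status = "infeasible", fluxes = NULL, objective = NA_real_))
  }

  # ---- phase 2: artificials locked at zero ---------------------------------
  x <- ph1$x; basis <- ph1$basis; status <- ph1$status
  U[n + seq_len(m)] <- 0
  x[n + seq_len(m)] <- pmin(x[n + seq_len(m)], 0)
  x[n + seq_len(m)] <- pmax(x[n + seq_len(m)], 0)
  costs2 <- c(cc, rep(0, m))
  allow2 <- c(rep(TRUE, n), rep(FALSE, m))
  ph2 <- run_phase(costs2, allow2, x, basis, status, max_iter, tol)
  if (!ph2$ok) {
    return(list(status = if (ph2$why == "unbounded") "unbounded" else ph2$why,
                fluxes = NULL, objective = NA_real_))
  }
  v <- ph2$x[seq_len(n)]
  # clip round-off outside the box
  v <- pmin(pmax(v, lb), ub)
  list(status = "optimal", fluxes = v, objective = sum(obj * v))
}
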