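# Independent oracles used to cross-check the package's LP solver and the
# extreme-ray enumeration. These deliberately take different routes than the
# implementation: exhaustive vertex / support enumeration, and SciPy's HiGHS
# solver through the system python.

# Brute-force LP over {S v = 0, lb <= v <= ub}: enumerate basic solutions
# (choose rank(S) basic columns, pin the rest at a bound), keep feasible
# vertices, return the best objective.
brute_force_lp <- function(obj, S, lb, ub, maximize = FALSE, tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  best <- NULL
  bestval <- if (maximize) -Inf else Inf
  free_sets <- if (r == 0) list(integer(0)) else combn(n, r, simplify = FALSE)
  for (bas in free_sets) {
    B <- S[, bas, drop = FALSE]
    if (length(bas) > 0 && qr(B)$rank < length(bas)) next
    nb <- setdiff(seq_len(n), bas)
    k <- length(nb)
    for (mask in 0:(2^k - 1)) {
      xn <- numeric(k)
      if (k > 0) {
        for (t in seq_len(k)) {
          xn[t] <- if (bitwAnd(mask, bitwShiftL(1L, t - 1L)) > 0) ub[nb[t]] else lb[nb[t]]
        }
      }
      x <- numeric(n)
      x[nb] <- xn
      if (length(bas) > 0) {
        rhs <- -S[, nb, drop = FALSE] %*% xn
        xb <- tryCatch(qr.solve(B, rhs), error = function(e) NULL)
        if (is.null(xb)) next
        x[bas] <- xb
      }
      if (max(abs(S %*% x)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if ((maximize && val > bestval + 1e-12) ||
          (!maximize && val < bestval - 1e-12)) {
        bestval <- val
        best <- x
      }
    }
  }
  list(objective = bestval, fluxes = best, feasible = is.finite(bestval))
}

# Exhaustive extreme-ray oracle for the cone {v >= 0 : A v = 0}: a support T
# carries an extreme ray iff the nullspace of A[, T] is one-dimensional, the
# nullvector can be signed strictly positive on T, and no smaller found
# support is contained in T. Rays returned scaled to max = 1.
support_minimal_rays <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  found <- list()
  for (size in seq_len(n)) {
    for (T in combn(n, size, simplify = FALSE)) {
      skip <- FALSE
      for (f in found) {
        if (all(f$supp %in% T)) { skip <- TRUE; break }
      }
      if (skip) next
      sub <- A[, T, drop = FALSE]
      ns <- nullspace_svd(sub)
      if (ncol(ns) != 1) next
      v <- ns[, 1]
      if (all(v < -tol)) v <- -v
      if (!all(v > tol)) next
      if (max(abs(sub %*% v)) > tol * max(1, max(abs(v)))) next
      ray <- numeric(n)
      ray[T] <- v
      found[[length(found) + 1]] <- list(supp = T, ray = ray / max(ray))
    }
  }
  found
}

# Nullspace of a small dense matrix via SVD (columns spanning {v: M v = 0}).
nullspace_svd <- function(M, tol = 1e-9) {
  n <- ncol(M)
  sv <- svd(M, nu = 0, nv = n)
  d <- c(sv$d, rep(0, n - length(sv$d)))
  keep <- d < tol * max(1, d[1])
  sv$v[, keep, drop = FALSE]
}

# SciPy HiGHS oracle: min/max c'v s.t. S v = 0, lb <= v <= ub.
scipy_lp <- function(obj, S, lb, ub, maximize = FALSE) {
  payload <- list(c = as.numeric(obj), A = unname(as.matrix(S)),
                  lb = as.numeric(lb), ub = as.numeric(ub),
                  maximize = maximize)
  fin <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = FALSE, digits = NA)
  code <- paste(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "c = np.array(d['c']); A = np.array(d['A'])",
    "if d['maximize'][0]: c = -c",
    "res = linprog(c, A_eq=A, b_eq=np.zeros(A.shape[0]),",
    "              bounds=list(zip(d['lb'], d['ub'])), method='highs')",
    "val = res.fun if res.status == 0 else None",
    "if val is not None and d['maximize'][0]: val = -val",
    "print(json.dumps({'status': int(res.status), 'objective': val,",
    "                  'x': None if res.x is None else list(res.x)}))",
    sep = "\n")
  fpy <- tempfile(fileext = ".py")
  writeLines(code, fpy)
  out <- system2("python", c(fpy, fin), stdout = TRUE, stderr = FALSE)
  res <- jsonlite::fromJSON(out[length(out)])
  list(status = if (res$status == 0) "optimal" else "not_optimal",
       objective = if (is.null(res$objective)) NA_real_ else res$objective,
       fluxes = if (is.null(res$x)) NULL else as.numeric(res$x))
}

# Random integer stoichiometric matrices for cone-enumeration cross-checks.
random_cone_matrix <- function(seed, n_rows = NULL, n_cols = NULL) {
  withr::with_seed(seed, {
    m <- n_rows %||% sample(2:3, 1)
    n <- n_cols %||% sample(5:8, 1)
    matrix(sample(c(-2, -1, 0, 0, 1, 1, 2), m * n, replace = TRUE), nrow = m)
  })
}

# All-irreversible model wrapping a raw stoichiometric matrix, so the split
# network equals the matrix itself.
cone_model_from_matrix <- function(A) {
  m <- nrow(A); n <- ncol(A)
  mets <- tibble::tibble(id = paste0("m", seq_len(m)),
                         name = paste0("m", seq_len(m)), compartment = "c")
  ids <- paste0("r", seq_len(n))
  stoich <- lapply(seq_len(n), function(j) {
    col <- A[, j]
    names(col) <- mets$id
    col[col != 0]
  })
  names(stoich) <- ids
  rxns <- tibble::tibble(id = ids, lower_bound = 0, upper_bound = 1000,
                         enzyme_associated = FALSE, objective_coefficient = 0)
  metabolic_model(mets, rxns, stoich, require_objective = FALSE)
}

`%||%` <- rlang::`%||%`
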