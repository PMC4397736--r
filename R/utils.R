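# Internal numeric helpers shared across modules.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0) return(1)
  Reduce(gcd2, x)
}

#' Scale a numeric vector to its smallest integer representation
#'
#' Multiplies by the smallest power of ten that makes all entries integral
#' (within `tol`), then divides by the greatest common divisor. Used to put
#' extreme rays and stoichiometric rows on a canonical exact-integer scale.
#'
#' @param x numeric vector.
#' @param tol tolerance for integrality detection.
#' @param max_denom largest power-of-ten denominator tried.
#' @return integer-valued numeric vector proportional to `x`.
#' @keywords internal
integerize <- function(x, tol = 1e-9, max_denom = 1e6) {
  if (all(x == 0)) return(x)
  mult <- 1
  while (max(abs(x * mult - round(x * mult))) > tol * mult) {
    mult <- mult * 10
    if (mult > max_denom) {
      abort("Cannot represent coefficients as exact integers (denominator too large).")
    }
  }
  y <- round(x * mult)
  y / gcd_vec(y)
}

# Exact-integer overflow guard for the enumeration arithmetic: doubles hold
# integers exactly up to 2^53; we stop far earlier.
check_int_magnitude <- function(x, limit = 2^40) {
  if (any(abs(x) > limit)) {
    abort("Integer arithmetic overflow guard tripped during ray enumeration.")
  }
  invisible(x)
}

# Strip a compartment suffix ("_c", "[c]") from a metabolite id, given the
# compartment tag, to obtain the base name used for currency matching.
met_base_name <- function(id, compartment) {
  base <- sub(paste0("\\[", compartment, "\\]$"), "", id)
  base <- sub(paste0("_", compartment, "$"), "", base)
  # generic fallback: a single trailing _<tag> of 1-2 characters
  if (identical(base, id)) base <- sub("_[a-z0-9]{1,2}$", "", id)
  tolower(base)
}

near_zero <- function(x, tol = 1e-9) abs(x) < tol
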