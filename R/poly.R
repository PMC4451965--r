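# Sparse multilinear sign polynomials in the gamma variables.
#
# A monomial is a set of factors g[i,j] with pairwise-distinct species
# indices i; it is encoded as the string "i.j|k.l|..." with factors sorted
# by species index. The empty product is "".

mono_key <- function(species, reaction) {
  if (!length(species)) return("")
  o <- order(species)
  paste(species[o], reaction[o], sep = ".", collapse = "|")
}

mono_factors <- function(key) {
  if (identical(key, "")) {
    return(matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("species", "reaction"))))
  }
  parts <- strsplit(strsplit(key, "|", fixed = TRUE)[[1]], ".", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("species", "reaction")))
  m
}

mono_pretty <- function(key) {
  if (identical(key, "")) return("1")
  f <- mono_factors(key)
  paste(sprintf("g[%d,%d]", f[, 1], f[, 2]), collapse = "*")
}

# merge-add two named numeric vectors of coefficients (exact integers)
coef_add <- function(a, b) {
  if (!length(a)) return(b[b != 0])
  if (!length(b)) return(a[a != 0])
  v <- c(a, b)
  out <- vapply(split(unname(v), names(v)), sum, 0)
  out[out != 0]
}

# Construct a sign_poly from integer numerators over a common denominator.
new_sign_poly <- function(coefs, den = 1, degree = NA_integer_) {
  coefs <- coefs[coefs != 0]
  if (length(coefs)) {
    red <- rat_reduce(unname(coefs), rep(den, length(coefs)))
    num <- red$num
    dn <- red$den
    names(num) <- names(dn) <- names(coefs)
    o <- order(names(num))
    num <- num[o]; dn <- dn[o]
  } else {
    num <- dn <- numeric(0)
  }
  if (is.na(degree)) {
    degree <- if (length(num)) {
      max(vapply(names(num), function(k) nrow(mono_factors(k)), 0L))
    } else 0L
  }
  structure(list(num = num, den = dn, degree = as.integer(degree)),
            class = "sign_poly")
}

#' Number of terms of a sign polynomial
#' @param p A \code{sign_poly}.
#' @return Integer count of stored (nonzero) terms.
#' @export
n_terms <- function(p) {
  stopifnot(inherits(p, "sign_poly"))
  length(p$num)
}

#' Terms of a sign polynomial as a data frame
#'
#' @param p A \code{sign_poly}.
#' @return A data frame with one row per term: \code{monomial} (canonical
#'   key), \code{pretty} (printed form), \code{num}, \code{den} (reduced
#'   rational coefficient) and \code{sign}. Terms are in canonical monomial
#'   order (sorted keys).
#' @export
poly_terms <- function(p) {
  stopifnot(inherits(p, "sign_poly"))
  data.frame(monomial = names(p$num),
             pretty = vapply(names(p$num), mono_pretty, ""),
             num = unname(p$num),
             den = unname(p$den),
             sign = sign(unname(p$num)),
             stringsAsFactors = FALSE, row.names = NULL)
}

fmt_coef <- function(num, den) {
  if (den == 1) sprintf("%g", abs(num)) else sprintf("%g/%g", abs(num), den)
}

#' Render a sign polynomial as canonical text
#'
#' Terms are printed in canonical monomial order (factors sorted by species
#' index, monomials sorted lexicographically) as \code{+/-c*g[i,j]*g[k,l]};
#' unit coefficients are omitted. The rendering is exactly reproducible, so
#' it is suitable for golden-file comparison.
#'
#' @param p A \code{sign_poly}.
#' @return A character scalar, \code{"0"} for the empty polynomial.
#' @export
format_polynomial <- function(p) {
  stopifnot(inherits(p, "sign_poly"))
  if (!length(p$num)) return("0")
  bits <- vapply(seq_along(p$num), function(t) {
    sgn <- if (p$num[t] > 0) "+" else "-"
    cf <- if (abs(p$num[t]) == 1 && p$den[t] == 1) ""
          else paste0(fmt_coef(p$num[t], p$den[t]), "*")
    paste0(sgn, cf, mono_pretty(names(p$num)[t]))
  }, character(1))
  paste(bits, collapse = " ")
}

#' @export
format.sign_poly <- function(x, ...) format_polynomial(x)

#' @export
print.sign_poly <- function(x, ...) {
  cat(sprintf("Sign polynomial, degree %d, %d terms (%d positive, %d negative)\n",
              x$degree, length(x$num), sum(x$num > 0), sum(x$num < 0)))
  cat(format_polynomial(x), "\n")
  invisible(x)
}

# exact equality of two sign polynomials
poly_equal <- function(p, q) {
  identical(names(p$num), names(q$num)) &&
    isTRUE(all.equal(unname(p$num), unname(q$num))) &&
    isTRUE(all.equal(unname(p$den), unname(q$den)))
}

# substitute gamma_{i,j} = 0: drop every term containing the factor
poly_zero_gamma <- function(p, species, reaction) {
  stopifnot(inherits(p, "sign_poly"))
  if (!length(p$num)) return(p)
  keep <- vapply(names(p$num), function(k) {
    f <- mono_factors(k)
    !any(f[, 1] == species & f[, 2] == reaction)
  }, logical(1))
  structure(list(num = p$num[keep], den = p$den[keep], degree = p$degree),
            class = "sign_poly")
}

#' Terms of the injectivity polynomial with the wrong sign
#'
#' For a network of rank s, a 2s-nucleus of the signed DSR-graph built only
#' from negative feedback loops contributes sign (-1)^s to the injectivity
#' polynomial. Terms of sign (-1)^(s+1) -- the "wrong sign" -- therefore
#' require at least one positive feedback loop, and they are the only
#' terms that can carry multistationarity.
#'
#' @param p A \code{sign_poly} of degree \code{s}.
#' @param s Rank of the stoichiometric matrix.
#' @return Data frame (subset of [poly_terms()]) holding the wrong-sign
#'   terms; zero rows when all terms carry the sign \code{(-1)^s}.
#' @export
wrong_sign_terms <- function(p, s) {
  tt <- poly_terms(p)
  wrong <- if (s %% 2 == 0) -1 else 1
  tt[tt$sign == wrong, , drop = FALSE]
}

#' Injectivity verdict from the sign pattern of the polynomial
#'
#' If the injectivity polynomial is not identically zero and all its
#' coefficients share one sign, the species-formation rate map is injective
#' on every positive stoichiometric compatibility class, so the network
#' cannot be multistationary for any kinetics with the given influence
#' pattern.
#'
#' @param p A \code{sign_poly}.
#' @return One of \code{"INJECTIVE"} (nonzero, single-signed),
#'   \code{"INCONCLUSIVE"} (both signs present: multistationarity cannot be
#'   excluded) or \code{"DEGENERATE"} (identically zero).
#' @export
injectivity_verdict <- function(p) {
  stopifnot(inherits(p, "sign_poly"))
  if (!length(p$num)) return("DEGENERATE")
  if (all(p$num > 0) || all(p$num < 0)) return("INJECTIVE")
  "INCONCLUSIVE"
}
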