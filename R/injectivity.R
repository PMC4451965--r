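#' Gauss-reduced basis of the conservation laws
#'
#' Computes the left kernel of the stoichiometric matrix -- the vectors
#' \eqn{\omega} with \eqn{\omega A = 0}, i.e. the conservation laws whose
#' level sets carve out the stoichiometric compatibility classes -- as a
#' basis in reduced row echelon form (RREF): each vector's first nonzero
#' entry is 1, the pivot positions are strictly increasing, and every pivot
#' position is zero in all other basis vectors. The RREF normalization pins
#' the basis uniquely, which makes the injectivity polynomial reproducible
#' bit for bit.
#'
#' @param A A \code{stoich_matrix}.
#' @return An object of class \code{kernel_basis}: list with rational
#'   \code{num}/\code{den} matrices (d x n, one basis vector per row),
#'   integer \code{pivots} (1-based index of each vector's first nonzero
#'   entry, strictly increasing) and \code{d} = n - rank(A). Full-rank
#'   matrices yield the empty basis (d = 0).
#' @export
left_kernel_basis <- function(A) {
  stopifnot(inherits(A, "stoich_matrix"))
  n <- nrow(A$mat)
  # omega A = 0  <=>  t(A) omega^t = 0
  ns <- nullspace_rational(rat_mat(t(A$mat) * 1.0))
  if (nrow(ns$num) == 0) {
    return(structure(list(num = matrix(0, 0, n), den = matrix(1, 0, n),
                          pivots = integer(0), d = 0L),
                     class = "kernel_basis"))
  }
  R <- rref_rational(ns)
  keep <- which(apply(R$num, 1, function(r) any(r != 0)))
  num <- R$num[keep, , drop = FALSE]
  den <- R$den[keep, , drop = FALSE]
  pivots <- vapply(seq_len(nrow(num)), function(r) which(num[r, ] != 0)[1L], 0L)
  structure(list(num = num, den = den, pivots = pivots, d = nrow(num)),
            class = "kernel_basis")
}

#' @export
print.kernel_basis <- function(x, ...) {
  cat(sprintf("Conservation-law basis: %d vector(s)\n", x$d))
  for (r in seq_len(x$d)) {
    v <- ifelse(x$den[r, ] == 1, sprintf("%g", x$num[r, ]),
                sprintf("%g/%g", x$num[r, ], x$den[r, ]))
    cat(sprintf("  w%d (pivot %d): (%s)\n", r, x$pivots[r],
                paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Injectivity polynomial p of a network
#'
#' Forms the symbolic n x n matrix \eqn{M = A Z^t} whose (i,k) entry is the
#' linear form \eqn{\sum_j a_{ij}\, \mathrm{sign}(z_{kj})\, g_{kj}},
#' replaces row \eqn{i_j} by the j-th vector of the Gauss-reduced
#' conservation-law basis (pivots \eqn{i_1 < \dots < i_d}), and expands the
#' determinant of the resulting matrix exactly. The result is a multilinear
#' polynomial of degree s = rank(A) in the gamma variables; its nonzero
#' terms have pairwise-distinct species and reaction indices.
#'
#' The expansion runs column by column with memoization on the set of used
#' rows (O(2^n * n) symbolic steps); all arithmetic is exact (integers over
#' a cleared common denominator), so term signs are never subject to
#' rounding.
#'
#' @param A A \code{stoich_matrix}.
#' @param Z An \code{influence_matrix} of matching dimensions.
#' @return A \code{sign_poly}; the empty polynomial if the determinant is
#'   identically zero.
#' @export
injectivity_polynomial <- function(A, Z) {
  stopifnot(inherits(A, "stoich_matrix"), inherits(Z, "influence_matrix"))
  n <- nrow(A$mat); m <- ncol(A$mat)
  if (nrow(Z$sign) != n || ncol(Z$sign) != m) {
    stop(sprintf("dimension mismatch: A is %dx%d, Z is %dx%d",
                 n, m, nrow(Z$sign), ncol(Z$sign)), call. = FALSE)
  }
  kb <- left_kernel_basis(A)
  s <- A$rank
  # clear denominators of the replaced rows; the common denominator D is
  # divided back out of the final coefficients
  D <- 1
  omega <- matrix(0, kb$d, n)
  for (r in seq_len(kb$d)) {
    Dr <- Reduce(lcm2, kb$den[r, ], accumulate = FALSE)
    omega[r, ] <- kb$num[r, ] * (Dr / kb$den[r, ])
    D <- D * Dr
  }
  replaced <- integer(n)            # 0 = plain row, else basis-vector index
  replaced[kb$pivots] <- seq_len(kb$d)

  # entries[[k]][[i]]: column k, row i
  entries <- vector("list", n)
  Amat <- A$mat
  Zs <- Z$sign
  for (k in seq_len(n)) {
    col <- vector("list", n)
    js_k <- which(Zs[k, ] != 0)
    for (i in seq_len(n)) {
      if (replaced[i] > 0L) {
        col[[i]] <- list(type = "const", v = omega[replaced[i], k])
      } else {
        js <- js_k[Amat[i, js_k] != 0]
        if (length(js)) {
          col[[i]] <- list(type = "lin", j = js,
                           coef = Amat[i, js] * Zs[k, js])
        } else {
          col[[i]] <- list(type = "const", v = 0)
        }
      }
    }
    entries[[k]] <- col
  }

  memo <- new.env(parent = emptyenv())
  rec <- function(k, avail) {
    if (k > n) {
      out <- 1
      names(out) <- ""
      return(out)
    }
    key <- paste(avail, collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    acc <- numeric(0)
    for (t in seq_along(avail)) {
      i <- avail[t]
      e <- entries[[k]][[i]]
      if (e$type == "const" && e$v == 0) next
      sub <- rec(k + 1L, avail[-t])
      if (!length(sub)) next
      sgn <- if (t %% 2L == 1L) 1 else -1
      if (e$type == "const") {
        contrib <- sub * (sgn * e$v)
      } else {
        contrib <- numeric(0)
        nm <- names(sub)
        for (q in seq_along(e$j)) {
          fct <- paste0(k, ".", e$j[q])
          v <- sub * (sgn * e$coef[q])
          names(v) <- ifelse(nm == "", fct, paste0(fct, "|", nm))
          contrib <- coef_add(contrib, v)
        }
      }
      acc <- coef_add(acc, contrib)
    }
    memo[[key]] <- acc
    acc
  }
  coefs <- rec(1L, seq_len(n))
  new_sign_poly(coefs, den = D, degree = s)
}

#' Zero one influence entry (break an edge of the DSR-graph)
#'
#' Setting z_ij = 0 removes the species -> reaction edge X_i -> r_j from the
#' DSR-graph and, equivalently, substitutes g[i,j] = 0 into the injectivity
#' polynomial. Used to test the loop-breaking property: once one edge of
#' every relevant positive feedback loop is removed, all wrong-sign terms
#' disappear.
#'
#' @param Z An \code{influence_matrix}.
#' @param species,reaction 1-based indices of the entry to zero.
#' @return The modified \code{influence_matrix}.
#' @export
zero_influence <- function(Z, species, reaction) {
  stopifnot(inherits(Z, "influence_matrix"))
  Z$sign[species, reaction] <- 0L
  Z
}
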