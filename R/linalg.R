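# Exact rational linear algebra on small matrices.
#
# Rationals are stored as parallel double matrices of numerators and
# (positive) denominators; all values stay well below 2^53 at the problem
# sizes this package targets, so double arithmetic is exact.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

# reduce num/den to lowest terms, den > 0
rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  g <- mapply(gcd2, num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  list(num = num, den = den)
}

rat_mat <- function(num, den = NULL) {
  if (is.null(den)) den <- array(1, dim(num))
  list(num = num, den = den)
}

# Reduced row echelon form of a rational matrix.
# Returns list(num, den, pivots) with pivots = pivot column per nonzero row.
rref_rational <- function(M) {
  num <- M$num
  den <- M$den
  nr <- nrow(num)
  nc <- ncol(num)
  pivots <- integer(0)
  r <- 1L
  for (c in seq_len(nc)) {
    if (r > nr) break
    # pick first row >= r with nonzero entry in column c
    piv <- which(num[r:nr, c] != 0)
    if (!length(piv)) next
    i <- r + piv[1L] - 1L
    if (i != r) {
      tmp <- num[r, ]; num[r, ] <- num[i, ]; num[i, ] <- tmp
      tmp <- den[r, ]; den[r, ] <- den[i, ]; den[i, ] <- tmp
    }
    # normalize pivot row to leading 1: divide by num[r,c]/den[r,c]
    pn <- num[r, c]; pd <- den[r, c]
    rr <- rat_reduce(num[r, ] * pd, den[r, ] * pn)
    num[r, ] <- rr$num; den[r, ] <- rr$den
    # eliminate column c from all other rows
    for (k in seq_len(nr)) {
      if (k == r || num[k, c] == 0) next
      fn <- num[k, c]; fd <- den[k, c]
      # row_k <- row_k - (fn/fd) * row_r
      new_num <- num[k, ] * fd * den[r, ] - fn * num[r, ] * den[k, ]
      new_den <- den[k, ] * fd * den[r, ]
      rr <- rat_reduce(new_num, new_den)
      num[k, ] <- rr$num; den[k, ] <- rr$den
    }
    pivots <- c(pivots, c)
    r <- r + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

rank_rational <- function(M) {
  length(rref_rational(M)$pivots)
}

# Basis of the null space {x : Mx = 0} of a rational matrix, one basis
# vector per free column, returned as rows of a rational matrix.
nullspace_rational <- function(M) {
  nc <- ncol(M$num)
  R <- rref_rational(M)
  piv <- R$pivots
  free <- setdiff(seq_len(nc), piv)
  d <- length(free)
  num <- matrix(0, d, nc)
  den <- matrix(1, d, nc)
  for (k in seq_along(free)) {
    f <- free[k]
    num[k, f] <- 1
    for (r in seq_along(piv)) {
      if (R$num[r, f] != 0) {
        num[k, piv[r]] <- -R$num[r, f]
        den[k, piv[r]] <- R$den[r, f]
      }
    }
  }
  rat_mat(num, den)
}
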