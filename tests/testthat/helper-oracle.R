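# Brute-force oracle: the injectivity polynomial as a naive permutation-sum
# determinant of the row-replaced symbolic matrix. The representation is
# deliberately different from the package's memoized column expansion:
# polynomials are plain named vectors keyed by sorted factor strings and the
# sum runs over all n! permutations. Tractable for n <= 5 (plus the 6-node
# apoptosis fixture is out of its reach on purpose; the acceptance suite
# uses it only on small instances).

oracle_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1L)) {
    for (pos in 0L:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

oracle_perm_sign <- function(p) {
  inv <- 0L
  n <- length(p)
  for (a in seq_len(n - 1L)) {
    inv <- inv + sum(p[a] > p[(a + 1L):n])
  }
  if (inv %% 2L == 0L) 1 else -1
}

# canonical monomial key matching the package's ("i.j|k.l", sorted by
# species index), rebuilt here from scratch
oracle_key <- function(sp, rx) {
  if (!length(sp)) return("")
  o <- order(sp)
  paste(sp[o], rx[o], sep = ".", collapse = "|")
}

# polynomial as named numeric over a common integer denominator D
oracle_poly_det <- function(A, Z) {
  n <- nrow(A$mat)
  kb <- left_kernel_basis(A)
  D <- 1
  omega <- matrix(0, kb$d, n)
  for (r in seq_len(kb$d)) {
    Dr <- Reduce(function(a, b) abs(a / dsrloops:::gcd2(a, b) * b),
                 kb$den[r, ])
    omega[r, ] <- kb$num[r, ] * (Dr / kb$den[r, ])
    D <- D * Dr
  }
  replaced <- integer(n)
  replaced[kb$pivots] <- seq_len(kb$d)

  # entry (i, k): list of terms (coef, sp, rx); constants have sp = NULL
  entry <- function(i, k) {
    if (replaced[i] > 0L) {
      v <- omega[replaced[i], k]
      if (v == 0) return(list())
      return(list(list(coef = v, sp = integer(0), rx = integer(0))))
    }
    js <- which(Z$sign[k, ] != 0 & A$mat[i, ] != 0)
    lapply(js, function(j) {
      list(coef = A$mat[i, j] * Z$sign[k, j], sp = k, rx = j)
    })
  }
  acc <- new.env(parent = emptyenv())
  for (perm in oracle_permutations(n)) {
    sgn <- oracle_perm_sign(perm)
    # product over columns k of entry(perm[k], k)
    terms <- list(list(coef = sgn, sp = integer(0), rx = integer(0)))
    for (k in seq_len(n)) {
      e <- entry(perm[k], k)
      if (!length(e)) { terms <- list(); break }
      nxt <- list()
      for (t1 in terms) {
        for (t2 in e) {
          nxt[[length(nxt) + 1L]] <- list(coef = t1$coef * t2$coef,
                                          sp = c(t1$sp, t2$sp),
                                          rx = c(t1$rx, t2$rx))
        }
      }
      terms <- nxt
    }
    for (t in terms) {
      key <- oracle_key(t$sp, t$rx)
      cur <- acc[[key]]
      acc[[key]] <- if (is.null(cur)) t$coef else cur + t$coef
    }
  }
  keys <- ls(acc)
  vals <- vapply(keys, function(k) acc[[k]], 0)
  keep <- vals != 0
  list(coefs = vals[keep], keys = keys[keep], den = D)
}

# render the oracle result with the same conventions as format_polynomial
oracle_poly_string <- function(A, Z) {
  o <- oracle_poly_det(A, Z)
  if (!length(o$coefs)) return("0")
  ord <- order(o$keys)
  keys <- o$keys[ord]
  coefs <- o$coefs[ord]
  bits <- vapply(seq_along(keys), function(t) {
    g <- dsrloops:::gcd2(coefs[t], o$den)
    num <- coefs[t] / g
    den <- o$den / g
    pretty <- if (keys[t] == "") "1" else {
      f <- do.call(rbind, strsplit(strsplit(keys[t], "|", fixed = TRUE)[[1]],
                                   ".", fixed = TRUE))
      paste(sprintf("g[%s,%s]", f[, 1], f[, 2]), collapse = "*")
    }
    cf <- if (abs(num) == 1 && den == 1) "" else {
      if (den == 1) sprintf("%g*", abs(num)) else sprintf("%g/%g*", abs(num), den)
    }
    paste0(if (num > 0) "+" else "-", cf, pretty)
  }, character(1))
  paste(bits, collapse = " ")
}
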