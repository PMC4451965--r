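# Signed DSR-graph: circuits, nuclei and relevant positive feedback loops.
#
# Node ids: reactions are 1..m, species are m+1..m+n. Reactions sorting
# before species makes the minimal node of any circuit a reaction node,
# which pins the canonical rotation used for deduplication and for motif
# signatures.

#' Build the (signed) DSR-graph of a network
#'
#' The directed species-reaction graph is bipartite: there is an edge
#' X_i -> r_j labelled z_ij for every nonzero influence entry, and an edge
#' r_j -> X_i labelled a_ij for every nonzero stoichiometric entry. The
#' signed DSR-graph replaces labels by their signs; circuit positivity is
#' defined on the signed graph, while the integer magnitudes of a_ij enter
#' only the nucleus-expansion coefficients.
#'
#' @param A A \code{stoich_matrix}.
#' @param Z An \code{influence_matrix} of matching dimensions.
#' @return An object of class \code{dsr_graph}.
#' @export
build_dsr_graph <- function(A, Z) {
  stopifnot(inherits(A, "stoich_matrix"), inherits(Z, "influence_matrix"))
  n <- nrow(A$mat); m <- ncol(A$mat)
  if (nrow(Z$sign) != n || ncol(Z$sign) != m) {
    stop(sprintf("dimension mismatch: A is %dx%d, Z is %dx%d",
                 n, m, nrow(Z$sign), ncol(Z$sign)), call. = FALSE)
  }
  structure(list(n = n, m = m,
                 species = rownames(A$mat), rids = colnames(A$mat),
                 a = A$mat, z = Z$sign),
            class = "dsr_graph")
}

#' @export
print.dsr_graph <- function(x, ...) {
  cat(sprintf("DSR-graph: %d species + %d reaction nodes, %d S->R edges, %d R->S edges\n",
              x$n, x$m, sum(x$z != 0), sum(x$a != 0)))
  invisible(x)
}

dsr_node_name <- function(G, id) {
  out <- character(length(id))
  isr <- id <= G$m
  out[isr] <- G$rids[id[isr]]
  out[!isr] <- G$species[id[!isr] - G$m]
  out
}

# adjacency list over node ids, successors in ascending id order
dsr_adjacency <- function(G) {
  N <- G$m + G$n
  adj <- vector("list", N)
  for (j in seq_len(G$m)) adj[[j]] <- G$m + which(G$a[, j] != 0)
  for (i in seq_len(G$n)) adj[[G$m + i]] <- which(G$z[i, ] != 0)
  adj
}

# Build a circuit object from a directed node sequence (must follow edges,
# wrap-around included). Rotates to the canonical start (minimal node id).
circuit_from_nodes <- function(G, nodes) {
  nodes <- unname(nodes)
  q <- length(nodes)
  r0 <- which.min(nodes)
  if (r0 != 1L) nodes <- c(nodes[r0:q], nodes[seq_len(r0 - 1L)])
  signs <- integer(q)
  lvalue <- 1
  fsp <- integer(0); frx <- integer(0)
  for (t in seq_len(q)) {
    v <- nodes[t]
    w <- nodes[if (t == q) 1L else t + 1L]
    if (v > G$m) {
      i <- v - G$m; j <- w
      val <- G$z[i, j]
      fsp <- c(fsp, i); frx <- c(frx, j)
    } else {
      j <- v; i <- w - G$m
      val <- G$a[i, j]
    }
    if (val == 0) {
      stop("node sequence does not follow DSR-graph edges", call. = FALSE)
    }
    signs[t] <- sign(val)
    lvalue <- lvalue * val
  }
  structure(list(nodes = nodes, signs = signs,
                 species_count = sum(nodes > G$m),
                 sign = sign(lvalue), lvalue = lvalue,
                 factors = cbind(species = fsp, reaction = frx),
                 key = paste(nodes, collapse = "-")),
            class = "dsr_circuit")
}

#' @export
format.dsr_circuit <- function(x, ..., graph = NULL) {
  lab <- if (is.null(graph)) as.character(x$nodes) else dsr_node_name(graph, x$nodes)
  sgn <- ifelse(x$signs > 0, "+", "-")
  paste0(paste0(lab, " -(", sgn, ")-> ", collapse = ""), lab[1])
}

#' @export
print.dsr_circuit <- function(x, ...) {
  cat(sprintf("Circuit (%s, %d species nodes): %s\n",
              if (x$sign > 0) "positive" else "negative",
              x$species_count, format(x, ...)))
  invisible(x)
}

#' Enumerate all elementary circuits of a DSR-graph
#'
#' Every directed cycle through distinct nodes, each reported once in its
#' canonical rotation (starting at its minimal node id, which is always a
#' reaction node), with the edge-sign sequence, the species-node count and
#' the circuit sign (product of signed edge labels). Positive circuits are
#' the positive feedback loops of the network.
#'
#' Enumeration is a rooted depth-first search restricted to nodes no
#' smaller than the root, so output order is deterministic.
#'
#' @param G A \code{dsr_graph}.
#' @return List of \code{dsr_circuit} objects.
#' @export
enumerate_circuits <- function(G) {
  adj <- dsr_adjacency(G)
  N <- G$m + G$n
  circuits <- list()
  for (start in seq_len(N)) {
    path <- integer(0)
    onpath <- logical(N)
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      onpath[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w == start) {
          circuits[[length(circuits) + 1L]] <<- circuit_from_nodes(G, path)
        } else if (w > start && !onpath[w]) {
          dfs(w)
        }
      }
      onpath[path[length(path)]] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(start)
  }
  circuits
}

nucleus_from_circuits <- function(circuits) {
  a2 <- sum(vapply(circuits, function(c) c$species_count %% 2L == 0L, TRUE))
  a1 <- length(circuits) - a2
  sgn <- (-1)^a2 * prod(vapply(circuits, `[[`, 0, "sign"))
  nodes <- sort(unlist(lapply(circuits, `[[`, "nodes")))
  structure(list(circuits = circuits, a1 = a1, a2 = a2,
                 sign = as.integer(sgn), nodes = nodes),
            class = "dsr_nucleus")
}

#' Sign of a nucleus
#'
#' A k-nucleus D, a union of pairwise node-disjoint circuits C_1..C_a
#' covering k nodes, carries the sign of \eqn{\sigma(D)\ell(D) =
#' (-1)^{a_2} \prod_i \ell(C_i)} on the signed graph, where a_2 counts the
#' circuits with an even number of species nodes. When no circuit of a
#' 2s-nucleus is a positive feedback loop this sign is necessarily
#' \eqn{(-1)^s}; a 2s-nucleus of sign \eqn{(-1)^{s+1}} must therefore
#' contain a positive feedback loop.
#'
#' @param D A \code{dsr_nucleus}.
#' @param s Optional rank; when given, the nucleus is checked to cover
#'   exactly 2s nodes.
#' @return \code{+1} or \code{-1}.
#' @export
nucleus_sign <- function(D, s = NULL) {
  stopifnot(inherits(D, "dsr_nucleus"))
  if (!is.null(s) && length(D$nodes) != 2L * s) {
    stop(sprintf("nucleus covers %d nodes, expected 2s = %d",
                 length(D$nodes), 2L * s), call. = FALSE)
  }
  D$sign
}

#' @export
print.dsr_nucleus <- function(x, ...) {
  cat(sprintf("%d-nucleus, sign %s, %d circuit(s) (a1 = %d, a2 = %d)\n",
              length(x$nodes), if (x$sign > 0) "+1" else "-1",
              length(x$circuits), x$a1, x$a2))
  for (c in x$circuits) cat("  ", format(c), "\n")
  invisible(x)
}

#' 2s-nuclei realizing a monomial of the injectivity polynomial
#'
#' A degree-s monomial g[i1,j1]...g[is,js] fixes the s species -> reaction
#' edges X_ik -> r_jk. Completing it into a 2s-nucleus means choosing s
#' reaction -> species edges from \{r_j1..r_js\} back onto \{X_i1..X_is\}
#' -- a perfect matching supported on nonzero stoichiometric entries. Each
#' such matching closes a union of disjoint circuits covering all 2s nodes.
#'
#' Matchings are enumerated by backtracking over the reaction nodes in
#' index order, so the output order is deterministic.
#'
#' @param G A \code{dsr_graph}.
#' @param term A monomial: either its canonical key string (see
#'   [poly_terms()]) or a 2-column matrix of (species, reaction) index
#'   pairs.
#' @return List of \code{dsr_nucleus} objects (possibly empty).
#' @export
nuclei_for_term <- function(G, term) {
  f <- if (is.character(term)) mono_factors(term) else {
    m <- as.matrix(term)
    storage.mode(m) <- "integer"
    colnames(m) <- c("species", "reaction")
    m
  }
  s <- nrow(f)
  if (!s) stop("empty term", call. = FALSE)
  for (k in seq_len(s)) {
    if (G$z[f[k, 1], f[k, 2]] == 0) {
      stop(sprintf("factor g[%d,%d] is not an edge of the DSR-graph",
                   f[k, 1], f[k, 2]), call. = FALSE)
    }
  }
  if (anyDuplicated(f[, 1]) || anyDuplicated(f[, 2])) {
    stop("term has repeated species or reaction indices", call. = FALSE)
  }
  I <- unname(f[, 1]); J <- unname(f[, 2])
  ord <- order(J)
  res <- list()
  match_to <- integer(s)            # position p in ord -> index u into I
  used <- logical(s)
  bt <- function(p) {
    if (p > s) {
      # successor map: species m+I[k] -> J[k]; reaction J[ord[p]] -> m+I[u]
      succ <- integer(G$m + G$n)
      for (k in seq_len(s)) succ[G$m + I[k]] <- J[k]
      for (q in seq_len(s)) succ[J[ord[q]]] <- G$m + I[match_to[q]]
      # decompose the functional digraph into circuits
      seen <- logical(G$m + G$n)
      circuits <- list()
      for (k in seq_len(s)) {
        v0 <- G$m + I[k]
        if (seen[v0]) next
        seq_nodes <- integer(0)
        v <- v0
        repeat {
          seq_nodes <- c(seq_nodes, v)
          seen[v] <- TRUE
          v <- succ[v]
          if (v == v0) break
        }
        circuits[[length(circuits) + 1L]] <- circuit_from_nodes(G, seq_nodes)
      }
      res[[length(res) + 1L]] <<- nucleus_from_circuits(circuits)
      return(invisible())
    }
    jj <- J[ord[p]]
    for (u in seq_len(s)) {
      if (!used[u] && G$a[I[u], jj] != 0) {
        used[u] <<- TRUE
        match_to[p] <<- u
        bt(p + 1L)
        used[u] <<- FALSE
      }
    }
  }
  bt(1L)
  res
}

#' Injectivity polynomial by global nucleus expansion
#'
#' Independent reconstruction of the injectivity polynomial from the
#' DSR-graph alone: the polynomial equals the sum of
#' \eqn{\sigma(D)\ell(D)} over all 2s-nuclei D of the graph, taken over
#' all size-s species and reaction index sets. Here the circuit labels
#' keep the integer stoichiometric magnitudes, which multiply into the
#' coefficients. The implementation enumerates all elementary circuits and
#' then all node-disjoint collections totalling s species nodes, a
#' different algorithm from the determinant expansion of
#' [injectivity_polynomial()], so agreement of the two is a strong
#' cross-check (used in the test suite).
#'
#' @param G A \code{dsr_graph}.
#' @param s Rank of the stoichiometric matrix (nucleus size is 2s).
#' @return A \code{sign_poly}.
#' @export
nucleus_expansion <- function(G, s) {
  circuits <- enumerate_circuits(G)
  nc <- length(circuits)
  coefs_env <- new.env(parent = emptyenv())
  N <- G$m + G$n
  used <- logical(N)
  # suffix species-count sums for pruning
  spc <- vapply(circuits, `[[`, 0L, "species_count")
  suffix <- rev(cumsum(rev(spc)))
  suffix <- c(suffix, 0L)
  acc <- numeric(0)
  emit <- function(sel) {
    a2 <- sum(spc[sel] %% 2L == 0L)
    coef <- (-1)^a2 * prod(vapply(circuits[sel], `[[`, 0, "lvalue"))
    fs <- do.call(rbind, lapply(circuits[sel], `[[`, "factors"))
    key <- mono_key(fs[, 1], fs[, 2])
    cur <- coefs_env[[key]]
    coefs_env[[key]] <- if (is.null(cur)) coef else cur + coef
  }
  sel <- integer(0)
  bt <- function(idx, budget) {
    if (budget == 0L) {
      emit(sel)
      return(invisible())
    }
    if (idx > nc || suffix[idx] < budget) return(invisible())
    # include circuits[idx] if disjoint and within budget
    ci <- circuits[[idx]]
    if (ci$species_count <= budget && !any(used[ci$nodes])) {
      used[ci$nodes] <<- TRUE
      sel[length(sel) + 1L] <<- idx
      bt(idx + 1L, budget - ci$species_count)
      sel <<- sel[-length(sel)]
      used[ci$nodes] <<- FALSE
    }
    bt(idx + 1L, budget)
  }
  if (s == 0L) {
    return(new_sign_poly(stats::setNames(1, ""), den = 1, degree = 0L))
  }
  bt(1L, as.integer(s))
  keys <- ls(coefs_env)
  coefs <- stats::setNames(vapply(keys, function(k) coefs_env[[k]], 0), keys)
  new_sign_poly(coefs, den = 1, degree = s)
}

#' Motif signature of a feedback loop
#'
#' The cyclic tuple of edge signs read around the circuit starting at a
#' reaction node, so that odd positions are labels of edges leaving
#' reaction nodes and even positions labels of edges leaving species
#' nodes. Rotating by an even number of positions (i.e. starting at a
#' different reaction node) yields the same motif; the signature is
#' canonicalized to the lexicographically smallest such rotation, with
#' \code{"+"} ordered before \code{"-"}.
#'
#' @param c A \code{dsr_circuit} in canonical rotation (starting at a
#'   reaction node, as produced by this package).
#' @return Signature string such as \code{"(+,+,-,+)"}.
#' @export
motif_signature <- function(c) {
  stopifnot(inherits(c, "dsr_circuit"))
  q <- length(c$signs)
  if (q %% 2L != 0L) stop("circuit does not alternate node kinds", call. = FALSE)
  # signs as 0 (+) / 1 (-) for lexicographic comparison
  v <- as.integer(c$signs < 0)
  best <- NULL
  for (off in seq(0L, q - 2L, by = 2L)) {
    rot <- v[((seq_len(q) - 1L + off) %% q) + 1L]
    if (is.null(best)) {
      best <- rot
    } else {
      for (t in seq_len(q)) {
        if (rot[t] < best[t]) { best <- rot; break }
        if (rot[t] > best[t]) break
      }
    }
  }
  paste0("(", paste(ifelse(best == 0L, "+", "-"), collapse = ","), ")")
}

#' Find the positive feedback loops relevant for multistationarity
#'
#' Runs the three-step structural procedure on a network with influence
#' matrix Z:
#' \enumerate{
#'   \item compute the injectivity polynomial of degree s = rank(A) and
#'     select its terms of wrong sign \eqn{(-1)^{s+1}};
#'   \item for each wrong-sign term, enumerate the 2s-nuclei of the DSR-graph
#'     realizing it and keep those whose sign is also \eqn{(-1)^{s+1}};
#'   \item collect the positive feedback loops (positive circuits) occurring
#'     in the kept nuclei.
#' }
#' The resulting loops are exactly the ones whose joint removal makes all
#' wrong-sign terms vanish, hence excludes multistationarity. Loops are
#' deduplicated across terms and nuclei; provenance (which terms produced
#' each loop) is recorded. If the polynomial is single-signed the verdict
#' is INJECTIVE and no loops are reported; the procedure cannot itself
#' establish that a network with wrong-sign terms is multistationary.
#'
#' @param net A \code{reaction_network}.
#' @param Z An \code{influence_matrix} for \code{net}; defaults to the
#'   mass-action influence pattern.
#' @return An object of class \code{loop_report}.
#' @export
find_relevant_loops <- function(net, Z = mass_action_influence(net)) {
  stopifnot(inherits(net, "reaction_network"))
  A <- stoichiometric_matrix(net)
  s <- A$rank
  p <- injectivity_polynomial(A, Z)
  verdict <- injectivity_verdict(p)
  G <- build_dsr_graph(A, Z)
  ws <- wrong_sign_terms(p, s)
  wrong <- if (s %% 2L == 0L) -1L else 1L

  nuclei_by_term <- list()
  wrong_nuclei <- list()
  loops_env <- new.env(parent = emptyenv())
  loop_order <- character(0)
  provenance <- list()
  if (verdict == "INCONCLUSIVE") {
    for (r in seq_len(nrow(ws))) {
      key <- ws$monomial[r]
      nuc <- nuclei_for_term(G, key)
      kept <- Filter(function(D) D$sign == wrong, nuc)
      nuclei_by_term[[key]] <- nuc
      wrong_nuclei[[key]] <- kept
      for (D in kept) {
        for (c in D$circuits) {
          if (c$sign > 0) {
            if (is.null(loops_env[[c$key]])) {
              loops_env[[c$key]] <- c
              loop_order <- c(loop_order, c$key)
              provenance[[c$key]] <- character(0)
            }
            provenance[[c$key]] <- union(provenance[[c$key]], key)
          }
        }
      }
    }
  }
  all_circuits <- enumerate_circuits(G)
  all_pos <- Filter(function(c) c$sign > 0, all_circuits)
  relevant <- lapply(loop_order, function(k) loops_env[[k]])
  structure(list(verdict = verdict, s = s,
                 polynomial = p,
                 wrong_sign_terms = ws,
                 nuclei_by_term = nuclei_by_term,
                 wrong_sign_nuclei = wrong_nuclei,
                 relevant_loops = relevant,
                 loop_provenance = provenance,
                 all_positive_loops = all_pos,
                 all_circuits = all_circuits,
                 network = net, graph = G,
                 stoich = A, influence = Z),
            class = "loop_report")
}
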