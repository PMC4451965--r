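#' Parse a reaction network from a plain-text reaction list
#'
#' Reads a reaction-list document in which every non-blank, non-comment line
#' describes one reaction:
#' \preformatted{
#'   id: LHS -> RHS      # irreversible
#'   id: LHS <-> RHS     # reversible, expands to id_f (LHS -> RHS)
#'                       # followed by id_r (RHS -> LHS)
#' }
#' Each side is a \code{"+"}-separated list of terms \code{"[coef] species"}
#' (coefficient defaults to 1, separated from the species name by
#' whitespace), or the literal \code{"0"} for an empty side (inflow/outflow).
#' Repeated species within one side sum their coefficients. Lines starting
#' with \code{"#"} and blank lines are ignored; trailing \code{"#"} comments
#' are stripped.
#'
#' Species are ordered by first appearance; reactions keep file order. A
#' reaction with both sides empty is rejected.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines.
#' @return An object of class \code{reaction_network}: a list with
#'   \code{species} (character vector) and \code{reactions} (list of
#'   \code{reaction} objects with \code{id}, \code{reactants},
#'   \code{products} named integer vectors).
#' @seealso [read_network()], [format.reaction_network()],
#'   [stoichiometric_matrix()]
#' @export
#' @examples
#' net <- parse_network("r1: Xcyt -> Xnuc
#' r2: Xnuc -> Xcyt
#' r3: Xnuc -> Xnucp
#' r4: Xnucp -> Xnuc")
#' net$species
parse_network <- function(text) {
  stopifnot(is.character(text), length(text) >= 1)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  species <- character(0)
  reactions <- list()
  ids <- character(0)

  parse_side <- function(side, lineno) {
    side <- trimws(side)
    if (side == "" ) {
      stop(sprintf("line %d: empty reaction side (use the literal '0')", lineno),
           call. = FALSE)
    }
    if (side == "0") return(integer(0))
    if (grepl("^\\+", side) || grepl("\\+$", side)) {
      stop(sprintf("line %d: dangling '+' in reaction side", lineno),
           call. = FALSE)
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- integer(0)
    for (tm in terms) {
      if (tm == "") {
        stop(sprintf("line %d: dangling '+' in reaction side", lineno),
             call. = FALSE)
      }
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1L; sp <- parts[1L]
      } else if (length(parts) == 2L) {
        coef_num <- suppressWarnings(as.numeric(parts[1L]))
        if (is.na(coef_num) || coef_num < 0 || coef_num != round(coef_num)) {
          stop(sprintf("line %d: coefficient '%s' is not a nonnegative integer",
                       lineno, parts[1L]), call. = FALSE)
        }
        coef <- as.integer(coef_num); sp <- parts[2L]
      } else {
        stop(sprintf("line %d: cannot parse term '%s'", lineno, tm),
             call. = FALSE)
      }
      if (grepl("^[0-9]", sp)) {
        stop(sprintf("line %d: species name '%s' may not start with a digit",
                     lineno, sp), call. = FALSE)
      }
      if (coef == 0L) next
      out[sp] <- if (sp %in% names(out)) out[[sp]] + coef else coef
    }
    out
  }

  add_reaction <- function(id, reactants, products, lineno) {
    if (id %in% ids) {
      stop(sprintf("line %d: duplicate reaction id '%s'", lineno, id),
           call. = FALSE)
    }
    if (!length(reactants) && !length(products)) {
      stop(sprintf("line %d: reaction '%s' has both sides empty", lineno, id),
           call. = FALSE)
    }
    for (sp in c(names(reactants), names(products))) {
      if (!sp %in% species) species <<- c(species, sp)
    }
    rx <- structure(list(id = id, reactants = reactants, products = products),
                    class = "reaction")
    reactions[[length(reactions) + 1L]] <<- rx
    ids <<- c(ids, id)
  }

  for (lineno in seq_along(lines)) {
    line <- sub("#.*$", "", lines[lineno])
    line <- trimws(line)
    if (line == "") next
    m <- regexec("^([^:]+):(.*)$", line)[[1]]
    if (m[1] == -1) {
      stop(sprintf("line %d: expected 'id: LHS -> RHS', got '%s'",
                   lineno, line), call. = FALSE)
    }
    id <- trimws(regmatches(line, regexec("^([^:]+):", line))[[1]][2])
    body <- trimws(sub("^[^:]+:", "", line))
    if (grepl("<->", body, fixed = TRUE)) {
      sides <- strsplit(body, "<->", fixed = TRUE)[[1]]
      if (length(sides) != 2L) {
        stop(sprintf("line %d: malformed reversible reaction", lineno),
             call. = FALSE)
      }
      lhs <- parse_side(sides[1], lineno)
      rhs <- parse_side(sides[2], lineno)
      if (!length(lhs) && !length(rhs)) {
        stop(sprintf("line %d: reaction '%s' has both sides empty", lineno, id),
             call. = FALSE)
      }
      add_reaction(paste0(id, "_f"), lhs, rhs, lineno)
      add_reaction(paste0(id, "_r"), rhs, lhs, lineno)
    } else if (grepl("->", body, fixed = TRUE)) {
      sides <- strsplit(body, "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L) {
        stop(sprintf("line %d: malformed reaction arrow", lineno),
             call. = FALSE)
      }
      add_reaction(id, parse_side(sides[1], lineno),
                   parse_side(sides[2], lineno), lineno)
    } else {
      stop(sprintf("line %d: no reaction arrow ('->' or '<->') found", lineno),
           call. = FALSE)
    }
  }
  if (!length(reactions)) stop("no reactions found in input", call. = FALSE)
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' Read a reaction network from a file
#'
#' @param path Path to a UTF-8 reaction-list file (see [parse_network()]).
#' @return A \code{reaction_network}.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  parse_network(readLines(path, warn = FALSE))
}

#' @export
format.reaction_network <- function(x, ...) {
  fmt_side <- function(v) {
    if (!length(v)) return("0")
    paste(ifelse(v == 1L, names(v), paste(v, names(v))), collapse = " + ")
  }
  vapply(x$reactions, function(r) {
    paste0(r$id, ": ", fmt_side(r$reactants), " -> ", fmt_side(r$products))
  }, character(1))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Serialize a network back to reaction-list text
#'
#' The output re-parses to an identical network (same species and reaction
#' order, ids and coefficients); reversible pairs are written pre-expanded.
#'
#' @param net A \code{reaction_network}.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to a file.
#' @export
write_network <- function(net, path = NULL) {
  lines <- format(net)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# coefficient of species sp in named integer vector side
side_coef <- function(side, sp) {
  if (sp %in% names(side)) side[[sp]] else 0L
}

#' Stoichiometric matrix of a reaction network
#'
#' Builds the n x m integer matrix with entry \eqn{a_{ij} = \beta_{ij} -
#' \alpha_{ij}}, the net production of species i by reaction j, and computes
#' its rank s exactly over the rationals.
#'
#' @param net A \code{reaction_network}.
#' @return An object of class \code{stoich_matrix}: list with \code{mat}
#'   (integer matrix, species x reactions, dimnames set) and \code{rank}.
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  n <- length(net$species)
  m <- length(net$reactions)
  A <- matrix(0L, n, m,
              dimnames = list(net$species,
                              vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_len(m)) {
    r <- net$reactions[[j]]
    for (sp in names(r$reactants)) {
      A[sp, j] <- A[sp, j] - r$reactants[[sp]]
    }
    for (sp in names(r$products)) {
      A[sp, j] <- A[sp, j] + r$products[[sp]]
    }
  }
  s <- rank_rational(rat_mat(A * 1.0))
  structure(list(mat = A, rank = s), class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat(sprintf("Stoichiometric matrix (%d species x %d reactions), rank %d\n",
              nrow(x$mat), ncol(x$mat), x$rank))
  print(x$mat)
  invisible(x)
}

# reactant coefficient matrix alpha (n x m), used for mass-action influence
reactant_matrix <- function(net) {
  n <- length(net$species)
  m <- length(net$reactions)
  alpha <- matrix(0L, n, m,
                  dimnames = list(net$species,
                                  vapply(net$reactions, `[[`, "", "id")))
  for (j in seq_len(m)) {
    r <- net$reactions[[j]]
    for (sp in names(r$reactants)) alpha[sp, j] <- r$reactants[[sp]]
  }
  alpha
}
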