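#' Influence matrix constructors
#'
#' The influence matrix Z records the sign of the partial derivative of each
#' reaction rate v_j with respect to each species concentration x_i, under
#' the assumption that every rate is strictly monotone in every variable:
#' entry (i,j) is +1 if v_j strictly increases in x_i, -1 if it strictly
#' decreases, and 0 if v_j does not depend on x_i. Every nonzero entry owns
#' a distinct symbolic variable g[i,j] (gamma), so the injectivity
#' polynomial can be expanded without committing to a functional form of
#' the kinetics.
#'
#' @name influence
NULL

new_influence <- function(sign, net) {
  stopifnot(is.matrix(sign),
            nrow(sign) == length(net$species),
            ncol(sign) == length(net$reactions),
            all(sign %in% c(-1L, 0L, 1L)))
  dimnames(sign) <- list(net$species,
                         vapply(net$reactions, `[[`, "", "id"))
  structure(list(sign = sign), class = "influence_matrix")
}

#' @describeIn influence Mass-action influence: rates are monomials in the
#'   reactant concentrations, hence strictly increasing in every reactant
#'   and independent of everything else; z_ij = +1 iff the reactant
#'   coefficient alpha_ij > 0.
#' @param net A \code{reaction_network}.
#' @return An \code{influence_matrix} (list with integer \code{sign} matrix
#'   in \{-1, 0, +1\}).
#' @export
mass_action_influence <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  alpha <- reactant_matrix(net)
  new_influence(matrix(as.integer(alpha > 0L), nrow(alpha), ncol(alpha)), net)
}

#' @describeIn influence Influence from an explicit sign table. \code{table}
#'   is a character matrix with entries in \code{c("+", "-", "0")} and
#'   dimnames naming species (rows) and reaction ids (columns); rows and
#'   columns are matched to the network by name, so any permutation of the
#'   network's order is accepted.
#' @param table Character matrix of signs (see above).
#' @export
influence_from_table <- function(net, table) {
  stopifnot(inherits(net, "reaction_network"))
  rids <- vapply(net$reactions, `[[`, "", "id")
  if (!is.matrix(table)) stop("influence table must be a matrix", call. = FALSE)
  if (nrow(table) != length(net$species) || ncol(table) != length(rids)) {
    stop(sprintf(paste0("influence table dimension mismatch: table is %dx%d, ",
                        "network needs %dx%d (species x reactions)"),
                 nrow(table), ncol(table), length(net$species), length(rids)),
         call. = FALSE)
  }
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop("influence table must have species rownames and reaction colnames",
         call. = FALSE)
  }
  if (!setequal(rownames(table), net$species)) {
    stop("influence table species do not match the network: missing ",
         paste(setdiff(net$species, rownames(table)), collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(colnames(table), rids)) {
    stop("influence table reactions do not match the network: missing ",
         paste(setdiff(rids, colnames(table)), collapse = ", "),
         call. = FALSE)
  }
  table <- table[net$species, rids, drop = FALSE]
  bad <- !(table %in% c("+", "-", "0"))
  if (any(bad)) {
    stop("illegal influence table entries (expected '+', '-' or '0'): ",
         paste(unique(table[bad]), collapse = " "), call. = FALSE)
  }
  sign <- matrix(0L, nrow(table), ncol(table))
  sign[table == "+"] <- 1L
  sign[table == "-"] <- -1L
  new_influence(sign, net)
}

#' Read an influence sign table from a TSV file
#'
#' The file's first column holds species names, the header row holds
#' reaction ids, and cells are \code{+}, \code{-} or \code{0}. Rows and
#' columns are matched to the network by name. Lines starting with
#' \code{"#"} are comments.
#'
#' @param path Path to the TSV file.
#' @param net The \code{reaction_network} the table refers to.
#' @return An \code{influence_matrix}.
#' @export
read_influence <- function(path, net) {
  if (!file.exists(path)) {
    stop("influence table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE)
  influence_from_table(net, as.matrix(df))
}

#' @export
print.influence_matrix <- function(x, ...) {
  nz <- which(x$sign != 0, arr.ind = TRUE)
  cat(sprintf("Influence matrix (%d species x %d reactions), %d nonzero entries\n",
              nrow(x$sign), ncol(x$sign), nrow(nz)))
  disp <- matrix(".", nrow(x$sign), ncol(x$sign), dimnames = dimnames(x$sign))
  disp[x$sign > 0] <- "+"
  disp[x$sign < 0] <- "-"
  print(disp, quote = FALSE)
  invisible(x)
}

# gamma identifiers of the nonzero entries, as a 2-column matrix of
# (species index, reaction index), in column-major order
influence_gammas <- function(Z) {
  idx <- which(Z$sign != 0, arr.ind = TRUE)
  colnames(idx) <- c("species", "reaction")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
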