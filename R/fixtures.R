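#' Worked-example fixtures
#'
#' Classical reaction networks used to validate the loop-finding procedure,
#' shipped as plain-text reaction lists (and influence sign tables where
#' the kinetics are not mass-action) under \code{inst/extdata}. Each fixture
#' bundles the parsed network, its influence matrix and a block of
#' documented expected outputs that the test suite asserts.
#'
#' Available fixtures:
#' \describe{
#'   \item{mitosis_z1}{Cdk1-cyclin B1 translocation/phosphorylation toy
#'     model with self-activating phosphorylation (influence table Z1);
#'     multi-stationary for some kinetics.}
#'   \item{mitosis_z2}{Same network, phosphorylation rate independent of
#'     the phosphorylated form (Z2); injective.}
#'   \item{ubiquitination}{Ring1B/Bmi1 histone ubiquitination, 10 species,
#'     15 reactions, hand-derived influence signs from the published
#'     rates.}
#'   \item{phospho_two_site}{Two-site distributive phosphorylation cycle,
#'     mass-action.}
#'   \item{cascade_2layer}{Two-layer cascade with P1 -> E feedback,
#'     mass-action.}
#'   \item{apoptosis}{Caspase activation model, mass-action.}
#'   \item{michaelis_menten}{Bare Michaelis-Menten mechanism; injective.}
#' }
#'
#' @param name Fixture name (see above).
#' @return An object of class \code{crn_fixture}: list with \code{name},
#'   \code{network}, \code{influence}, \code{files} (paths of the shipped
#'   text files) and \code{expected}.
#' @seealso [fixture_names()], [find_relevant_loops()]
#' @export
get_fixture <- function(name) {
  if (!name %in% fixture_names()) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "), call. = FALSE)
  }
  ext <- function(f) {
    p <- system.file("extdata", f, package = "dsrloops")
    if (p == "") stop("fixture file missing from installation: ", f,
                      call. = FALSE)
    p
  }
  spec <- switch(name,
    mitosis_z1 = list(rxn = "mitosis.rxn", tsv = "mitosis_z1.tsv",
      expected = list(n_species = 3, n_reactions = 4, s = 2,
                      verdict = "INCONCLUSIVE", n_terms = 5,
                      n_wrong_terms = 2, n_wrong_nuclei = 2,
                      n_circuits = 7, n_positive_loops = 3,
                      n_relevant_loops = 1, multistationary = TRUE)),
    mitosis_z2 = list(rxn = "mitosis.rxn", tsv = "mitosis_z2.tsv",
      expected = list(n_species = 3, n_reactions = 4, s = 2,
                      verdict = "INJECTIVE", n_terms = 3,
                      n_wrong_terms = 0, n_relevant_loops = 0,
                      multistationary = FALSE)),
    ubiquitination = list(rxn = "ubiquitination.rxn", tsv = "ubiquitination.tsv",
      expected = list(n_species = 10, n_reactions = 15,
                      verdict = "INCONCLUSIVE", n_relevant_loops = 2,
                      multistationary = TRUE)),
    phospho_two_site = list(rxn = "phospho_two_site.rxn", tsv = NULL,
      mass_tsv = "phospho_two_site.tsv",
      expected = list(n_species = 10, n_reactions = 12,
                      verdict = "INCONCLUSIVE", n_relevant_loops = 2,
                      multistationary = TRUE)),
    cascade_2layer = list(rxn = "cascade_2layer.rxn", tsv = NULL,
      mass_tsv = "cascade_2layer.tsv",
      expected = list(n_species = 11, n_reactions = 13,
                      verdict = "INCONCLUSIVE", n_relevant_loops = 3,
                      multistationary = TRUE)),
    apoptosis = list(rxn = "apoptosis.rxn", tsv = NULL,
      mass_tsv = "apoptosis.tsv",
      expected = list(n_species = 6, n_reactions = 14,
                      verdict = "INCONCLUSIVE", n_relevant_loops = 2,
                      multistationary = TRUE)),
    michaelis_menten = list(rxn = "michaelis_menten.rxn", tsv = NULL,
      mass_tsv = "michaelis_menten.tsv",
      expected = list(n_species = 4, n_reactions = 3,
                      verdict = "INJECTIVE", n_relevant_loops = 0,
                      multistationary = FALSE))
  )
  net <- read_network(ext(spec$rxn))
  files <- list(rxn = ext(spec$rxn))
  if (is.null(spec$tsv)) {
    # mass-action kinetics; the equivalent sign table is still shipped as a
    # TSV (exercised by the parser tests)
    Z <- mass_action_influence(net)
    files$tsv <- ext(spec$mass_tsv)
  } else {
    files$tsv <- ext(spec$tsv)
    Z <- read_influence(files$tsv, net)
  }
  structure(list(name = name, network = net, influence = Z,
                 files = files, expected = spec$expected),
            class = "crn_fixture")
}

#' @describeIn get_fixture Names of all shipped fixtures.
#' @export
fixture_names <- function() {
  c("mitosis_z1", "mitosis_z2", "ubiquitination", "phospho_two_site",
    "cascade_2layer", "apoptosis", "michaelis_menten")
}

#' @export
print.crn_fixture <- function(x, ...) {
  cat("Fixture:", x$name, "\n")
  print(x$network)
  invisible(x)
}

#' Seeded random small network for property tests
#'
#' Generates a reproducible reaction network with stoichiometric
#' coefficients in \{0, 1, 2\}, at least one reaction with a nonzero net
#' column, and a random influence sign table whose support is a superset of
#' the reactant support (reactant influences may be negative to exercise
#' signed kinetics; occasional non-reactant influences model product
#' feedback). Sizes are kept small so the brute-force oracles (permutation
#' determinant, global nucleus expansion) stay tractable.
#'
#' The caller's RNG state is saved and restored, so generation is a pure
#' function of \code{seed}.
#'
#' @param seed Integer seed.
#' @param n_max Maximum species count (must be <= 6 for oracle
#'   tractability).
#' @param m_max Maximum reaction count.
#' @return List with \code{network} (\code{reaction_network}) and
#'   \code{influence} (\code{influence_matrix}).
#' @export
random_network <- function(seed, n_max = 5, m_max = 8) {
  stopifnot(n_max >= 2, n_max <= 6, m_max >= 2)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  n <- sample(2:n_max, 1)
  m <- sample(2:m_max, 1)
  species <- paste0("X", seq_len(n))
  repeat {
    alpha <- matrix(sample(0:2, n * m, replace = TRUE,
                           prob = c(0.65, 0.3, 0.05)), n, m)
    beta <- matrix(sample(0:2, n * m, replace = TRUE,
                          prob = c(0.65, 0.3, 0.05)), n, m)
    ok_rows <- colSums(alpha) + colSums(beta) > 0     # no empty reactions
    some_net <- any(beta - alpha != 0)                # A not identically zero
    if (all(ok_rows) && some_net) break
  }
  fmt_side <- function(v) {
    nz <- which(v > 0)
    if (!length(nz)) return("0")
    paste(ifelse(v[nz] == 1, species[nz], paste(v[nz], species[nz])),
          collapse = " + ")
  }
  lines <- vapply(seq_len(m), function(j) {
    sprintf("r%d: %s -> %s", j, fmt_side(alpha[, j]), fmt_side(beta[, j]))
  }, character(1))
  net <- parse_network(lines)
  # species that appear in no reaction drop out during parsing, so build
  # the sign table over the parsed species list
  tab <- matrix("0", length(net$species), m,
                dimnames = list(net$species,
                                vapply(net$reactions, `[[`, "", "id")))
  for (i in seq_along(net$species)) {
    for (j in seq_len(m)) {
      if (alpha[match(net$species[i], species), j] > 0) {
        tab[i, j] <- if (stats::runif(1) < 0.85) "+" else "-"
      } else if (stats::runif(1) < 0.1) {
        tab[i, j] <- if (stats::runif(1) < 0.5) "+" else "-"
      }
    }
  }
  list(network = net, influence = influence_from_table(net, tab))
}
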