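test_that("the DSR-graph mirrors the nonzero supports of Z and A", {
  fx <- get_fixture("mitosis_z1")
  A <- stoichiometric_matrix(fx$network)
  G <- build_dsr_graph(A, fx$influence)
  expect_equal(G$n + G$m, 7)
  expect_equal(sum(G$z != 0), 5)
  expect_equal(sum(G$a != 0), 8)

  G2 <- build_dsr_graph(A, get_fixture("mitosis_z2")$influence)
  expect_equal(sum(G2$z != 0), 4)      # same graph minus the Xnuc_p -> r3 edge
  expect_identical(G$a, G2$a)

  zero_tab <- matrix("0", 3, 4,
                     dimnames = list(fx$network$species, colnames(A$mat)))
  G0 <- build_dsr_graph(A, influence_from_table(fx$network, zero_tab))
  expect_equal(sum(G0$z != 0), 0)
  expect_length(enumerate_circuits(G0), 0)

  expect_error(build_dsr_graph(A, get_fixture("apoptosis")$influence),
               "dimension mismatch")
})

test_that("the mitosis DSR-graph has 7 elementary circuits, 3 of them positive", {
  rep <- fixture_report("mitosis_z1")
  cc <- rep$all_circuits
  expect_length(cc, 7)
  expect_length(rep$all_positive_loops, 3)
  # the self-activation circuit Xnuc_p -> r3 -> Xnuc_p is positive
  G <- rep$graph
  self <- Filter(function(c) length(c$nodes) == 2 &&
                   setequal(dsrloops:::dsr_node_name(G, c$nodes),
                            c("Xnuc_p", "r3")), cc)
  expect_length(self, 1)
  expect_equal(self[[1]]$sign, 1)
  # canonical rotation starts at the reaction node
  expect_true(all(vapply(cc, function(c) c$nodes[1] <= G$m, TRUE)))
})

test_that("nuclei realizing a term are perfect-matching completions of its edges", {
  rep <- fixture_report("mitosis_z1")
  G <- rep$graph
  # gamma_{2,2} gamma_{3,3}: only r2 -> Xnuc, r3 -> Xnuc_p closes a 4-nucleus
  nuc <- nuclei_for_term(G, "2.2|3.3")
  expect_length(nuc, 1)
  expect_length(nuc[[1]]$circuits, 2)
  expect_true(all(vapply(nuc[[1]]$circuits, `[[`, 0L, "species_count") == 1L))
  expect_equal(nucleus_sign(nuc[[1]], s = 2), -1)     # (-1)^(s+1), kept

  # both wrong-sign terms together give the two published 4-nuclei, each
  # pairing the positive self-circuit with one negative self-circuit
  kept <- unlist(rep$wrong_sign_nuclei, recursive = FALSE)
  expect_length(kept, 2)
  for (D in kept) {
    signs <- vapply(D$circuits, `[[`, 0, "sign")
    expect_setequal(signs, c(1, -1))
    expect_length(D$nodes, 4)
  }

  # a catalyst-only column cannot be matched back: no completing nucleus
  net <- parse_network(c("r1: A -> A + B", "r2: B -> A"))
  A2 <- stoichiometric_matrix(net)
  G2 <- build_dsr_graph(A2, mass_action_influence(net))
  expect_length(nuclei_for_term(G2, rbind(c(1L, 1L))), 0)
  expect_error(nuclei_for_term(G2, rbind(c(2L, 1L))), "not an edge")
})

test_that("nucleus signs follow the parity law", {
  # single positive self-circuit as a 2-nucleus (s = 1): sign +1 = (-1)^(s+1)
  net <- parse_network("r1: A -> 2 A")
  G <- build_dsr_graph(stoichiometric_matrix(net), mass_action_influence(net))
  nuc <- nuclei_for_term(G, rbind(c(1L, 1L)))
  expect_length(nuc, 1)
  expect_equal(nucleus_sign(nuc[[1]], s = 1), 1)

  # all-negative nuclei always carry (-1)^s; positive-free wrong sign is
  # impossible (checked across every nucleus of every term of random nets)
  for (seed in 1:20) {
    rn <- random_network(seed)
    A <- stoichiometric_matrix(rn$network)
    G <- build_dsr_graph(A, rn$influence)
    p <- injectivity_polynomial(A, rn$influence)
    s <- A$rank
    for (key in poly_terms(p)$monomial) {
      for (D in nuclei_for_term(G, key)) {
        expect_length(D$nodes, 2 * s)
        # nucleus monomial (its species->reaction edges) equals the term
        fs <- do.call(rbind, lapply(D$circuits, `[[`, "factors"))
        expect_identical(dsrloops:::mono_key(fs[, 1], fs[, 2]), key)
        # every node has in- and out-degree 1: each node appears in exactly
        # one circuit, and circuits are node-disjoint simple cycles
        expect_identical(D$nodes, sort(unique(D$nodes)))
        if (all(vapply(D$circuits, `[[`, 0, "sign") < 0)) {
          expect_equal(nucleus_sign(D), (-1)^s)
        }
      }
    }
  }
})

test_that("the global nucleus expansion reproduces the determinant polynomial", {
  for (nm in c("mitosis_z1", "mitosis_z2", "michaelis_menten", "apoptosis")) {
    fx <- get_fixture(nm)
    A <- stoichiometric_matrix(fx$network)
    G <- build_dsr_graph(A, fx$influence)
    expect_identical(
      format_polynomial(nucleus_expansion(G, A$rank)),
      format_polynomial(injectivity_polynomial(A, fx$influence)),
      label = nm)
  }
})

test_that("motif signatures are canonical under even rotation", {
  rep <- fixture_report("mitosis_z1")
  red <- Filter(function(c) length(c$nodes) == 2 && c$sign > 0,
                rep$all_positive_loops)[[1]]
  expect_equal(motif_signature(red), "(+,+)")

  # a 4-species mixed-sign loop: rotating the start reaction node must not
  # change the signature
  repp <- fixture_report("phospho_two_site")
  left <- Filter(function(c) c$species_count == 4, repp$relevant_loops)[[1]]
  sig <- motif_signature(left)
  expect_equal(sig, "(+,+,+,+,-,+,-,+)")
  for (off in c(2, 4, 6)) {
    rot <- left
    q <- length(left$signs)
    rot$signs <- left$signs[((seq_len(q) - 1 + off) %% q) + 1]
    expect_equal(motif_signature(rot), sig)
  }

  # an all-positive cycle canonicalizes to itself
  expect_equal(motif_signature(Filter(function(c) c$species_count == 2,
                                      repp$relevant_loops)[[1]]),
               "(+,+,+,+)")
})

test_that("relevant loops are positive circuits of wrong-sign nuclei only", {
  for (nm in fixture_names()) {
    rep <- fixture_report(nm)
    all_keys <- vapply(rep$all_positive_loops, `[[`, "", "key")
    rel_keys <- vapply(rep$relevant_loops, `[[`, "", "key")
    expect_true(all(rel_keys %in% all_keys), label = nm)
    if (rep$verdict != "INCONCLUSIVE") {
      expect_length(rep$relevant_loops, 0)
    }
    # every wrong-sign nucleus contains at least one positive circuit
    for (kept in rep$wrong_sign_nuclei) {
      for (D in kept) {
        expect_true(any(vapply(D$circuits, `[[`, 0, "sign") > 0), label = nm)
      }
    }
  }
})
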