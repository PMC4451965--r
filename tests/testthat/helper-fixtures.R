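# Shared report cache (find_relevant_loops is deterministic; computing each
# fixture once keeps the suite fast) and frozen expected values.

fixture_report <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      fx <- get_fixture(name)
      cache[[name]] <<- find_relevant_loops(fx$network, fx$influence)
    }
    cache[[name]]
  }
})

# published 5-term polynomial for the mitosis network with influence Z1
# (canonical ordering of this package) and its 3-term restriction under Z2
GOLDEN_P_Z1 <- "+g[1,1]*g[2,3] -g[1,1]*g[3,3] +g[1,1]*g[3,4] -g[2,2]*g[3,3] +g[2,2]*g[3,4]"
GOLDEN_P_Z2 <- "+g[1,1]*g[2,3] +g[1,1]*g[3,4] +g[2,2]*g[3,4]"

MULTISTATIONARY_FIXTURES <- c("mitosis_z1", "ubiquitination",
                              "phospho_two_site", "cascade_2layer",
                              "apoptosis")

# one-edge-per-loop breaking choices: all combinations of one influence
# factor (species -> reaction edge) from each relevant loop
loop_break_choices <- function(rep) {
  per_loop <- lapply(rep$relevant_loops, function(c) {
    lapply(seq_len(nrow(c$factors)), function(k) c$factors[k, , drop = TRUE])
  })
  combos <- list(list())
  for (choices in per_loop) {
    combos <- do.call(c, lapply(combos, function(cm) {
      lapply(choices, function(ch) c(cm, list(ch)))
    }))
  }
  combos
}
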