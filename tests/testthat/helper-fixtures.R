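# Shared fixture builders.  All fixtures are generated in code; no data
# files.

# The fixture family used by the theorem and oracle tests: deterministic
# per seed, <= 12 reactions, always a positive maximal growth.
random_fixture <- function(seed) {
  make_fixture(fixture_spec(
    n_metabolites = 6 + seed %% 3,
    n_reactions = 9 + seed %% 4,
    reversible_fraction = c(0, 0.25, 0.5)[1 + seed %% 3],
    n_parallel_paths = 1 + seed %% 2,
    include_dem = seed %% 2 == 1,
    include_dead = seed %% 3 == 0,
    seed = seed))
}

# Two parallel single-step paths with capacities 3 and 4 into biomass;
# mu_max = 7 and every backbone weight is 1.
parallel_paths_34 <- function() {
  make_fixture(fixture_spec(
    n_metabolites = 3, n_reactions = 5, n_parallel_paths = 2,
    reversible_fraction = 0, path_capacities = c(3, 4), seed = 3))
}

# growth context without re-solving FBA (for property loops over gamma)
ctx_at <- function(mu, gamma) {
  structure(list(mu_max = mu, gamma = gamma, flux = NULL),
            class = "growth_context")
}

expect_same_report <- function(a, b, fields = c(
    "chokepoints", "dead_end_metabolites", "essential", "blocked")) {
  for (f in fields) expect_identical(a[[f]], b[[f]])
  expect_identical(a$partition$dead, b$partition$dead)
  expect_identical(a$partition$reversible, b$partition$reversible)
  expect_identical(a$partition$non_reversible, b$partition$non_reversible)
}

# evaluate a cli_main() call, discarding its printed output
capture_code <- function(expr) {
  invisible(utils::capture.output(code <- expr))
  code
}

# minimal SBML documents written in code for reader tests
write_l3_fbc_sbml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1" fbc:required="false">',
    ' <model id="toy" fbc:strict="true">',
    '  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '  <listOfSpecies>',
    '   <species id="A" compartment="c" boundaryCondition="false" constant="false"/>',
    '   <species id="B_ext" compartment="c" boundaryCondition="true" constant="false"/>',
    '  </listOfSpecies>',
    '  <listOfParameters>',
    '   <parameter id="lb1" value="-1000" constant="true"/>',
    '   <parameter id="ub1" value="1000" constant="true"/>',
    '  </listOfParameters>',
    '  <listOfReactions>',
    '   <reaction id="r1" reversible="true" fbc:lowerFluxBound="lb1" fbc:upperFluxBound="ub1">',
    '    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="B_ext" stoichiometry="2" constant="true"/></listOfProducts>',
    '   </reaction>',
    '   <reaction id="rg" reversible="false">',
    '    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '   </reaction>',
    '  </listOfReactions>',
    '  <fbc:listOfObjectives fbc:activeObjective="obj">',
    '   <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '    <fbc:listOfFluxObjectives>',
    '     <fbc:fluxObjective fbc:reaction="rg" fbc:coefficient="1"/>',
    '    </fbc:listOfFluxObjectives>',
    '   </fbc:objective>',
    '  </fbc:listOfObjectives>',
    ' </model>',
    '</sbml>'), path)
  path
}

write_l2_kinetic_sbml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    ' <model id="toy2">',
    '  <listOfSpecies>',
    '   <species id="A" boundaryCondition="false"/>',
    '  </listOfSpecies>',
    '  <listOfReactions>',
    '   <reaction id="r1" reversible="false">',
    '    <listOfProducts><speciesReference species="A"/></listOfProducts>',
    '    <kineticLaw>',
    '     <listOfParameters>',
    '      <parameter id="LOWER_BOUND" value="0"/>',
    '      <parameter id="UPPER_BOUND" value="10"/>',
    '     </listOfParameters>',
    '    </kineticLaw>',
    '   </reaction>',
    '   <reaction id="r2" reversible="true">',
    '    <listOfReactants><speciesReference species="A"/></listOfReactants>',
    '   </reaction>',
    '  </listOfReactions>',
    ' </model>',
    '</sbml>'), path)
  path
}
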