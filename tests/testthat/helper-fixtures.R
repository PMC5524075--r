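# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdir().

# linear chain: EX_A (-> A), R1 (A -> B), EX_B (B ->)
chain3_model <- function(lb = 0, ub = 10, gpr_r1 = "gA") {
  metabolic_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
               stringsAsFactors = FALSE),
    list(list(id = "EX_A", stoich = c(A = 1), lower_bound = lb,
              upper_bound = ub, is_exchange = TRUE),
         list(id = "R1", stoich = c(A = -1, B = 1), lower_bound = lb,
              upper_bound = ub, gpr = gpr_r1),
         list(id = "EX_B", stoich = c(B = -1), lower_bound = lb,
              upper_bound = ub, is_exchange = TRUE))
  )
}

# chain with a dead-end side branch off A (no outlet for D)
deadend_model <- function() {
  metabolic_model(
    data.frame(id = c("A", "B", "D"), name = c("A", "B", "D"),
               compartment = "c", stringsAsFactors = FALSE),
    list(list(id = "EX_A", stoich = c(A = 1), lower_bound = 0,
              upper_bound = 10, is_exchange = TRUE),
         list(id = "R1", stoich = c(A = -1, B = 1), lower_bound = 0,
              upper_bound = 10),
         list(id = "RD", stoich = c(A = -1, D = 1), lower_bound = 0,
              upper_bound = 10),
         list(id = "EX_B", stoich = c(B = -1), lower_bound = 0,
              upper_bound = 10, is_exchange = TRUE))
  )
}

all_states <- function(model, state) {
  list(condition = "test",
       state_of = setNames(rep(state, length(model$reactions)),
                           names(model$reactions)))
}

# reproducible random trilevel states over all reactions
random_states <- function(model, seed) {
  rids <- names(model$reactions)
  fluxcond:::with_seed(seed, {
    list(condition = "rand",
         state_of = setNames(
           sample(c("HIGH", "MODERATE", "LOW"), length(rids),
                  replace = TRUE, prob = c(0.3, 0.4, 0.3)),
           rids))
  })
}

write_model_string <- function(model) {
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  paste(readLines(path), collapse = "\n")
}

minimal_sbml <- function() {
  path <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="met A" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="B" name="met B" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_cap" value="12.5" constant="true"/>
      <parameter id="lb_rev" value="-12.5" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_gA" fbc:label="gA"/>
      <fbc:geneProduct fbc:id="G_gB" fbc:label="gB"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_cap">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="ub_cap">
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_gA"/>
            <fbc:geneProductRef fbc:geneProduct="G_gB"/>
          </fbc:and>
        </fbc:geneProductAssociation>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_B" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_cap">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}
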