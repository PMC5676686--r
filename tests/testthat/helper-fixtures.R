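# Small fixtures built in code.

# Two reactions, three metabolites, two genes:
#   r1: a[c] -> b[c]        (GENE1)
#   r2: b[c] + b[m] -> ...  (GENE1, GENE2)   [b duplicated across compartments]
tiny_model <- function() {
  metabolic_model(
    genes = c("Gene1", "GENE2"),
    reactions = list(
      r1 = list(genes = "gene1",
                stoich = c("a[c]" = -1, "b[c]" = 1)),
      r2 = list(genes = c("GENE1", "Gene2"),
                stoich = c("b[c]" = -1, "b[m]" = 1))),
    metabolites = data.frame(
      id = c("a[c]", "b[c]", "b[m]"),
      base_name = c("a", "b", "b"),
      compartment = c("c", "c", "m"),
      formula = c("C16H32O2", "H2O", "H2O"),
      stringsAsFactors = FALSE))
}

# Minimal SBML Level 3 + FBC document exercising gene products, boolean
# gene associations, compartments and chemical formulas.
sbml_fixture <- function(dangling_species = FALSE) {
  bad <- if (dangling_species) {
    '<speciesReference species="M_ghost_c" stoichiometry="1" constant="true"/>'
  } else ""
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="false">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="m" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_palmitate_c" name="palmitate" compartment="c"
               fbc:chemicalFormula="C16H32O2" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="M_h2o_c" name="H2O" compartment="c"
               fbc:chemicalFormula="H2O" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="M_pcpool_m" name="PC pool" compartment="m"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_acsl6" fbc:label="Acsl6"/>
      <fbc:geneProduct fbc:id="G_cyp2c55" fbc:label="Cyp2c55"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_syn" reversible="false" fast="false">
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_acsl6"/>
            <fbc:geneProductRef fbc:geneProduct="G_cyp2c55"/>
          </fbc:or>
        </fbc:geneProductAssociation>
        <listOfReactants>
          <speciesReference species="M_palmitate_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_pcpool_m" stoichiometry="1" constant="true"/>
          <speciesReference species="M_h2o_c" stoichiometry="1" constant="true"/>
          %s
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', bad)
}

write_sbml_fixture <- function(..., dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.xml")
  writeLines(sbml_fixture(...), path)
  path
}

# Toy lipid table: 4 species, 2 classes, 5 + 5 samples; species PC 34:1
# shifted far apart between groups (the smallest exact-KS p with 5 v 5 is
# 2/choose(10,5) ~ 0.0079, which survives BH over four species).
toy_lipid_table <- function() {
  m <- rbind(
    "PC 34:1" = c(100, 110, 105, 98, 112, 1000, 1100, 1050, 980, 1120),
    "PC 36:2" = c(50, 55, 52, 54, 51, 51, 54, 53, 52, 55),
    "PI 38:4" = c(200, 210, 205, 202, 212, 208, 203, 207, 201, 211),
    "PI 34:2" = c(10, NA, 12, 11, 13, 11, 13, NA, 12, 10))
  colnames(m) <- c(paste0("A", 1:5), paste0("B", 1:5))
  lipid_table(m, c("PC", "PC", "PI", "PI"),
              setNames(rep(c("A", "B"), each = 5), colnames(m)))
}
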