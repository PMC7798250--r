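# shared fixtures: small models and independent oracles

# reversible two-compartment exchange S -> P in a given scaling mode
two_cell_model <- function(mode, V1, V2, A = NULL, kf, kr, c0 = 1) {
  m <- new_model()
  if (mode == "single") {
    m <- add_compartment(m, "pool", V1 + V2)
    m <- add_species(m, "S", "pool", conc = c0)
    m <- add_species(m, "P", "pool", conc = 0)
    return(add_reaction(m, "tr", c(S = 1), c(P = 1), kf = kf, kr = kr,
                        mode = "single"))
  }
  m <- add_compartment(m, "c1", V1)
  m <- add_compartment(m, "c2", V2)
  m <- add_species(m, "S", "c1", conc = c0)
  m <- add_species(m, "P", "c2", conc = 0)
  add_reaction(m, "tr", c(S = 1), c(P = 1), kf = kf, kr = kr,
               mode = mode, area = if (mode == "area") A else NULL)
}

# amount dynamics of the linear exchange: n' = M n with
#   M = [[-a, b], [a, -b]],  a = loss rate of S, b = gain from P
exchange_rate_matrix <- function(mode, V1, V2, A, kf, kr) {
  if (mode == "area") {
    a <- A * kf / V1
    b <- A * kr / V2
  } else {
    a <- kf
    b <- kr
  }
  matrix(c(-a, a, b, -b), 2, 2)
}

# independent matrix-exponential oracle for the 2-state linear system
expm_solution <- function(M, n0, times) {
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(M * t) %*% n0), numeric(2)))
}

# minimal hand-written SBML with an irreversible volume-scaled law
#   V_nuc * k * [S],   sizes cyt = 10, nuc = 2
irreversible_toy_sbml <- function(k = 0.05) {
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy">
    <listOfCompartments>
      <compartment id="cyt" spatialDimensions="3" size="10" constant="true"/>
      <compartment id="nuc" spatialDimensions="3" size="2" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="cyt" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="P" compartment="nuc" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k" value="%s" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="uptake" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply> <times/> <ci> nuc </ci> <ci> k </ci> <ci> S </ci> </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', formatC(k, format = "g"))
}

# two-volume (non-factorable) law: V1*kf*[S] - V2*kr*[P]
two_volume_law_sbml <- function() {
  '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy2v">
    <listOfCompartments>
      <compartment id="c1" spatialDimensions="3" size="5" constant="true"/>
      <compartment id="c2" spatialDimensions="3" size="3" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="c1" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="P" compartment="c2" initialConcentration="0" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="kf" value="0.1" constant="true"/>
      <parameter id="kr" value="0.05" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="transport" reversible="true">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="P" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply> <minus/>
              <apply> <times/> <ci> c1 </ci> <ci> kf </ci> <ci> S </ci> </apply>
              <apply> <times/> <ci> c2 </ci> <ci> kr </ci> <ci> P </ci> </apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}

sbml_with_event <- function() {
  '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="ev">
    <listOfCompartments>
      <compartment id="c" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="c" initialConcentration="1" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply> <times/> <cn> 0.1 </cn> <ci> S </ci> </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
    <listOfEvents>
      <event id="e1">
        <trigger initialValue="true" persistent="true">
          <math xmlns="http://www.w3.org/1998/Math/MathML"><cn> 1 </cn></math>
        </trigger>
      </event>
    </listOfEvents>
  </model>
</sbml>'
}
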