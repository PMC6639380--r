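<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="toy_chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_A" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_M1" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_M2" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_Z" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="bnd_lb_1" value="0" constant="true"/>
      <parameter id="bnd_ub_1" value="10" constant="true"/>
      <parameter id="bnd_lb_2" value="0" constant="true"/>
      <parameter id="bnd_ub_2" value="INF" constant="true"/>
      <parameter id="bnd_lb_3" value="0" constant="true"/>
      <parameter id="bnd_ub_3" value="INF" constant="true"/>
      <parameter id="bnd_lb_4" value="0" constant="true"/>
      <parameter id="bnd_ub_4" value="INF" constant="true"/>
      <parameter id="bnd_lb_5" value="0" constant="true"/>
      <parameter id="bnd_ub_5" value="INF" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_EX_src" reversible="false" fast="false" fbc:lowerFluxBound="bnd_lb_1" fbc:upperFluxBound="bnd_ub_1">
        <listOfProducts>
          <speciesReference species="M_A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_R1" reversible="false" fast="false" fbc:lowerFluxBound="bnd_lb_2" fbc:upperFluxBound="bnd_ub_2">
        <listOfReactants>
          <speciesReference species="M_A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_M1" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_R2" reversible="false" fast="false" fbc:lowerFluxBound="bnd_lb_3" fbc:upperFluxBound="bnd_ub_3">
        <listOfReactants>
          <speciesReference species="M_M1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_M2" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_R3" reversible="false" fast="false" fbc:lowerFluxBound="bnd_lb_4" fbc:upperFluxBound="bnd_ub_4">
        <listOfReactants>
          <speciesReference species="M_M2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_Z" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_BIO" reversible="false" fast="false" fbc:lowerFluxBound="bnd_lb_5" fbc:upperFluxBound="bnd_ub_5">
        <listOfReactants>
          <speciesReference species="M_Z" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_BIO" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
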