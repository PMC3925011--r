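<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_chain" name="three-metabolite chain">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" name="substrate" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false" aioflux:carbon="6" xmlns:aioflux="https://aioflux/ns"/>
      <species id="B" name="product" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false" aioflux:carbon="6" xmlns:aioflux="https://aioflux/ns"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" name="A uptake" reversible="false" fast="false">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" name="A to B" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_B" name="B secretion" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
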