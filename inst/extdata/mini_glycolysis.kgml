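<?xml version="1.0" encoding="UTF-8"?>
<pathway name="path:syn00010" org="syn" number="00010" title="synthetic glycolysis sketch">
  <entry id="1" name="cpd:C00031" type="compound">
    <graphics name="C00031" x="100" y="100" type="circle"/>
  </entry>
  <entry id="2" name="cpd:C00668" type="compound">
    <graphics name="C00668" x="100" y="200" type="circle"/>
  </entry>
  <entry id="3" name="cpd:C05345" type="compound">
    <graphics name="C05345" x="100" y="300" type="circle"/>
  </entry>
  <entry id="4" name="cpd:C00031" type="compound">
    <graphics name="C00031 alias" x="300" y="100" type="circle"/>
  </entry>
  <entry id="5" name="syn:HK1" type="gene" reaction="rn:R01786">
    <graphics name="HK1" x="200" y="150" type="rectangle"/>
  </entry>
  <entry id="6" name="ec:5.3.1.9" type="enzyme" reaction="rn:R03321">
    <graphics name="GPI" x="200" y="250" type="rectangle"/>
  </entry>
  <entry id="7" name="path:syn00020" type="map">
    <graphics name="TCA cycle" x="400" y="400" type="roundrectangle"/>
  </entry>
  <entry id="8" name="cpd:C00267" type="compound">
    <graphics name="C00267" x="300" y="200" type="circle"/>
  </entry>
  <reaction id="10" name="rn:R01786" type="irreversible">
    <substrate id="1" name="cpd:C00031"/>
    <product id="2" name="cpd:C00668"/>
  </reaction>
  <reaction id="11" name="rn:R03321" type="reversible">
    <substrate id="2" name="cpd:C00668"/>
    <product id="3" name="cpd:C05345"/>
  </reaction>
  <reaction id="12" name="rn:R01786dup" type="irreversible">
    <substrate id="4" name="cpd:C00031"/>
    <product id="2" name="cpd:C00668"/>
  </reaction>
  <reaction id="13" name="rn:R00771" type="reversible">
    <substrate id="8" name="cpd:C00267"/>
    <product id="1" name="cpd:C00031"/>
  </reaction>
  <relation entry1="5" entry2="1" type="ECrel"/>
  <relation entry1="5" entry2="6" type="ECrel"/>
</pathway>
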