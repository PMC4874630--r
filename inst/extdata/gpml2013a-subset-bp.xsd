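<?xml version="1.0" encoding="UTF-8"?>
<!-- Companion to gpml2013a-subset.xsd: the minimal BioPAX publication
     cross-reference elements the writer emits. -->
<xsd:schema xmlns:xsd="http://www.w3.org/2001/XMLSchema"
            xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"
            xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
            targetNamespace="http://www.biopax.org/release/biopax-level3.owl#"
            elementFormDefault="qualified">
  <xsd:import namespace="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
              schemaLocation="gpml2013a-subset-rdf.xsd"/>
  <xsd:element name="ID" type="xsd:string"/>
  <xsd:element name="Database" type="xsd:string"/>
  <xsd:element name="PublicationXref">
    <xsd:complexType>
      <xsd:sequence>
        <xsd:element ref="bp:ID"/>
        <xsd:element ref="bp:Database"/>
      </xsd:sequence>
      <xsd:attribute ref="rdf:id" use="required"/>
    </xsd:complexType>
  </xsd:element>
</xsd:schema>
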