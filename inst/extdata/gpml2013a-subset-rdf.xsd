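<?xml version="1.0" encoding="UTF-8"?>
<!-- Companion to gpml2013a-subset.xsd: the single RDF attribute used. -->
<xsd:schema xmlns:xsd="http://www.w3.org/2001/XMLSchema"
            targetNamespace="http://www.w3.org/1999/02/22-rdf-syntax-ns#">
  <xsd:attribute name="id" type="xsd:string"/>
</xsd:schema>
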