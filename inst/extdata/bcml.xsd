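<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:simpleType name="vocabularyName">
    <xs:restriction base="xs:string">
      <xs:enumeration value="organism"/>
      <xs:enumeration value="organism-part"/>
      <xs:enumeration value="cell-type"/>
      <xs:enumeration value="environment"/>
      <xs:enumeration value="experiment-type"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="glyphClass">
    <xs:restriction base="xs:string">
      <xs:enumeration value="macromolecule"/>
      <xs:enumeration value="simple-chemical"/>
      <xs:enumeration value="nucleic-acid-feature"/>
      <xs:enumeration value="complex"/>
      <xs:enumeration value="unspecified-entity"/>
      <xs:enumeration value="source-sink"/>
      <xs:enumeration value="phenotype"/>
      <xs:enumeration value="process"/>
      <xs:enumeration value="association"/>
      <xs:enumeration value="dissociation"/>
      <xs:enumeration value="and-operator"/>
      <xs:enumeration value="or-operator"/>
      <xs:enumeration value="not-operator"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="arcClass">
    <xs:restriction base="xs:string">
      <xs:enumeration value="consumption"/>
      <xs:enumeration value="production"/>
      <xs:enumeration value="catalysis"/>
      <xs:enumeration value="stimulation"/>
      <xs:enumeration value="inhibition"/>
      <xs:enumeration value="necessary-stimulation"/>
      <xs:enumeration value="modulation"/>
      <xs:enumeration value="logic-arc"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="moduleType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="sensing"/>
      <xs:enumeration value="transduction"/>
      <xs:enumeration value="outcome"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="termType">
    <xs:attribute name="vocabulary" type="vocabularyName" use="required"/>
    <xs:attribute name="identifier" type="xs:string" use="required"/>
    <xs:attribute name="label" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="findingType">
    <xs:sequence>
      <xs:element name="context" type="termType" minOccurs="1" maxOccurs="5"/>
      <xs:element name="reference" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="xrefType">
    <xs:attribute name="database" type="xs:string" use="required"/>
    <xs:attribute name="accession" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="glyphType">
    <xs:sequence>
      <xs:element name="xref" type="xrefType" minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="finding" type="findingType" minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="glyph" type="glyphType" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:ID" use="required"/>
    <xs:attribute name="class" type="glyphClass" use="required"/>
    <xs:attribute name="label" type="xs:string"/>
    <xs:attribute name="compartment" type="xs:IDREF"/>
    <xs:attribute name="family" type="xs:boolean"/>
    <xs:attribute name="tags" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="arcType">
    <xs:sequence>
      <xs:element name="finding" type="findingType" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="id" type="xs:ID" use="required"/>
    <xs:attribute name="class" type="arcClass" use="required"/>
    <xs:attribute name="source" type="xs:IDREF" use="required"/>
    <xs:attribute name="target" type="xs:IDREF" use="required"/>
  </xs:complexType>

  <xs:complexType name="moduleTypeDef">
    <xs:sequence>
      <xs:element name="member" minOccurs="1" maxOccurs="unbounded">
        <xs:complexType>
          <xs:attribute name="ref" type="xs:IDREF" use="required"/>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
    <xs:attribute name="id" type="xs:ID" use="required"/>
    <xs:attribute name="type" type="moduleType" use="required"/>
    <xs:attribute name="label" type="xs:string"/>
    <xs:attribute name="entry" type="xs:IDREF"/>
    <xs:attribute name="exit" type="xs:IDREF"/>
  </xs:complexType>

  <xs:element name="pathway">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="organism" type="termType"/>
        <xs:element name="compartment" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="id" type="xs:ID" use="required"/>
            <xs:attribute name="label" type="xs:string"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="glyph" type="glyphType" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="arc" type="arcType" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="module" type="moduleTypeDef" minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="chain" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="upstream" type="xs:IDREF" use="required"/>
            <xs:attribute name="downstream" type="xs:IDREF" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="note" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:simpleContent>
              <xs:extension base="xs:string">
                <xs:attribute name="key" type="xs:string"/>
              </xs:extension>
            </xs:simpleContent>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="id" type="xs:string" use="required"/>
      <xs:attribute name="name" type="xs:string"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
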