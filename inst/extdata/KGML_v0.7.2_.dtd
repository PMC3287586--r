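<!-- KGML (KEGG Markup Language) v0.7.2-compatible document type definition.
     Covers the pathway/entry/graphics/relation/subtype vocabulary emitted
     and consumed by this package. -->

<!ELEMENT pathway (entry*, relation*, reaction*)>
<!ATTLIST pathway
    name    CDATA #REQUIRED
    org     CDATA #REQUIRED
    number  CDATA #IMPLIED
    title   CDATA #IMPLIED
    image   CDATA #IMPLIED
    link    CDATA #IMPLIED>

<!ELEMENT entry (graphics*, component*)>
<!ATTLIST entry
    id       CDATA #REQUIRED
    name     CDATA #REQUIRED
    type     CDATA #REQUIRED
    link     CDATA #IMPLIED
    reaction CDATA #IMPLIED>

<!ELEMENT graphics EMPTY>
<!ATTLIST graphics
    name    CDATA #IMPLIED
    x       CDATA #IMPLIED
    y       CDATA #IMPLIED
    coords  CDATA #IMPLIED
    type    CDATA #IMPLIED
    width   CDATA #IMPLIED
    height  CDATA #IMPLIED
    fgcolor CDATA #IMPLIED
    bgcolor CDATA #IMPLIED>

<!ELEMENT component EMPTY>
<!ATTLIST component
    id CDATA #REQUIRED>

<!ELEMENT relation (subtype*)>
<!ATTLIST relation
    entry1 CDATA #REQUIRED
    entry2 CDATA #REQUIRED
    type   CDATA #REQUIRED>

<!ELEMENT subtype EMPTY>
<!ATTLIST subtype
    name  CDATA #REQUIRED
    value CDATA #REQUIRED>

<!ELEMENT reaction (substrate*, product*)>
<!ATTLIST reaction
    id   CDATA #REQUIRED
    name CDATA #REQUIRED
    type CDATA #REQUIRED>

<!ELEMENT substrate EMPTY>
<!ATTLIST substrate
    id   CDATA #REQUIRED
    name CDATA #REQUIRED>

<!ELEMENT product EMPTY>
<!ATTLIST product
    id   CDATA #REQUIRED
    name CDATA #REQUIRED>
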