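{
  "name": "Abacavir transport synthetic example",
  "organism": "Homo sapiens",
  "sourceVersion": "54",
  "authors": ["A. Curator"],
  "maintainers": [{"name": "R. Editor", "email": "editor@example.org"}],
  "entities": [
    {
      "id": "E1",
      "displayName": "abacavir [extracellular]",
      "class": "small_molecule",
      "geometry": {"centerX": 100, "centerY": 100, "width": 90, "height": 25},
      "xrefs": [
        {"dataSource": "ChEBI", "identifier": "CHEBI:421707"},
        {"dataSource": "Reactome", "identifier": "R-ALL-2161506"}
      ]
    },
    {
      "id": "E2",
      "displayName": "abacavir [cytosol]",
      "class": "small_molecule",
      "geometry": {"centerX": 340, "centerY": 100, "width": 90, "height": 25},
      "xrefs": [
        {"dataSource": "ChEBI", "identifier": "CHEBI:421707"},
        {"dataSource": "Reactome", "identifier": "R-ALL-2161951"}
      ]
    },
    {
      "id": "E3",
      "displayName": "SLC22A2",
      "class": "protein",
      "geometry": {"centerX": 220, "centerY": 40, "width": 80, "height": 25},
      "xrefs": [
        {"dataSource": "Reactome", "identifier": "R-HSA-549286"},
        {"dataSource": "UniProt", "identifier": "O15244"}
      ],
      "literature": ["21428697"]
    }
  ],
  "reactions": [
    {
      "id": "R1",
      "type": "transition",
      "branches": [
        {"role": "input", "entityId": "E1"},
        {"role": "output", "entityId": "E2"},
        {"role": "catalyst", "entityId": "E3"}
      ],
      "backbonePoints": [[160, 100], [280, 100]],
      "xrefs": [{"dataSource": "Reactome", "identifier": "R-HSA-2161538"}]
    }
  ],
  "compartments": [],
  "notes": []
}
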