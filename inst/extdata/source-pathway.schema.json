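{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Reaction-centric source pathway",
  "description": "JSON document format consumed by read_source_pathway(): entities with role-typed reaction branches, complexes/entity sets with components, compartments and notes, in top-left-origin diagram coordinates.",
  "type": "object",
  "required": ["name"],
  "additionalProperties": false,
  "properties": {
    "name": {"type": "string"},
    "organism": {"type": "string"},
    "sourceVersion": {"type": ["string", "number"]},
    "authors": {"type": "array", "items": {"type": "string"}},
    "maintainers": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": {"type": "string"},
          "email": {"type": "string"}
        }
      }
    },
    "xref": {"$ref": "#/definitions/xref"},
    "entities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "displayName", "class", "geometry"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "displayName": {"type": "string"},
          "class": {
            "enum": ["protein", "small_molecule", "rna", "gene",
                     "process_node", "complex", "entity_set", "other"]
          },
          "compartment": {"type": "string"},
          "geometry": {
            "type": "object",
            "required": ["centerX", "centerY", "width", "height"],
            "properties": {
              "centerX": {"type": "number"},
              "centerY": {"type": "number"},
              "width": {"type": "number", "exclusiveMinimum": 0},
              "height": {"type": "number", "exclusiveMinimum": 0}
            }
          },
          "xrefs": {"type": "array", "items": {"$ref": "#/definitions/xref"}},
          "components": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["ref"],
              "properties": {
                "ref": {"type": "string"},
                "stoichiometry": {"type": "integer", "minimum": 1,
                                  "default": 1}
              }
            }
          },
          "literature": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "branches", "backbonePoints"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "type": {
            "enum": ["transition", "binding", "dissociation", "omitted",
                     "uncertain"],
            "default": "transition"
          },
          "branches": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["role", "entityId"],
              "properties": {
                "role": {"enum": ["input", "output", "catalyst",
                                  "activator", "inhibitor"]},
                "entityId": {"type": "string"},
                "stoichiometry": {"type": "integer", "minimum": 1,
                                  "default": 1}
              }
            }
          },
          "backbonePoints": {
            "type": "array",
            "minItems": 2,
            "items": {
              "type": "array",
              "minItems": 2,
              "maxItems": 2,
              "items": {"type": "number"}
            }
          },
          "xrefs": {"type": "array", "items": {"$ref": "#/definitions/xref"}},
          "literature": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "compartments": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "geometry"],
        "properties": {
          "id": {"type": "string"},
          "name": {"type": "string"},
          "geometry": {
            "type": "object",
            "required": ["x", "y", "width", "height"],
            "properties": {
              "x": {"type": "number"},
              "y": {"type": "number"},
              "width": {"type": "number", "exclusiveMinimum": 0},
              "height": {"type": "number", "exclusiveMinimum": 0}
            }
          },
          "membrane": {"type": "boolean", "default": false}
        }
      }
    },
    "notes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["text"],
        "properties": {
          "text": {"type": "string", "minLength": 1},
          "position": {"type": "array", "minItems": 2, "maxItems": 2,
                       "items": {"type": "number"}}
        }
      }
    }
  },
  "definitions": {
    "xref": {
      "type": "object",
      "required": ["dataSource", "identifier"],
      "properties": {
        "dataSource": {"enum": ["UniProt", "ChEBI", "Reactome", "Ensembl",
                                "HMDB", "PubMed", "Other"]},
        "identifier": {"type": "string", "minLength": 1}
      }
    }
  }
}
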