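{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "skimploid run report",
  "type": "object",
  "required": ["trees", "rf_matrix", "topology_labels", "maternal_calls",
               "parental_signatures", "provenance"],
  "properties": {
    "trees": {"type": "object", "r_type": "list",
              "description": "compartment -> Newick string"},
    "rf_matrix": {"type": "array", "r_type": "matrix",
                  "description": "pairwise Robinson-Foulds distances between compartment trees"},
    "topology_labels": {"type": "object", "r_type": "list",
                        "description": "polyploid -> compartment -> cladeI_like | cladeII_like | unresolved"},
    "maternal_calls": {"type": "object", "r_type": "list",
                       "description": "polyploid -> {maternal, ties, compartment}"},
    "satellite_abundance": {"type": ["array", "null"], "r_type": "matrix",
                            "description": "species x consensus percent abundance"},
    "satellite_presence": {"type": ["array", "null"], "r_type": "matrix"},
    "satellite_grouping": {"type": ["array", "null"], "r_type": "data.frame"},
    "parental_signatures": {"type": "object", "r_type": "list"},
    "provenance": {"type": "object", "r_type": "list",
                   "description": "package version, seeds, full parameter set"}
  }
}
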