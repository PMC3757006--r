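{
  "title": "ramanredox run report",
  "description": "Structural contract for report.json written by run_pipeline(); enforced by validate_report().",
  "type": "object",
  "required": ["package", "version", "config_hash", "created", "n_spectra",
               "calibration", "indices", "summaries"],
  "properties": {
    "package": {"type": "string", "const": "ramanredox"},
    "version": {"type": "string"},
    "config_hash": {"type": "string", "description": "md5 of the configuration (provenance)"},
    "created": {"type": "string", "description": "ISO-8601 timestamp"},
    "n_spectra": {"type": "integer", "minimum": 1},
    "calibration": {
      "type": "object",
      "required": ["q", "se", "n"],
      "properties": {
        "q": {"type": "number", "exclusiveMinimum": 0},
        "se": {"type": "number", "minimum": 0},
        "n": {"type": "integer", "minimum": 1}
      }
    },
    "indices": {
      "type": "array",
      "description": "one row per input spectrum; filenames unique",
      "items": {
        "type": "object",
        "required": ["filename", "condition", "replicate", "norm_604",
                     "norm_750", "norm_1127", "norm_1337", "norm_1358",
                     "norm_1377", "ratio_c_b", "f_dmb", "i_sum"]
      }
    },
    "summaries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["condition", "index", "n", "mean", "se"]
      }
    },
    "comparisons": {
      "type": ["object", "null"],
      "description": "per-index Kruskal-Wallis p and Dunn post-hoc table"
    },
    "percent_of_control": {
      "type": ["array", "null"],
      "description": "per-condition index means as percent of the control mean"
    }
  }
}
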