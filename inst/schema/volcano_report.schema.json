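{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "volcano_report",
  "type": "object",
  "required": ["dataset", "settings", "selection", "model", "shape",
               "outliers", "table", "version"],
  "properties": {
    "dataset": {
      "type": "object",
      "required": ["n", "x_col", "y_col", "dropped_rows"],
      "properties": {
        "n": {"type": "integer", "minimum": 3},
        "x_col": {"type": "string"},
        "y_col": {"type": "string"},
        "descriptor_names": {"type": "array", "items": {"type": "string"}},
        "dropped_rows": {"type": "integer", "minimum": 0},
        "provenance": {"type": "string"}
      }
    },
    "settings": {
      "type": "object",
      "required": ["lambda", "min_segment", "max_breakpoints",
                   "contamination", "bic_form"],
      "properties": {
        "lambda": {"type": "number", "minimum": 0},
        "weight_floor": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "explicit_weights": {"type": "boolean"},
        "min_segment": {"type": "integer", "minimum": 2},
        "max_breakpoints": {"type": "integer", "minimum": 0, "maximum": 2},
        "flat_tol": {"type": "number", "minimum": 0},
        "orientation": {"enum": ["maximize", "minimize"]},
        "z": {"type": "number", "minimum": 0},
        "contamination": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 0.5},
        "bic_form": {"type": "string"}
      }
    },
    "selection": {
      "type": "object",
      "required": ["chosen_b", "candidates"],
      "properties": {
        "chosen_b": {"type": "integer", "minimum": 0, "maximum": 2},
        "candidates": {"type": "object"},
        "infeasible": {"type": "object"}
      }
    },
    "model": {
      "type": "object",
      "required": ["alpha", "intercept", "betas", "psis", "r2", "rss",
                   "converged"],
      "properties": {
        "alpha": {"type": "number"},
        "intercept": {"type": "number"},
        "betas": {"type": "array", "items": {"type": "number"}},
        "psis": {"type": "array", "items": {"type": "number"}},
        "segment_slopes": {"type": "array", "items": {"type": "number"}},
        "psi_se": {"type": "array"},
        "r2": {"type": "number", "maximum": 1},
        "bic": {"type": ["number", "string"]},
        "rss": {"type": "number", "minimum": 0},
        "converged": {"type": "boolean"},
        "demoted": {"type": "boolean"}
      }
    },
    "shape": {
      "enum": ["volcano_sharp", "volcano_plateau", "monotonic",
               "inverted", "flat", "invalid"]
    },
    "peak": {
      "type": ["object", "null"],
      "required": ["x_peak", "y_peak", "x_lo", "x_hi", "kind"],
      "properties": {
        "x_peak": {"type": "number"},
        "y_peak": {"type": "number"},
        "x_lo": {"type": "number"},
        "x_hi": {"type": "number"},
        "kind": {"enum": ["sharp", "plateau"]},
        "band_available": {"type": "boolean"}
      }
    },
    "outliers": {
      "type": "object",
      "required": ["method", "contamination", "flags"],
      "properties": {
        "method": {"enum": ["mcd", "robust_z"]},
        "contamination": {"type": "number"},
        "cutoff": {"type": "number"},
        "flags": {"type": "array", "items": {"type": "boolean"}},
        "robust_distance": {"type": "array", "items": {"type": "number"}}
      }
    },
    "table": {
      "type": "object",
      "required": ["label", "x", "y", "weight", "predicted", "residual",
                   "outlier"]
    },
    "version": {"type": "string"}
  }
}
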