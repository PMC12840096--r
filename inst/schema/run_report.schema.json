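{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ampcnv run report",
  "type": "object",
  "required": ["tool", "version", "seed", "configs", "data", "diagnostics", "calls"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "configs": {
      "type": "object",
      "required": ["hyperparameters"],
      "properties": {
        "hyperparameters": {"type": "object"},
        "sampler": {"type": "object"},
        "calling": {"type": "object"}
      }
    },
    "data": {
      "type": "object",
      "required": ["n_genes", "n_amplicons", "n_filtered"],
      "properties": {
        "n_genes": {"type": "integer"},
        "n_amplicons": {"type": "integer"},
        "n_filtered": {"type": "integer"},
        "reference": {"type": "string"}
      }
    },
    "diagnostics": {
      "type": "object",
      "required": ["mean_accept_prob", "num_divergences", "min_ess"],
      "properties": {
        "mean_accept_prob": {"type": "number"},
        "num_divergences": {"type": "number"},
        "min_ess": {"type": "number"}
      }
    },
    "convergence": {"type": "object"},
    "calls": {"type": "array"},
    "evidence": {"type": "object"}
  }
}
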