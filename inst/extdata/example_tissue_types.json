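{
  "tonsil": ["B cell", "T cell", "Macrophage"],
  "lung": ["Epithelial", "Macrophage", "T cell"],
  "intestine": ["B cell", "Epithelial", "Macrophage", "T cell"]
}
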