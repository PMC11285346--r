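{
  "markers": [
    {
      "node": "G003_2",
      "cell_type": "T01",
      "direction": "inclusion"
    }
  ],
  "mxe": [
    {
      "node_a": "G001_3",
      "node_b": "G001_4",
      "cell_type": "T02",
      "orientation": "a_in_b_out"
    }
  ],
  "blocks": [
    {
      "gene": "G002",
      "node_start": 2,
      "node_end": 4,
      "cell_type": "T03",
      "direction": "above"
    }
  ]
}
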