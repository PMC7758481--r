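CD8:
  - CD8A
  - CD8B
CTL:
  - GZMA
  - GZMB
  - PRF1
  - KLRD1
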