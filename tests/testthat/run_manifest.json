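{
  "command": "help",
  "package_version": "0.1.0",
  "seed": 1,
  "x": "1",
  "files": []
}
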