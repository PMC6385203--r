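{
  "acidic_pocket": ["E97", "D237", "S240", "E242", "D347", "D351", "E355", "Y191", "T236"],
  "thumb_base": ["V187", "F188", "S199", "D253", "E254", "F257", "F301", "F302", "D303", "I312", "E315"],
  "central_vestibule": ["E79", "D212", "Q276", "Q278", "R371", "E375", "E413", "E418"],
  "side_cavity": ["L261", "F263", "A274", "I307", "V414", "N416", "F411", "L415"]
}
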