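[{"camera":"right","frame":0,"label":"weed","score":1,"box":{"x_min":-139.15019762845861,"y_min":425,"x_max":360.84980237154139,"y_max":775}}]
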