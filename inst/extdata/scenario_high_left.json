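[{"camera":"left","frame":0,"label":"weed","score":1,"box":{"x_min":919.1501976284585,"y_min":425,"x_max":1419.1501976284585,"y_max":775}}]
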