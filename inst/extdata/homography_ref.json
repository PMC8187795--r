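{
  "h": [
    [9.29968576e-01, -8.34785721e-01, 3.28368011e+02],
    [3.21580417e-01, 9.89425377e-01, -3.15245367e+02],
    [-7.93435882e-05, 5.73575359e-05, 1.0]
  ]
}
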