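# Rectal NTCP endpoint parameter registry, version 1.
# LKB endpoints: n (volume effect), m (slope), td50 (Gy).
# RS endpoints: d50 (Gy), gamma (slope at D50), s (seriality).
# alpha_beta in Gy applies to the EQD2 conversion for all endpoints.
version: 1
alpha_beta: 3.0
# NB: the volume-effect key must be quoted ("n" is a YAML 1.1 boolean).
lkb:
  G1-LRB:              {"n": 0.23, m: 0.37, td50: 57.3}
  G2-LRB:              {"n": 0.19, m: 0.32, td50: 75.8}
  G1-stool-frequency:  {"n": 0.27, m: 0.56, td50: 55.7}
  G2-stool-frequency:  {"n": 0.31, m: 0.36, td50: 75.8}
  G1-bowel-pain:       {"n": 0.17, m: 0.49, td50: 142.6}
  G1-sphincter-control: {"n": 0.24, m: 0.32, td50: 79.1}
  G1-stricture-ulcer:  {"n": 0.32, m: 0.25, td50: 84.4}
rs:
  G2-LRB:              {d50: 83.6, gamma: 1.42, s: 0.50}
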