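; minimal example of the simplified ASC dialect:
; a CellBody contour block plus parenthesized branch trees,
; "|" separates sibling branches; thickness values are diameters (um)
("CellBody"
  (-4.2  2.1 0 1) (-0.5  4.8 0 1) ( 3.9  2.6 0 1)
  ( 4.6 -1.8 0 1) ( 0.3 -4.9 0 1) (-3.8 -2.4 0 1)
)
("Dendrite"
  (6.1 0.4 0.2 1.6) (11.8 1.0 0.6 1.4)
  ( (16.2  4.1 1.1 1.1) (20.5  7.3 1.8 1.0)
  | (16.0 -3.2 0.9 1.1) (20.1 -6.8 1.2 0.9) )
)
("Axon"
  (-5.9 -0.7 -0.3 1.0) (-12.3 -1.5 -0.8 0.9) (-18.8 -2.0 -1.4 0.8)
)
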