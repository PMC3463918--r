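{
  "_comment": "Small synthetic example of a defective skeleton graph: one monofurcation (m), one trifurcation (t), parallel parent edges (p1/p2) and an isolated node (iso). correct_graph() repairs it into a strictly bifurcative tree.",
  "nodes": [
    {"id": "root", "x": 0.0, "y": 0.0, "z": 30.0},
    {"id": "t", "x": 0.0, "y": 0.0, "z": 20.0},
    {"id": "a", "x": -12.0, "y": 0.0, "z": 10.0},
    {"id": "b", "x": 0.0, "y": 8.0, "z": 10.0},
    {"id": "c", "x": 10.0, "y": -4.0, "z": 12.0},
    {"id": "m", "x": -16.0, "y": 1.0, "z": 4.0},
    {"id": "a1", "x": -20.0, "y": 2.0, "z": -2.0},
    {"id": "c1", "x": 14.0, "y": -8.0, "z": 4.0},
    {"id": "c2", "x": 16.0, "y": 0.0, "z": 6.0},
    {"id": "iso", "x": 50.0, "y": 50.0, "z": 50.0}
  ],
  "edges": [
    {"id": "trunk", "from": "root", "to": "t", "radius": 4.0},
    {"id": "d_a", "from": "t", "to": "a", "radius": 2.6},
    {"id": "d_b", "from": "t", "to": "b", "radius": 1.9},
    {"id": "d_c", "from": "t", "to": "c", "radius": 2.2},
    {"id": "mono_in", "from": "a", "to": "m", "radius": 2.1},
    {"id": "mono_out", "from": "m", "to": "a1", "radius": 1.7},
    {"id": "p1", "from": "c", "to": "c1", "radius": 1.2},
    {"id": "p2", "from": "c", "to": "c1", "radius": 0.9},
    {"id": "d_c2", "from": "c", "to": "c2", "radius": 1.4}
  ],
  "roots": ["root"]
}
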