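{
  "swim_speed": 19.0,
  "tumble_diffusion": 6.61,
  "run_rot_diffusion": 0.062,
  "tumble_rot_diffusion": 3.5,
  "char_frequency": 9.27,
  "curvature_radius": 25.0,
  "z_surface": 3.0,
  "z_bulk": 8.0,
  "dt": 0.001,
  "t_cap": 300.0
}
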