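# Default pipeline configuration (all keys optional; these are the
# package defaults, spelled out).
seed: 1
scan:
  phantom_diameter: 200      # mm
  insert_diameter: 25        # mm
  insert_offset_mm: 60       # mm from phantom centre
  blur_sigma: 0.45           # mm, Gaussian system PSF (Standard kernel)
  noise_sd: 4                # HU inside the phantom (140 mA reference)
  matrix: 512
  pixel_mm: 0.459
  n_slices: 5
ttf:
  material: bone             # bone | acrylic | polyethylene | air | phantom-edge
nps:
  n_rois: 5                  # 1, 2, 3, 4, 5, 6 or 9
  shift: left                # left | right | up | down | none
task:
  diameter: 5                # mm
  contrast: 15               # HU
  matrix: 300
  pixel_mm: 0.05
observer: NPW                # NPW | NPWE | NPWi
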