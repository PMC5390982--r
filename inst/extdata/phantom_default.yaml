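# Default cranium phantom: spherical bone shell (outer radius 16 mm, wall
# 6 mm) in a 64^3 volume at 1 mm isotropic spacing, with a canal-like
# opening at the base (foramen magnum analogue), a few diploic voids in the
# wall, one thin crack, and mild CT noise.
dims: [64, 64, 64]
spacing: [1.0, 1.0, 1.0]
outer_radius: 16
thickness: 6
bone_value: 400
air_value: -1000
openings:
  - direction: [0, 0, -1]
    radius: 8
diploic_voids:
  n: 6
  radius_range: [1.0, 2.0]
cracks:
  - normal: [1, 0, 0]
    thickness: 1.0
    offset: 0
noise_sd: 50
seed: 1
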