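# End-to-end demo: simulate a 2 x 60 Mb genome with 30 cut sites and run
# every analysis stage. Values in bp unless noted.
seed: 7
out_dir: dsbchrom_demo
stages: [simulate, hic, insulation, chip, asymmetry, boundary, bands]
simulation:
  n_sites: 30
  min_separation: 1000000
  edge_margin: 2000000
  params:
    genome: {chrA: 60000000, chrB: 60000000}
    contact_bin_size: 25000
    stripe_strength: 2
    stripe_extent: 1000000
    cut_attenuation: 0.4
    depth: 5000000
hic:
  half_width: 1500000
  epsilon: 1
insulation:
  square_size: 500000
  window: 50000
boundary:
  dist_range: [200000, 700000]
  flank: 100000
  n_controls: 100
bands:
  broadening: 1.5
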