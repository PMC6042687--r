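# Demo run: simulated Drosophila-like nuclei with three whole-arm paints,
# strong somatic pairing, and three sub-arm band probes (cen/mid/tel) tiled
# along the first paint's chain. The schema mirrors sim_params()
# field-for-field; bead index ranges are [from, to].
simulation:
  nucleus_radii: [2.5, 4.0, 4.0]        # ellipsoid semi-axes (z, y, x) um
  voxel_spacing: [0.25, 0.1, 0.1]       # um, anisotropic widefield stack
  grid_dim: [64, 128, 128]
  channels:
    - {name: chr2L, n_chains: 2, beads_per_chain: 120, bead_radius: 0.3, step_length: 0.5}
    - {name: chr2R, n_chains: 2, beads_per_chain: 120, bead_radius: 0.3, step_length: 0.5}
    - {name: chrX,  n_chains: 2, beads_per_chain: 120, bead_radius: 0.3, step_length: 0.5}
  confinement: 0.3                      # condensin-II-like compaction dial
  anchor_min_sep: 2.0                   # um between unpaired homolog anchors
  pairing_prob: 0.9                     # >90% somatic pairing
  band_probes: {channel: chr2L, cen: [1, 15], mid: [53, 67], tel: [106, 120]}
  # translocation: {donor: chr2L, acceptor: chr2R, fraction: 0.3}
  psf_sigma: [0.25, 0.12, 0.12]         # um, post-deconvolution effective PSF
  photon_scale: 150
  read_noise_sd: 3
  background: 100
  seed: 1
n_cells: 100
seed: 1
dna_channel: dna
min_volume: 0.05                        # um^3 component filter
relative_min: 0.1                       # speck filter for pairing calls
contact_mode: adjacency
report:
  plots: false
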