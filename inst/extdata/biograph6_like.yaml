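# Biograph-6-like full-ring scanner used as a collimator-less cascade
# coincidence camera. Crystal pitches are left unset so they tile the ring
# circumference and the axial FOV exactly.
ring_radius: 424.5
n_modules: 48
crystals_per_module_transaxial: 13
crystals_per_module_axial: 13
n_block_rings: 3
transaxial_fov: 585.0
axial_fov: 162.0
detection_efficiency: 0.9
energy_resolution_range: [0.12, 0.18]
ctr_fwhm_ps: 100
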