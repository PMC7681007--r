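# Worked siQ-ChIP manifest.
# The ip block carries the published worked-example bench numbers for an
# H3K27me3 IP (37,298,373 mapped reads; 20 of 856 fmol library sequenced;
# 11 PCR cycles; 10 of 24.2 ng carried into the library). Bead-capture yield
# rho is left at 1 (the no-loss limit) because it was not printed.
# The input block and the volumes are illustrative/synthetic: input-side
# bench values were not published.
ip:
  mapped_reads: 37298373
  library_sequenced: 20
  library_total: 856
  pcr_cycles: 11
  bead_capture_yield: 1
  ip_mass_total: 24.2
  mass_into_library: 10
  molar_unit: fmol
  mass_unit: ng
input:
  mapped_reads: 30000000
  library_sequenced: 20
  library_total: 400
  pcr_cycles: 6
  bead_capture_yield: 1
  ip_mass_total: 60
  mass_into_library: 10
  molar_unit: fmol
  mass_unit: ng
volumes:
  total_volume: 600
  input_aliquot: 60
  unit: ul
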