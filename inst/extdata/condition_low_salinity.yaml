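# Low-salinity growth condition for the bundled toy model: measured-style
# glucose uptake, default maintenance, low-salinity biomass formulation.
name: low
biomass: BIO_L
exchanges:
  EX_glc: [-10, 0]
atpm:
  id: ATPM
  flux: 7.6
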