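# High-salinity growth condition: reduced glucose uptake, doubled upkeep
# (ion gradients and solute synthesis are energetically expensive),
# high-salinity biomass formulation.
name: high
biomass: BIO_H
exchanges:
  EX_glc: [-6.5, 0]
atpm:
  id: ATPM
  flux: 15.2
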