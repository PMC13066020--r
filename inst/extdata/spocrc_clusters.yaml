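# Node-set rosters for the spoCRC model.
#
# inflammatory_cluster: the immune-environment nodes (immune cells,
#   cytokines, chemokines, and their receptors). Clamped OFF to simulate the
#   model without the inflammatory network. The exact roster is reconstructed
#   from the network wiring and is a reproduction sensitivity.
# start_off: nodes that always start in the OFF state (the inflammatory
#   cascade including receptors, COX2/PGE2/EP2, and the two readout nodes).
inflammatory_cluster:
  - DC
  - MAC
  - TH
  - TREG
  - IL6
  - CCL2
  - TNFa
  - TGFb
  - IL10
  - IL1b
  - IL12
  - IFNg
  - GP130
  - TNFR1
  - TGFBR
  - CCR2
  - IL1R
  - IL10R
start_off:
  - DC
  - MAC
  - TH
  - TREG
  - IL6
  - CCL2
  - TNFa
  - TGFb
  - IL10
  - IL1b
  - IL12
  - IFNg
  - GP130
  - TNFR1
  - TGFBR
  - CCR2
  - IL1R
  - IL10R
  - COX2
  - PGE2
  - EP2
  - Apoptosis
  - Proliferation
reporting_nodes:
  apoptosis: Apoptosis
  proliferation: Proliferation
  b_catenin: bcatenin
  cox2_pge2: COX2
  akt: AKT
  nfkb: NFkB
  il6: IL6
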