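# COXIB inhibition profiles: target node -> polymorphism of the attached
# inhibitor node (the per-step probability that the drug node is active and
# shuts its target down). Both drugs nearly fully block COX2 (0.9); celecoxib
# additionally inhibits AKT, NF-kB and PDE5 at 0.3, sulindac cannot inhibit
# AKT (0.0). Potency differences beyond AKT are not modeled.
celecoxib:
  COX2: 0.9
  AKT: 0.3
  NFkB: 0.3
  PDE5: 0.3
sulindac:
  COX2: 0.9
  AKT: 0.0
  NFkB: 0.3
  PDE5: 0.3
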