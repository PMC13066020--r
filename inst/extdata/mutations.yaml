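# CRC mutation sets as node clamps (whole-run).
# LOF = clamp OFF, GOF = clamp ON; 18q allelic loss removes SMAD, DCC and
# the netrin-bound receptor diDCC. Combinations are unions of clamps.
APC_LOF:
  APC: "off"
P53_LOF:
  p53: "off"
RAS_GOF:
  RAS: "on"
LOSS_18Q:
  SMAD: "off"
  DCC: "off"
  diDCC: "off"
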