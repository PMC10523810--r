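# ICD-10 code-set registry for road traffic mortality quality assessment.
#
# Five nonspecific ("garbage") categories, each with:
#   garbage_sets:  the codes counted as nonspecific at that level
#   denominators:  the parent set of the level (garbage members of the level
#                  included), used for coding-quality proportions and for the
#                  temporal-window rule
#   targets:       the destination set for proportionate redistribution
#                  (garbage codes of every category are always excluded from
#                  targets, on top of the ranges listed here)
#
# Codes are "X59" (3-character) or "V87.3" (4-character). Ranges "V01-X59" are
# inclusive at the 3-character level and span ICD-10 letter order.
# A bare "V87" is listed as garbage: a road vehicle collision with the road
# user left unspecified.
version: 1
garbage_sets:
  ILL_DEFINED: [R95, R96, R98, R99]
  UNDETERMINED_INTENT: [Y34, Y87.2, Y89.9]
  UNSPEC_UNINTENTIONAL: [X59]
  UNSPEC_TRANSPORT: [V99, Y85.9]
  UNSPEC_RT: [V87, V87.0, V87.1, V87.2, V87.3, V87.4, V87.5, V87.6, V87.7, V87.8, V89.2]
denominators:
  ILL_DEFINED: [A00-Z99]
  UNDETERMINED_INTENT: [V01-Y89]
  UNSPEC_UNINTENTIONAL: [V01-X59]
  UNSPEC_TRANSPORT: [V01-V99, Y85.9]
  UNSPEC_RT: [V01-V89]
targets:
  ILL_DEFINED: [A00-Z99]
  UNDETERMINED_INTENT: [V01-Y89]
  UNSPEC_UNINTENTIONAL: [V01-X59]
  UNSPEC_TRANSPORT: [V01-V98]
  UNSPEC_RT: [V20-V79]
road_user_groups:
  PEDESTRIAN: [V01-V09]
  PEDAL_CYCLIST: [V10-V19]
  MOTORCYCLIST: [V20-V29]
  OCCUPANT: [V30-V79]
  OTHER_RT: [V80-V89]
road_traffic: [V01-V89]
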