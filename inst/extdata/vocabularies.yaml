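# Controlled vocabularies for fishery classification.
# version 1: 25 gear types (Kelleher-style names), 19 FAO Major Fishing
# Areas (codes kept as strings), 8 target species groups.
version: 1
period:
  start: 2010
  end: 2014
gear_types:
  - bottom otter trawl
  - beam trawl
  - shrimp trawl
  - midwater trawl
  - pair trawl
  - dredge
  - purse seine
  - beach seine
  - danish seine
  - surrounding net (other)
  - gillnet
  - trammel net
  - entangling net
  - pelagic longline
  - demersal longline
  - handline
  - pole and line
  - troll line
  - jig
  - pot and trap
  - barriers, fences and traps
  - lift net
  - cast net
  - harpoon
  - unspecified gear
fao_areas:
  - "18"
  - "21"
  - "27"
  - "31"
  - "34"
  - "37"
  - "41"
  - "47"
  - "48"
  - "51"
  - "57"
  - "58"
  - "61"
  - "67"
  - "71"
  - "77"
  - "81"
  - "87"
  - "88"
target_groups:
  - demersal fishes
  - small pelagic fishes
  - tuna and billfishes
  - crustaceans
  - cephalopods
  - molluscs excl. cephalopods
  - sharks and rays
  - miscellaneous coastal fishes
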