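species:
- order: Anseriformes
  common_name: Mallard
  species_name: Anas platyrhynchos
  diploid_number: 80.0
  fusions: []
  probe_failures: []
- order: Charadriiformes
  common_name: Eurasian woodcock
  species_name: Scolopax rusticola
  diploid_number: 96.0
  fusions: []
  probe_failures: []
- order: Columbiformes
  common_name: Rock dove
  species_name: Columba livia
  diploid_number: 80.0
  fusions: []
  probe_failures: []
- order: Columbiformes
  common_name: Eurasian collared dove
  species_name: Streptopelia decaocto
  diploid_number: 76.0
  fusions: []
  probe_failures: []
- order: Falconiformes
  common_name: Peregrine falcon
  species_name: Falco peregrinus
  diploid_number: 50.0
  fusions:
    GGA4:
    - GGA15
    - GGA18
    - GGA19
    GGA2:
    - GGA23
    - GGA28
    GGA1: GGA10
    GGA3: GGA12
    GGA5: GGA13
    GGA6: GGA14
    GGA7: GGA17
    GGA8: GGA21
  probe_failures: []
- order: Falconiformes
  common_name: Saker falcon
  species_name: Falco cherrug
  diploid_number: 52.0
  fusions:
    GGA4:
    - GGA15
    - GGA18
    - GGA19
    GGA2:
    - GGA23
    - GGA28
    GGA1: GGA10
    GGA3: GGA12
    GGA5: GGA13
    GGA6: GGA14
    GGA7: GGA17
    GGA8: GGA21
  probe_failures: []
- order: Falconiformes
  common_name: Gyrfalcon
  species_name: Falco rusticolus
  diploid_number: 52.0
  fusions:
    GGA4:
    - GGA15
    - GGA18
    - GGA19
    GGA2:
    - GGA23
    - GGA28
    GGA1: GGA10
    GGA3: GGA12
    GGA5: GGA13
    GGA6: GGA14
    GGA7: GGA17
    GGA8: GGA21
  probe_failures: []
- order: Galliformes
  common_name: Turkey
  species_name: Meleagris gallopavo
  diploid_number: 80.0
  fusions: []
  probe_failures: []
- order: Galliformes
  common_name: Chinese quail
  species_name: Coturnix chinensis
  diploid_number: 78.0
  fusions: []
  probe_failures: []
- order: Galliformes
  common_name: Japanese quail
  species_name: Coturnix japonica
  diploid_number: 78.0
  fusions: []
  probe_failures: []
- order: Galliformes
  common_name: Guinea fowl
  species_name: Numida meleagris
  diploid_number: 78.0
  fusions: []
  probe_failures: []
- order: Galliformes
  common_name: Indian peafowl
  species_name: Pavo cristatus
  diploid_number: 78.0
  fusions: []
  probe_failures: []
- order: Galliformes
  common_name: Sand partridge
  species_name: Ammoperdix heyi
  diploid_number: 78.0
  fusions: []
  probe_failures: []
- order: Otidiformes
  common_name: Houbara bustard
  species_name: Chlamydotis undulata
  diploid_number: 76.0
  fusions: []
  probe_failures: []
- order: Passeriformes
  common_name: Common blackbird
  species_name: Turdus merula
  diploid_number: 80.0
  fusions: []
  probe_failures: GGA25
- order: Passeriformes
  common_name: Atlantic canary
  species_name: Serinus canaria
  diploid_number: 80.0
  fusions: []
  probe_failures: GGA25
- order: Passeriformes
  common_name: Zebra finch
  species_name: Taeniopygia guttata
  diploid_number: 80.0
  fusions: []
  probe_failures: GGA25
- order: Psittaciformes
  common_name: Budgerigar
  species_name: Melopsittacus undulatus
  diploid_number: 62.0
  fusions:
    GGA1: GGA10
    GGA2: GGA11
    GGA3: GGA14
    GGA4: GGA12
    GGA5: GGA13
    GGA6: GGA17
  probe_failures: []
- order: Psittaciformes
  common_name: Cockatiel
  species_name: Nymphicus hollandicus
  diploid_number: 72.0
  fusions:
    GGA2: GGA10
    GGA1: GGA11
    GGA3: GGA14
  probe_failures: []
- order: Psittaciformes
  common_name: Red-crowned parakeet
  species_name: Cyanoramphus novaezelandiae
  diploid_number: 70.0
  fusions:
    GGA2: GGA10
    GGA1: GGA11
    GGA3: GGA14
  probe_failures: []
- order: Strigiformes
  common_name: Pharaoh eagle-owl
  species_name: Bubo ascalaphus
  diploid_number: 72.0
  fusions: []
  probe_failures: []
- order: Struthioniformes
  common_name: Common ostrich
  species_name: Struthio camelus
  diploid_number: 80.0
  fusions: []
  probe_failures: []
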