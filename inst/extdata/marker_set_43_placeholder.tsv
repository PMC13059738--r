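# Placeholder 43-gene bacterial single-copy marker set (names only).
# Completeness/redundancy arithmetic depends only on the set size; supply
# your own curated list (e.g. a CPR-adapted set) for real bins.
marker
rplA
rplB
rplC
rplD
rplE
rplF
rplI
rplK
rplL
rplM
rplN
rplO
rplP
rplQ
rplR
rplS
rplT
rplU
rplV
rplW
rplX
rpmA
rpsB
rpsC
rpsD
rpsE
rpsG
rpsH
rpsI
rpsJ
rpsK
rpsL
rpsM
rpsO
rpsP
rpsQ
rpsR
rpsS
infB
pheS
pheT
secY
ffh
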