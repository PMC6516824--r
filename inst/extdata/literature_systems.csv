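name,mechanism,n1,n2
Tau,fragmentation,NA,NA
Ure2p,fragmentation,NA,NA
Actin-Arp2/3,lateral branching,NA,NA
IAPP,monomer-dependent secondary nucleation,NA,NA
Amyloid-beta40,monomer-dependent secondary nucleation,NA,NA
Amyloid-beta42,monomer-dependent secondary nucleation,NA,NA
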