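synthetic toy panel (hand-written example data, not empirical)
SCA30
SM3
SM37
SCA47
SCA49
90RTE
SCA8
Pop
fish01 ,  001002 001001 002003 001001 001002 001001 001004
fish02 ,  001001 001002 002002 001002 002002 001001 001001
fish03 ,  002003 001001 001002 001001 001001 001002 002002
fish04 ,  001002 002002 000000 001001 001002 001001 001003
fish05 ,  001001 001003 001001 001002 001001 001001 001002
fish06 ,  003003 001001 002002 000000 001002 001002 002004
fish07 ,  001003 001002 001002 001001 002002 001001 001001
fish08 ,  001001 002003 001001 001002 001001 001001 003003
fish09 ,  001002 001001 002003 001001 001002 001002 001002
fish10 ,  002002 001002 001002 001001 000000 001001 001004
Pop
fish11 ,  001001 001001 002002 002002 001001 001001 002002
fish12 ,  001002 001002 001002 001002 001002 001002 001002
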