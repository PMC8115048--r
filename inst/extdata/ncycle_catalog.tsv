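symbol	ko	keywords
focA	K03459	formate[ /-]?nitrite transporter|\bfocA\b
nirA	K00366	ferredoxin[ -]+nitrite reductase|\bnirA\b
nirK	K00368	copper[ -]containing nitrite reductase|nitrite reductase \(NO[ -]forming\)|\bnirK\b
norB	K04561	nitric[ -]oxide reductase|\bnorB\b
amoC	K10946	ammonia monooxygenase subunit C|methane/ammonia monooxygenase subunit C|\bamoC\b
glnK	K04752	nitrogen regulatory protein P[ -]?II|PII protein|\bglnK\b
amtB	K03320	ammonium transporter|\bamtB\b
ompL	K07275	porin OmpL|outer membrane porin OmpL|\bompL\b
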