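# Synthetic snapshot of available AD mouse-model strain names (11 entries).
# Strain names are the canonical identifiers; matching is on the normalized
# token n-gram ("3xTg-AD" -> [3xtg, ad]).
5xFAD: 5xFAD
3xTg-AD: 3xTg-AD
Tg2576: Tg2576
PS19: PS19
TgCRND8: TgCRND8
J20: J20
rTg4510: rTg4510
TgSwDI: TgSwDI
LOAD1: LOAD1
LOAD2: LOAD2
hAbeta-KI: hAbeta-KI
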