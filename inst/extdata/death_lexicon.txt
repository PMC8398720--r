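# Open death-category word list (one entry per line, trailing * = prefix
# wildcard). Stands in for proprietary dictionaries of the same semantic
# category; counts are comparable in spirit, not numerically identical.
die
dies
died
dying
dead
deadly
death*
deceas*
demise
fatal*
lethal*
kill*
murder*
homicid*
suicid*
massacre*
slaughter*
genocide
drown*
overdos*
perish*
corpse*
cadaver*
casket*
coffin*
grave
graves
graveyard*
tomb*
bury
buries
buried
burial*
cremat*
funeral*
eulog*
obituar*
mourn*
grief
griev*
bereave*
widow*
euthanas*
autopsy
morgue
mortuary
mortal*
afterlife
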