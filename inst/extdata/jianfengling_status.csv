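species,national_level,redlist,cites
Macaca mulatta,II,LC,II
Muntiacus nigripes,II,VU,
Sus scrofa,,LC,
Paradoxurus hermaphroditus,II,EN,III
Melogale moschata,,NT,
Atherurus macrourus,,LC,
Dremomys pyrrhomerus,,NT,
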