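s01	north
s02	north
s03	north
s04	south
s05	south
s06	south
s07	east
s08	east
s09	east
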