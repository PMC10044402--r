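species	functional	partial	pseudogene	subfamilies
Giant panda	408	94	137	248
Spectacled bear	269	106	73	205
American black bear	497	17	103	249
Brown bear	423	70	89	241
Polar bear	394	33	94	252
Asian black bear	608	89	95	271
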