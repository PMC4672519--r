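compound	s_thermophilus	l_bulgaricus	note
Amino acids	Consumes	Provides	literature-derived annotation; not produced by this package
Carbon dioxide	Provides	Consumes	literature-derived annotation; not produced by this package
Fatty acids	Provides	Consumes	literature-derived annotation; not produced by this package
Folic acid	Provides	Consumes	literature-derived annotation; not produced by this package
Formic acid	Provides	Consumes	literature-derived annotation; not produced by this package
Ornithine	Provides	Consumes	literature-derived annotation; not produced by this package
Peptides	Consumes	Provides	literature-derived annotation; not produced by this package
Putrescine	Consumes	Provides	literature-derived annotation; not produced by this package
Pyruvatic acid	Provides	Consumes	literature-derived annotation; not produced by this package
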