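metabolite	max_uptake
biotin	10
lactose	10
milk_peptides	10
nicotinate	10
pantothenate	10
phosphate	10
pyridoxamine	10
riboflavin	10
thiamin	10
water	1000
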