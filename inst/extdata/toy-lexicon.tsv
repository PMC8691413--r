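okay	0.25
fine	0.5
decent	0.75
good	1.0
nice	1.25
happy	1.5
glad	1.75
great	2.0
lovely	2.25
wonderful	2.5
amazing	2.75
excellent	3.0
helpful	1.0
kind	1.5
hopeful	2.0
safe	1.0
true	0.5
calm	0.75
dull	-0.25
poor	-0.5
sad	-0.75
bad	-1.0
upset	-1.25
angry	-1.5
awful	-1.75
terrible	-2.0
horrible	-2.25
disgusting	-2.5
dreadful	-2.75
horrific	-3.0
useless	-1.0
scary	-1.5
dangerous	-2.0
false	-0.5
wrong	-0.75
fear	-1.25
hate	-2.25
lie	-1.75
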