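OSM	phosphorylates	STAT3
STAT3	phosphorylates	HIF1A
HIF1A	phosphorylates	VEGFA
STAT3	phosphorylates	JUN
SP1	phosphorylates	CEBPB
STAT3	phosphorylates	SP1
HIF1A	phosphorylates	TIMP1
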