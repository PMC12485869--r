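node	assay	condition	lfc
STAT3	protein	OSM	1.8
STAT3	transcript	OSM	2.4
HIF1A	protein	OSM	2.1
VEGFA	transcript	OSM	1.4
SP1	transcript	OSM	0.6
JUN	protein	OSM	1.1
TIMP1	transcript	OSM	1.9
CEBPB	transcript	OSM	-0.4
OSM	transcript	OSM	3.0
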