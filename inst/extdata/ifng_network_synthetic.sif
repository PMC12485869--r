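IFNG	phosphorylates	STAT1
STAT1	phosphorylates	STAT3
SP1	phosphorylates	CEBPB
STAT3	phosphorylates	JUN
STAT1	phosphorylates	IRF1
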