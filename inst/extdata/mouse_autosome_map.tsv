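chrom	length_cM
chr1	98.5
chr2	103.9
chr3	82.7
chr4	88.6
chr5	90.2
chr6	79.0
chr7	89.1
chr8	76.2
chr9	75.1
chr10	77.9
chr11	88.0
chr12	63.9
chr13	67.3
chr14	66.4
chr15	59.0
chr16	57.8
chr17	60.6
chr18	59.4
chr19	56.7
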