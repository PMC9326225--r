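chrom	length
chr1	1e+07
chr2	1e+07
chr3	1e+07
chr4	1e+07
chr5	1e+07
chr6	1e+07
chr7	1e+07
chr8	1e+07
chr9	1e+07
chr10	1e+07
chr11	1e+07
chr12	1e+07
chr13	1e+07
chr14	1e+07
chr15	1e+07
chr16	1e+07
chr17	1e+07
chr18	1e+07
chr19	1e+07
chr20	1e+07
chr21	1e+07
chr22	1e+07
chrX	1e+07
chrY	1e+07
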