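metric	hap_a	hap_b
contig_n50_mb	15.08	9.77
scaffold_n50_mb	113.08	118.94
longest_scaffold_mb	208.22	207.91
assembled_size_mb	2100.886	2156.539
gc_content_pct	40.33	40.22
anchored_pct	97.19	97.96
repeat_pct	74.02	71.73
gene_number	64070	68392
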