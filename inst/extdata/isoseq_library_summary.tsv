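library_size_kb	smrt_cells	polymerase_reads	flnc_reads	hq_isoforms
1-2	12	905500	419736	117970
2-4	12	1231202	612254	144968
3-5	12	1238704	542507	105423
3.5-6	8	697016	161752	55532
4-10	8	818271	246844	28810
Total	52	4890693	1983093	452703
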