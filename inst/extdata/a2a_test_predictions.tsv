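compound_id	tetra	penta
22	8.10378	8.17729
23	8.59992	8.92832
24	8.91106	8.98461
25	7.96806	8.06957
26	8.25996	8.47440
27	7.87135	8.11297
28	8.16918	8.42937
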