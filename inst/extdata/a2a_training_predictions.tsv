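compound_id	tetra	penta	outlier
1	8.98294818	9.12779843	FALSE
2	6.99156978	7.13790683	TRUE
3	8.27890486	8.12289461	TRUE
4	7.20833204	6.98392019	TRUE
5	6.43900240	6.39827940	TRUE
6	8.39284814	8.11686529	FALSE
7	7.76172650	7.89970630	FALSE
8	6.92233110	6.94590035	TRUE
9	8.10517950	8.23468370	FALSE
10	8.45979122	8.24137752	FALSE
11	8.27402464	8.18126794	FALSE
12	7.91841568	8.05102783	FALSE
13	8.11225228	8.20539668	FALSE
14	7.56453846	7.54459856	FALSE
15	7.30993500	7.47680180	FALSE
16	7.42057922	7.53430987	FALSE
17	6.78045040	6.85313340	FALSE
18	7.04603034	7.04921319	FALSE
19	7.50229980	7.23382085	FALSE
20	6.34535314	6.41080264	FALSE
21	5.96752642	5.79898512	FALSE
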