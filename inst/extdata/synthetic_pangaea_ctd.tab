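/* DATA DESCRIPTION:
Synthetic CTD example in the PANGAEA tab-separated dialect.
This file is a constructed fixture (not downloaded repository data) used
to exercise the dialect reader: comment header block, tab separation,
descriptive column labels, and NA cells.
*/
Event	Depth water [m]	Sal	Temp [deg C]	pH	O2 [umol/l]	Fluorometer [arbitrary units]
LL	1	24.3	15.5	8.33	231	2.1
LL	2	28.1	14.2	8.21	215	1.8
LL	50	32.3	11.0	7.92	158	0.3
LL	150	32.6	10.8	7.89	152	0.1
PG	1	NA	17.0	8.41	280	2.5
PG	100	NA	10.6	7.86	148	0.2
PG	300	NA	10.4	7.75	120	0.1
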