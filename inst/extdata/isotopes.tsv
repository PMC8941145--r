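# Stable isotope masses (u) and natural abundances, IUPAC 2021 compilation.
# neutron_shift: nominal mass shift relative to the lightest isotope.
# version: 1
element	isotope	mass	abundance	neutron_shift
C	12C	12.0000000	0.9893	0
C	13C	13.0033548	0.0107	1
H	1H	1.0078250	0.999885	0
H	2H	2.0141018	0.000115	1
N	14N	14.0030740	0.99636	0
N	15N	15.0001089	0.00364	1
O	16O	15.9949146	0.99757	0
O	17O	16.9991317	0.00038	1
O	18O	17.9991596	0.00205	2
S	32S	31.9720707	0.9499	0
S	33S	32.9714589	0.0075	1
S	34S	33.9678670	0.0425	2
S	36S	35.9670809	0.0001	4
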