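step	roll	tilt	twist
AA	-6.471317	-3.156272	35.62
AC	-0.878499	0.661997	34.4
AG	8.394883	0.293156	27.7
AT	2.6	0	31.5
CA	1.534299	-3.145779	34.5
CC	1.143742	-1.761208	33.67
CG	6.7	0	29.8
CT	8.394883	-0.293156	27.7
GA	-2.65	4.589935	36.9
GC	-5	0	40
GG	1.143742	1.761208	33.67
GT	-0.878499	-0.661997	34.4
TA	0.9	0	36
TC	-2.65	-4.589935	36.9
TG	1.534299	3.145779	34.5
TT	-6.471317	3.156272	35.62
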