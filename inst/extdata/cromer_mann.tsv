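# Cromer-Mann 4-Gaussian X-ray atomic form factors, International Tables for
# Crystallography Vol. C, Table 6.1.1.4; excluded solvent volumes (A^3) from
# the Fraser-Suzuki dummy-atom convention used by solution-scattering codes.
element	a1	b1	a2	b2	a3	b3	a4	b4	c	volume_A3
H	0.489918	20.6593	0.262003	7.74039	0.196767	49.5519	0.049879	2.20159	0.001305	5.15
C	2.31000	20.8439	1.02000	10.2075	1.58860	0.568700	0.865000	51.6512	0.215600	16.44
N	12.2126	0.005700	3.13220	9.89330	2.01250	28.9975	1.16630	0.582600	-11.52900	2.49
O	3.04850	13.2771	2.28680	5.70110	1.54630	0.323900	0.867000	32.9089	0.250800	9.13
S	6.90530	1.46790	5.20340	22.2151	1.43790	0.253600	1.58630	56.1720	0.866900	19.86
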