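# Synthetic per-residue CD basis spectra (delta-epsilon, M^-1 cm^-1).
# Parametric Gaussian-band approximations at canonical band positions:
# helix +192/-208/-222 nm, strand +196/-217 nm, coil -197 nm,
# turn weak -190/+205/+225 nm. Amplitudes follow textbook per-residue
# magnitudes; these are NOT digitized experimental reference sets.
wavelength	helix	strand	turn	coil
180	3.8106	0.3672	-0.538	-0.6286
181	4.9995	0.53	-0.6987	-0.8803
182	6.4048	0.7469	-0.882	-1.2078
183	8.0113	1.028	-1.082	-1.6237
184	9.7834	1.3817	-1.2897	-2.1387
185	11.6632	1.8137	-1.4931	-2.7601
186	13.5715	2.3248	-1.6781	-3.49
187	15.4113	2.9101	-1.83	-4.3238
188	17.0742	3.5572	-1.9346	-5.2485
189	18.4488	4.2459	-1.98	-6.2421
190	19.4313	4.9484	-1.9583	-7.2736
191	19.9355	5.6307	-1.8664	-8.3042
192	19.9015	6.2549	-1.7065	-9.2888
193	19.3022	6.7822	-1.4859	-10.1797
194	18.1462	7.1764	-1.216	-10.9299
195	16.4762	7.408	-0.9113	-11.4972
196	14.3651	7.4565	-0.5875	-11.8479
197	11.9078	7.3129	-0.26	-11.9606
198	9.2126	6.9805	0.0569	-11.8274
199	6.3913	6.4741	0.3518	-11.4554
200	3.551	5.8184	0.6157	-10.8658
201	0.787	5.0446	0.8428	-10.0916
202	-1.8216	4.1876	1.0301	-9.1745
203	-4.2143	3.2825	1.1768	-8.1612
204	-6.3497	2.3618	1.2839	-7.0994
205	-8.204	1.4532	1.3541	-6.034
206	-9.7691	0.5788	1.3909	-5.0041
207	-11.0496	-0.2451	1.3984	-4.0411
208	-12.0608	-1.0073	1.3813	-3.1674
209	-12.8253	-1.7008	1.3444	-2.3969
210	-13.3708	-2.3215	1.2927	-1.735
211	-13.7282	-2.8666	1.2309	-1.1806
212	-13.9289	-3.3342	1.1635	-0.7276
213	-14.003	-3.7227	1.0944	-0.3662
214	-13.9779	-4.0302	1.0271	-0.0851
215	-13.8765	-4.2555	0.9642	0.1277
216	-13.7164	-4.3981	0.9077	0.2838
217	-13.5093	-4.4589	0.8586	0.3937
218	-13.2615	-4.4402	0.8172	0.4667
219	-12.974	-4.347	0.7832	0.5103
220	-12.6444	-4.1861	0.7556	0.5311
221	-12.2677	-3.9666	0.733	0.534
222	-11.8384	-3.699	0.714	0.5232
223	-11.3518	-3.3954	0.6967	0.5021
224	-10.8056	-3.068	0.6797	0.4734
225	-10.2006	-2.729	0.6615	0.4394
226	-9.5412	-2.3898	0.641	0.4019
227	-8.8355	-2.0602	0.6173	0.3627
228	-8.0947	-1.7485	0.59	0.323
229	-7.3324	-1.4609	0.5591	0.2839
230	-6.5638	-1.2017	0.5248	0.2465
231	-5.8042	-0.9732	0.4876	0.2113
232	-5.0683	-0.7759	0.4481	0.1789
233	-4.3691	-0.609	0.4072	0.1496
234	-3.7173	-0.4706	0.3659	0.1235
235	-3.1212	-0.358	0.3249	0.1008
236	-2.5857	-0.2681	0.2851	0.0812
237	-2.1134	-0.1977	0.2471	0.0646
238	-1.7041	-0.1435	0.2117	0.0508
239	-1.3554	-0.1026	0.1791	0.0394
240	-1.0634	-0.0722	0.1497	0.0302
241	-0.8229	-0.05	0.1236	0.0229
242	-0.6281	-0.0341	0.1008	0.0171
243	-0.4729	-0.0229	0.0812	0.0127
244	-0.3511	-0.0151	0.0646	0.0092
245	-0.2571	-0.0098	0.0508	0.0067
246	-0.1857	-0.0063	0.0394	0.0047
247	-0.1323	-0.004	0.0302	0.0033
248	-0.093	-0.0025	0.0229	0.0023
249	-0.0644	-0.0015	0.0171	0.0016
250	-0.044	-9e-04	0.0127	0.0011
251	-0.0297	-5e-04	0.0092	7e-04
252	-0.0197	-3e-04	0.0067	5e-04
253	-0.0129	-2e-04	0.0047	3e-04
254	-0.0084	-1e-04	0.0033	2e-04
255	-0.0053	-1e-04	0.0023	1e-04
256	-0.0034	0	0.0016	1e-04
257	-0.0021	0	0.0011	1e-04
258	-0.0013	0	7e-04	0
259	-8e-04	0	5e-04	0
260	-5e-04	0	3e-04	0
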