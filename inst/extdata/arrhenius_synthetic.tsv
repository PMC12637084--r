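constant	fatty_acid	Ea_kJ_per_mol	k_ref	T_ref_C
ki	18:1	245	2e-13	40
kp1	18:1	4.5	1e3	40
kp2	18:1	12	5e-3	40
kd	18:1	nd	1.5e-8	40
kbimol	18:1	63	5e-12	40
kpro1	18:1	nd	1e-7	40
kpro2	18:1	nd	1e-5	40
ke1	18:1	29	1.5e-4	40
ke2	18:1	nd	1e-4	40
ke3	18:1	30	2e-4	40
ke4	18:1	nd	2e-5	40
kald	18:1	49	3e-4	40
kket	18:1	2.8	4e-4	40
kloh1	18:1	nd	4e-4	40
kloh2	18:1	7.6	6e-4	40
kt1	18:1	nd	1e5	40
kt2	18:1	nd	1e5	40
kt3	18:1	nd	1e5	40
ki	18:2	270	1.5e-14	25
kp1	18:2	23	1e3	25
kp2	18:2	8.0	5e-2	25
kd	18:2	95	4e-9	25
kbimol	18:2	76	1e-11	25
kpro1	18:2	nd	1e-7	25
kpro2	18:2	nd	1e-5	25
ke1	18:2	95	1e-4	25
ke2	18:2	28	3e-4	25
ke3	18:2	23	5e-4	25
ke4	18:2	63	5e-5	25
kald	18:2	16	1e-4	25
kket	18:2	42	8e-5	25
kloh1	18:2	nd	8e-5	25
kloh2	18:2	29	4e-4	25
kt1	18:2	nd	1e5	25
kt2	18:2	nd	1e5	25
kt3	18:2	nd	1e5	25
ki	18:3	135	2e-14	4
kp1	18:3	19	1e3	4
kp2	18:3	11	1e-1	4
kd	18:3	nd	4e-9	4
kbimol	18:3	86	1e-11	4
kpro1	18:3	nd	1e-7	4
kpro2	18:3	nd	1e-5	4
ke1	18:3	nd	8e-4	4
ke2	18:3	131	8e-4	4
ke3	18:3	nd	1.5e-3	4
ke4	18:3	107	1e-4	4
kald	18:3	116	8e-4	4
kket	18:3	nd	1e-4	4
kloh1	18:3	nd	2e-4	4
kloh2	18:3	7.8	1.2e-3	4
kt1	18:3	nd	1e5	4
kt2	18:3	nd	1e5	4
kt3	18:3	nd	1e5	4
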