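species	valence	r_MO	r_OO	bare_diameter	x	gate_diameter	population_factor
K	1	2.80	2.72	2.8	6	8.32	1
K	1	2.80	2.72	2.8	5	8.32	2.2e-2
K	1	2.80	2.72	2.8	4	6.21	5.5e-5
K	1	2.80	2.72	2.8	3	5.54	2.5e-8
K	1	2.80	2.72	2.8	2	2.8	7.9e-13
Na	1	2.36	2.72	2.0	6	7.44	1
Na	1	2.36	2.72	2.0	5	7.44	5.8e-3
Na	1	2.36	2.72	2.0	4	5.44	1.7e-5
Na	1	2.36	2.72	2.0	3	5.10	3.7e-10
Na	1	2.36	2.72	2.0	2	2.0	6.3e-17
Ca	2	2.36	2.72	NA	6	7.44	1
Ca	2	2.36	2.72	NA	5	7.44	1.8e-16
Ca	2	2.36	2.72	NA	4	5.44	4.4e-34
Ca	2	2.36	2.72	NA	3	5.10	8.5e-53
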