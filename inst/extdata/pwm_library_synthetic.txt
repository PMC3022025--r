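>REST_like_synthetic
0.25	0.25	0.25	0.25
0.05	0.10	0.10	0.75
0.10	0.70	0.10	0.10
0.80	0.05	0.10	0.05
0.05	0.10	0.75	0.10
0.05	0.80	0.05	0.10
0.85	0.05	0.05	0.05
0.05	0.85	0.05	0.05
0.05	0.85	0.05	0.05
0.85	0.05	0.05	0.05
0.05	0.05	0.85	0.05
0.05	0.05	0.85	0.05
0.05	0.05	0.85	0.05
0.75	0.05	0.10	0.10
0.10	0.70	0.10	0.10
0.25	0.25	0.25	0.25
>TATA_like_synthetic
0.05	0.05	0.05	0.85
0.85	0.05	0.05	0.05
0.05	0.05	0.05	0.85
0.85	0.05	0.05	0.05
0.60	0.05	0.05	0.30
0.85	0.05	0.05	0.05
0.50	0.10	0.30	0.10
>CRE_like_synthetic
0.05	0.05	0.05	0.85
0.05	0.05	0.85	0.05
0.85	0.05	0.05	0.05
0.05	0.85	0.05	0.05
0.05	0.05	0.85	0.05
0.05	0.05	0.05	0.85
0.05	0.85	0.05	0.05
0.85	0.05	0.05	0.05
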