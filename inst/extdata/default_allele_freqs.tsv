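# Synthetic default frequencies of the trait-associated allele (panel
# column allele1) per population. These are plausible order-of-magnitude
# values chosen for simulation realism, NOT estimates from any study
# cohort.
population	rs12913832	rs1545397	rs16891982	rs1426654	rs885479	rs6119471	rs12203592	rs12896399
AA	0.03	0.15	0.05	0.35	0.03	0.85	0.02	0.15
SA	0.07	0.30	0.25	0.85	0.05	0.10	0.05	0.25
EA	0.01	0.85	0.02	0.05	0.65	0.10	0.01	0.15
E	0.75	0.95	0.97	0.99	0.07	0.02	0.15	0.45
mix	0.35	0.50	0.50	0.60	0.15	0.25	0.08	0.30
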