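trait,category,prevalence
substance_use,mental,0.0160
hyperkinetic,mental,0.0258
personality,mental,0.0047
psychotic,mental,0.0076
depressive,mental,0.0909
acute_stress,mental,0.0760
sleep_disturbance,mental,0.0538
anxiety,mental,0.0350
alcohol_use,mental,0.0178
phobia_compulsive,mental,0.0144
neck_back,somatic,0.1876
injury_musculoskeletal,somatic,0.0854
fractures,somatic,0.0718
naevus_mole,somatic,0.1085
acne,somatic,0.0593
laceration_cut,somatic,0.1020
headaches,somatic,0.1368
abdominal_pain,somatic,0.1614
asthma,somatic,0.0670
allergic_rhinitis,somatic,0.1008
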