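name	stems	related
adaptation	adapt	evolution, niche, plasticity, phenological shifts
aggregation	aggregat	consortia, superstructures
attractor	attractor	criticality, hysteresis, tipping points, stable states
chaos	chaos + chaotic	sensitivity, phase space divergence
diversity	diversit	entropy, heterogeneity, information, variation
dynamicity	dynamic	evolution, stasis, transformation
emergence	emergen	collective intelligence, gestalt principles
feedback	feedback	reinforcement, top-down causation
flow	flow	information, linkages
fractality	fractal	regularity, scale invariance
hierarchy	hierarch	levels, nestedness, scales
homeostasis	homeosta	control, robustness
interaction	interact	competition, dependence, parasitism, mutualism, synergy
memory	memory + memories	lagged responses, Markov processes
modularity	modul	cluster, connectivity, stability
network	network	food webs, feedbacks, nodes
nonequilibrium	non-equilib + non equilib + nonequilib	balance, disturbance, multiple stable states, instability
nonlinearity	non-linear + non linear + nonlinear	higher-order effects
resilience	resilien	brittleness, robustness, stability
scaling	scal + scale-depend + scale depend	discrete hierarchy, grain, levels
self-organization	self-orga + self orga + selforga	evolution, emergence, multicellularity, pattern formation
stability	stabilit	invasibility, persistence, resistance, robustness
threshold	thresho	criticality, tipping point
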