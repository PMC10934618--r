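# Default pipeline configuration.
# Protocol constants follow the canonical continuous fluorogenic NSP assays
# (0.1 M HEPES, 0.5 M NaCl, 0.03% Triton X-100, pH 7.5, 37 C); Michaelis
# constants are NOT published for these enzyme/substrate pairs and the KM
# values below are package placeholders — replace them with measured values
# before analysing real data.
kinetics:
  HNE:
    enzyme_conc: 1.0e-9        # M; elastase is specified by activity (1.25 mU/mL),
                               # a nominal 1 nM stands in for the molar amount
    substrate_id: MeO-Suc-AAPV-AFC
    S: 4.0e-5                  # M (40 uM substrate during the read)
    KM: 8.0e-5                 # M; placeholder -> competition factor 1.5
  PR3:
    enzyme_conc: 7.0e-9        # M (7 nM proteinase 3)
    substrate_id: MeO-Suc-AAPV-AFC
    S: 1.25e-4                 # M (125 uM)
    KM: 1.25e-4                # M; placeholder -> competition factor 2
  CatG:
    enzyme_conc: 2.0e-8        # M (20 nM cathepsin G)
    substrate_id: Suc-AAPF-AFC
    S: 2.5e-4                  # M (250 uM)
    KM: 1.25e-4                # M; placeholder -> competition factor 3
screen:
  I_molar: 2.5e-5              # 25 uM screening concentration
  preincubation_s: 900         # 15 min substrate-free preincubation
triage:
  no_inhibition_below: 0.05    # < 5% inhibition -> assumed inactive
  bounded_upper: 0.40          # 5-40% (closed interval) -> constant < bound
  bound_constant: 50           # M^-1 s^-1, the "< 50" inactivity convention
ladder:
  n_concentrations: 7          # seven-point inhibitor ladders
  replicates: 3                # triplicate independent experiments
  kobs_duration_span: [0.5, 5.0]  # identifiable-exponential design window
noise:
  relative_sd: 0.05            # per-point scatter keeping replicate SD <= 10%
  additive_sd: 0.0
reference_compound: "27"       # fold changes are reported against compound 27
dual_window: 10                # max fold gap for a "dual HNE/PR3" call
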