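# The worked four-component adherence case study, shared across tests,
# with its analytically known reference quantities (population-average and
# quintile-average gains follow from integrating the linear effect functions
# by hand).

cs_design <- case_study_design()
cs_effects <- case_study_effects()
cs_conditions <- enumerate_conditions(cs_design)

# integral over S ~ U(0,1) of each condition's gain function
cs_true_mean <- c(
  Min = 0, A = 0.75, B = 0.5, AB = 1.25, C = 0, AC = 0.75, BC = 1,
  ABC = 1.75, D = 0.5, AD = 1.25, BD = 1, ABD = 1.75, CD = 0.5,
  ACD = 1.25, BCD = 1.5, ABCD = 2.25
)

# linear effects: quintile averages are the values at stratum midpoints
cs_quintile_mid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
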