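# Example carafa run configuration (see ?run_config for all keys).
# input_dir omitted: a study-scale dataset is simulated from the seed.
seed: 7
n_perm: 999
alpha: 0.05
run_bayes: yes
magnitude: abs
min_n: 5
outlier_screen: yes
covariables: [month, air_temp]
candidates: [treatment, herbs, litter]
env_vars: [formica, collembola, litter, canopy_openness, herbs, air_temp, soil_moisture]
mcmc:
  chains: 4
  iter_traits: 3000
  iter_env: 4000
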