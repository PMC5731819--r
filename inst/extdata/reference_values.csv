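# Transcription of published single-molecule CoSMoS measurements of the
# E. coli beta-clamp / clamp-loader / polymerase system (mean +/- s.e.m.).
# These numbers are the recovery targets for the simulation scenarios; they
# are data, not outputs of this package.
experiment,quantity,value,sem,units
clamp_loading,tau_loader_dna,1.20,0.05,s
clamp_loading,tau_loader,0.41,0.01,s
clamp_loading,tau_clamp_loaded,1429.7,177.0,s
clamp_loading_atpgs,tau_complex,2.7,0.2,s
clamp_unloading,release_lag,4.1,0.4,s
clamp_unloading,tau_loader_total,10.8,1.2,s
clamp_unloading,tau_loader_nonproductive,2.5,0.1,s
clamp_unloading,pct_nonproductive,53,NA,%
pol3_lifetime,tau_pol3,15.7,1.1,s
pol3_lifetime,tau_pol3_dntp,16.1,1.0,s
pol3_lifetime,tau_pol3_no_dna_bleach,18.1,1.6,s
pol3_lifetime,tau_pol3_dna_bleach,16.8,1.8,s
pol1_dna,tau_pol1,42.2,1.8,s
polymerase_competition,tau_pol3,15.7,1.1,s
polymerase_competition,tau_pol4,14.2,1.8,s
polymerase_competition,tau_pol3_coloc_expt,15.8,0.9,s
polymerase_competition,coloc_duration,8.2,0.6,s
polymerase_competition,pct_switch_ab,70,NA,%
polymerase_competition,pct_switch_ba,22,NA,%
polymerase_competition,pct_coloc,9,NA,%
polymerase_competition,lag_ab,20.3,3.5,s
tau_complex,tau_pol3,14.8,0.9,s
tau_complex,pct_switch_ab,95,NA,%
tau_complex,pct_switch_ba,0,NA,%
tau_complex,pct_coloc,5,NA,%
tau_complex,lag_ab,11.3,1.3,s
groove_mutants,tau_pol3_eps_weak,7.9,1.2,s
groove_mutants,tau_pol3_eps_strong,40.2,8.7,s
groove_mutants,tau_pol4_groove,2.7,0.2,s
groove_mutants,tau_pol4_rim,14.9,1.7,s
groove_mutants,tau_pol2,10.4,1.3,s
groove_mutants,tau_pol2_groove,4.4,0.8,s
dna_substrates,tau_pol3_matched,15.7,1.1,s
dna_substrates,tau_pol3_lesion,17.6,2.1,s
dna_substrates,tau_pol3_mismatched,19.0,1.4,s
fluorophores,bleach_atto488,274.4,16.5,s
fluorophores,bleach_atto565,145.7,7.5,s
fluorophores,bleach_atto647N,93.0,7.4,s
labelling,p_label_pol3_alpha,67,NA,%
labelling,p_label_epsilon,71,NA,%
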