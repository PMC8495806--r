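# comma-separated, dot-decimal, UTF-8
# Length-mass regressions: mass = 10^(intercept + exp_length*log10(L)
# [+ exp_width*log10(W)]) for scale=log10 (analogous with natural log),
# lengths in mm, masses in mg. mass_basis says whether the prediction is
# fresh or dry; dry predictions are multiplied by dry_to_fresh_factor.
# PLACEHOLDER defaults marked for replacement from the cited collections
# (Sohlstroem et al. 2018, Mercer et al. 2001, Ruiz-Lupion et al. 2019).
taxon,scale,intercept,exp_length,exp_width,mass_basis,dry_to_fresh_factor,unit_in,unit_out,source
generic_arthropod,log10,-1.02,2.53,,fresh,1,mm,mg,Sohlstroem et al. 2018 (placeholder - verify)
generic_arthropod_lw,log10,-0.92,1.40,1.08,fresh,1,mm,mg,Sohlstroem et al. 2018 (placeholder - verify)
soil_mesofauna,log10,-1.52,2.60,,dry,4.0,mm,mg,Mercer et al. 2001 (placeholder - verify)
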