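# comma-separated, dot-decimal, UTF-8
# Boltzmann-Arrhenius metabolic regressions: ln X = ln_x0 + a*ln(M) - E/(k*T_K)
# with k = 8.62e-5 eV/K, M in mg fresh mass, X in J/h.
# PLACEHOLDER defaults: the widely used terrestrial-invertebrate coefficients
# attributed to Ehnes et al. 2011 (Ecol. Lett.); verify against the original
# source and replace with taxon-specific rows before real analyses.
group,ln_x0,a,activation_energy_eV,unit_mass,unit_out,source
default,23.055335,0.695071,0.68642,mg,J/h,Ehnes et al. 2011 (placeholder - verify)
detritivore,23.055335,0.695071,0.68642,mg,J/h,Ehnes et al. 2011 (placeholder - verify)
herbivore,23.055335,0.695071,0.68642,mg,J/h,Ehnes et al. 2011 (placeholder - verify)
omnivore,23.055335,0.695071,0.68642,mg,J/h,Ehnes et al. 2011 (placeholder - verify)
predator,23.055335,0.695071,0.68642,mg,J/h,Ehnes et al. 2011 (placeholder - verify)
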